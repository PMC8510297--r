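#' Construct a drug-perturbation compendium
#'
#' @param effects Gene-by-drug numeric matrix of perturbation effect sizes
#'   (each column: one drug's differential-expression profile vs control).
#' @param gold_mask Named logical vector over genes marking the reliable
#'   ("gold") genes; `NULL` means all genes are reliable.
#' @return Object of class `DrugCompendium`.
#' @export
drug_compendium <- function(effects, gold_mask = NULL) {
  effects <- as.matrix(effects)
  if (is.null(rownames(effects)) || is.null(colnames(effects)))
    stop("effects must have gene rownames and drug colnames")
  if (is.null(gold_mask))
    gold_mask <- stats::setNames(rep(TRUE, nrow(effects)), rownames(effects))
  if (!all(rownames(effects) %in% names(gold_mask)))
    stop("gold_mask must cover every compendium gene")
  structure(list(effects = effects,
                 gold_mask = gold_mask[rownames(effects)]),
            class = "DrugCompendium")
}

#' Read a compendium from TSV files
#'
#' The effects file is genes x drugs (first column `gene`, header = drug
#' ids); the optional mask file is two columns `gene<TAB>gold` with
#' `TRUE`/`FALSE`.
#'
#' @param effects_path,mask_path File paths (`mask_path` may be `NULL`).
#' @return A [drug_compendium()].
#' @export
read_drug_compendium <- function(effects_path, mask_path = NULL) {
  tab <- utils::read.delim(effects_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  eff <- as.matrix(tab[, -1, drop = FALSE])
  rownames(eff) <- as.character(tab[[1]])
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- utils::read.delim(mask_path, stringsAsFactors = FALSE)
    mask <- stats::setNames(as.logical(m[[2]]), as.character(m[[1]]))
  }
  drug_compendium(eff, mask)
}

#' Correlation between the disease signature and one drug profile
#'
#' Pearson correlation between the signature's summary effect sizes and the
#' drug's perturbation effect sizes over the genes present in both (and
#' flagged gold when `gold_only`). A strongly negative r marks a
#' signature-reversing drug. The p-value is two-sided from the t transform
#' with `n_shared - 2` degrees of freedom.
#'
#' @param sig A `GeneSignature`.
#' @param effects Named numeric vector: one drug's per-gene effect sizes.
#' @param gold_mask Named logical vector over the profile's genes, or
#'   `NULL`.
#' @param gold_only Restrict to gold genes (default `TRUE`).
#' @return List: `r`, `p`, `n_shared`. `r` is `NA` (p `NA`) when either
#'   vector is constant across the shared genes.
#' @export
disease_drug_correlation <- function(sig, effects, gold_mask = NULL,
                                     gold_only = TRUE) {
  dis <- signature_effects(sig)
  genes <- intersect(names(dis), names(effects))
  if (gold_only && !is.null(gold_mask))
    genes <- genes[gold_mask[genes] %in% TRUE]
  genes <- genes[!is.na(effects[genes])]
  if (length(genes) < 3L)
    stop("fewer than 3 shared genes between signature and drug profile")
  x <- dis[genes]; y <- effects[genes]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n_shared = length(genes)))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_shared = length(genes))
}

#' Rank a drug compendium against a disease signature
#'
#' Correlates every drug with the signature, Benjamini-Hochberg-corrects
#' the p-values across drugs, and ranks with rank 1 = most negative r
#' (strongest reversal). Drugs with undefined correlation are excluded from
#' ranking. Ties in r are broken by q then drug id.
#'
#' @param sig A `GeneSignature`.
#' @param compendium A `DrugCompendium`.
#' @param gold_only Restrict correlations to gold genes (default `TRUE`).
#' @return `data.frame`: `drug_id`, `n_shared`, `r`, `p`, `q`, `rank`,
#'   sorted by rank.
#' @export
rank_drugs <- function(sig, compendium, gold_only = TRUE) {
  drugs <- colnames(compendium$effects)
  res <- lapply(drugs, function(d) {
    h <- disease_drug_correlation(sig, compendium$effects[, d],
                                  compendium$gold_mask, gold_only)
    data.frame(drug_id = d, n_shared = h$n_shared, r = h$r, p = h$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (all(is.na(out$r))) stop("all drug profiles degenerate")
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  ranked <- out[ok, ]
  ord <- order(ranked$r, ranked$q, ranked$drug_id)
  ranked <- ranked[ord, ]
  ranked$rank <- seq_len(nrow(ranked))
  dropped <- out[!ok, ]
  if (nrow(dropped)) dropped$rank <- NA_integer_
  out <- rbind(ranked, dropped)
  rownames(out) <- NULL
  out
}

#' Genes reversed between disease and drug
#'
#' Among genes shared between the signature and the profile, counts those
#' whose effect signs are opposite (disease up / drug down or vice versa).
#'
#' @param sig A `GeneSignature`.
#' @param effects Named numeric vector of one drug's effect sizes.
#' @return List: `genes` (character), `fraction`, `n_shared`.
#' @export
reversal_gene_set <- function(sig, effects) {
  dis <- signature_effects(sig)
  genes <- intersect(names(dis), names(effects))
  genes <- genes[!is.na(effects[genes])]
  opp <- genes[sign(dis[genes]) * sign(effects[genes]) < 0]
  list(genes = sort(opp),
       fraction = if (length(genes)) length(opp) / length(genes) else NA_real_,
       n_shared = length(genes))
}

#' Threshold sensitivity grid for the drug ranking
#'
#' For every combination of FDR and absolute-effect-size thresholds,
#' reselects the signature, re-ranks the compendium, and records the top-k
#' reversal drugs. Stability is the mean pairwise Jaccard similarity of the
#' top-k sets across non-empty cells (1 when a single cell is evaluable).
#'
#' @param meta [run_meta()] table.
#' @param lodo [lodo_filter()] result or `NULL`.
#' @param compendium A `DrugCompendium`.
#' @param fdr_grid FDR thresholds (default `c(0.01, 0.05, 0.10, 0.20)`).
#' @param es_grid Effect-size floors (default `c(0.6, 0.8, 1.0, 1.2)`).
#' @param top_k Size of the per-cell top list (default 10).
#' @param gold_only Passed to [rank_drugs()].
#' @return List: `cells` (data.frame with `fdr`, `es`, `n_signature`,
#'   `top` as a list-column of drug ids), `stability`.
#' @export
sensitivity_grid <- function(meta, lodo, compendium,
                             fdr_grid = c(0.01, 0.05, 0.10, 0.20),
                             es_grid = c(0.6, 0.8, 1.0, 1.2),
                             top_k = 10, gold_only = TRUE) {
  grid <- expand.grid(fdr = sort(fdr_grid), es = sort(es_grid),
                      KEEP.OUT.ATTRS = FALSE)
  tops <- vector("list", nrow(grid))
  nsig <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sig <- suppressWarnings(
      select_signature(meta, lodo, fdr = grid$fdr[i], abs_es = grid$es[i]))
    nsig[i] <- nrow(sig$up) + nrow(sig$down)
    tops[[i]] <- if (nsig[i] >= 3L) {
      rk <- rank_drugs(sig, compendium, gold_only)
      utils::head(rk$drug_id[order(rk$rank)], top_k)
    } else character(0)
  }
  grid$n_signature <- nsig
  grid$top <- tops
  filled <- which(nsig >= 3L)
  stability <- if (length(filled) <= 1L) 1 else {
    pairs <- utils::combn(filled, 2)
    mean(apply(pairs, 2, function(ij) {
      a <- tops[[ij[1]]]; b <- tops[[ij[2]]]
      length(intersect(a, b)) / length(union(a, b))
    }))
  }
  list(cells = grid, stability = stability)
}
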