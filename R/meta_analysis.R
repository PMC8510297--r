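#' Hedges' adjusted g for a two-group comparison
#'
#' Standardized mean difference (case minus control) on the pooled standard
#' deviation, with the small-sample bias correction
#' \eqn{J = 1 - 3/(4\,df - 1)}, \eqn{df = n_1 + n_2 - 2}. The sampling
#' variance is \eqn{(n_1+n_2)/(n_1 n_2) + g^2 / (2(n_1+n_2))}.
#'
#' @param case_vals,ctrl_vals Numeric vectors, at least 2 finite values each.
#' @return List with `g` and `var_g`.
#' @export
hedges_g <- function(case_vals, ctrl_vals) {
  case_vals <- case_vals[is.finite(case_vals)]
  ctrl_vals <- ctrl_vals[is.finite(ctrl_vals)]
  n1 <- length(case_vals); n2 <- length(ctrl_vals)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 finite values per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(case_vals) +
          (n2 - 1) * stats::var(ctrl_vals)) / df
  if (sp2 <= 0)
    stop("degenerate gene: zero pooled standard deviation")
  J <- 1 - 3 / (4 * df - 1)
  g <- J * (mean(case_vals) - mean(ctrl_vals)) / sqrt(sp2)
  list(g = g, var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
}

#' Inverse-variance pooling of per-study effect sizes
#'
#' Fixed-effect pooling uses weights \eqn{w_i = 1/v_i}. The
#' DerSimonian-Laird random-effects model first computes Cochran's
#' \eqn{Q = \sum w_i (g_i - \bar g_F)^2}, the method-of-moments
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i))},
#' then re-pools with weights \eqn{1/(v_i + \tau^2)}.
#'
#' @param g_list Per-study effect sizes.
#' @param var_list Per-study sampling variances (> 0), same length.
#' @param model `"random_dl"` (default) or `"fixed"`.
#' @return List: `summary_es`, `summary_se`, `z`, `p` (two-sided normal),
#'   `tau2`, `cochran_q`, `k`.
#' @export
pool_effects <- function(g_list, var_list, model = c("random_dl", "fixed")) {
  model <- match.arg(model)
  stopifnot(length(g_list) == length(var_list), all(var_list > 0))
  k <- length(g_list)
  if (k < 2L) stop("pooling needs at least 2 studies")
  w <- 1 / var_list
  es_f <- sum(w * g_list) / sum(w)
  q <- sum(w * (g_list - es_f)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  if (model == "fixed") {
    es <- es_f; se <- sqrt(1 / sum(w)); tau2_out <- 0
  } else {
    ws <- 1 / (var_list + tau2)
    es <- sum(ws * g_list) / sum(ws); se <- sqrt(1 / sum(ws))
    tau2_out <- tau2
  }
  z <- es / se
  list(summary_es = es, summary_se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), tau2 = tau2_out, cochran_q = q, k = k)
}

#' Fisher's method for combining independent p-values
#'
#' \eqn{X^2 = -2 \sum \ln p_i} referred to a chi-squared distribution with
#' \eqn{2k} degrees of freedom. Zero p-values are clamped to 1e-300 with a
#' warning.
#'
#' @param p_list Numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
combine_pvalues_fisher <- function(p_list) {
  stopifnot(length(p_list) >= 1L, all(p_list <= 1))
  if (any(p_list <= 0)) {
    warning("p-value(s) of 0 clamped to 1e-300")
    p_list <- pmax(p_list, 1e-300)
  }
  stats::pchisq(-2 * sum(log(p_list)), df = 2 * length(p_list),
                lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

# Per-dataset gene-level summary statistics over a gene universe.
# Returns matrices (genes x 1 column each) of means, variances, group sizes,
# plus the pooled-t one-sided p-values used by the Fisher branch.
# Genes absent from the dataset or degenerate (zero pooled SD) come back NA.
.study_stats <- function(ds, universe) {
  idx <- match(universe, rownames(ds$expr))
  expr <- ds$expr[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  expr[is.na(idx), ] <- NA_real_
  ca <- expr[, ds$labels == "case", drop = FALSE]
  co <- expr[, ds$labels == "control", drop = FALSE]
  n1 <- rowSums(!is.na(ca)); n2 <- rowSums(!is.na(co))
  m1 <- rowMeans(ca, na.rm = TRUE); m2 <- rowMeans(co, na.rm = TRUE)
  v1 <- (rowSums(ca^2, na.rm = TRUE) - n1 * m1^2) / pmax(n1 - 1, 1)
  v2 <- (rowSums(co^2, na.rm = TRUE) - n2 * m2^2) / pmax(n2 - 1, 1)
  ok <- n1 >= 2 & n2 >= 2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  ok <- ok & sp2 > 0
  J <- 1 - 3 / (4 * df - 1)
  g <- ifelse(ok, J * (m1 - m2) / sqrt(sp2), NA_real_)
  vg <- ifelse(ok, (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)), NA_real_)
  tstat <- ifelse(ok, (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)), NA_real_)
  p_up <- ifelse(ok, stats::pt(tstat, df, lower.tail = FALSE), NA_real_)
  p_dn <- ifelse(ok, stats::pt(tstat, df, lower.tail = TRUE), NA_real_)
  list(g = g, vg = vg, p_up = p_up, p_dn = p_dn)
}

#' Per-gene multi-cohort meta-analysis
#'
#' For every gene in the shared universe: per-study Hedges' g (pooled-SD,
#' small-sample corrected), inverse-variance summary effect size
#' (DerSimonian-Laird random effects by default), a two-sided p-value from
#' the pooled z, Benjamini-Hochberg FDR across genes, and Fisher-combined
#' one-sided p-values per direction from each study's pooled-variance
#' t-statistic. Genes degenerate in a study are pooled over the remaining
#' studies; genes with fewer than 2 usable studies are dropped.
#'
#' @param datasets List of `ExpressionDataset`s (>= 2).
#' @param model Pooling model, `"random_dl"` or `"fixed"`.
#' @param min_fraction Passed to [shared_gene_universe()]; default 1 (gene
#'   must be measured in every dataset).
#' @return `data.frame` with one row per gene: `gene`, `summary_es`,
#'   `summary_se`, `z`, `p_es`, `q_es`, `tau2`, `cochran_q`,
#'   `p_fisher_up`, `p_fisher_down`, `n_studies`.
#' @export
run_meta <- function(datasets, model = c("random_dl", "fixed"),
                     min_fraction = 1) {
  model <- match.arg(model)
  stopifnot(length(datasets) >= 2L)
  universe <- shared_gene_universe(datasets, min_fraction)
  if (length(universe) == 0L) stop("empty shared gene universe")
  k <- length(datasets)
  stats_l <- lapply(datasets, .study_stats, universe = universe)
  G  <- vapply(stats_l, `[[`, numeric(length(universe)), "g")
  V  <- vapply(stats_l, `[[`, numeric(length(universe)), "vg")
  PU <- vapply(stats_l, `[[`, numeric(length(universe)), "p_up")
  PD <- vapply(stats_l, `[[`, numeric(length(universe)), "p_dn")
  dim(G) <- dim(V) <- dim(PU) <- dim(PD) <- c(length(universe), k)

  usable <- !is.na(G) & !is.na(V)
  n_studies <- rowSums(usable)
  keep <- n_studies >= 2L
  G <- G[keep, , drop = FALSE]; V <- V[keep, , drop = FALSE]
  PU <- PU[keep, , drop = FALSE]; PD <- PD[keep, , drop = FALSE]
  usable <- usable[keep, , drop = FALSE]
  genes <- universe[keep]
  kg <- n_studies[keep]

  W <- ifelse(usable, 1 / V, 0)
  sw <- rowSums(W)
  es_f <- rowSums(W * ifelse(usable, G, 0)) / sw
  Q <- rowSums(W * (ifelse(usable, G, es_f) - es_f)^2)
  denom <- sw - rowSums(W^2) / sw
  tau2 <- pmax(0, (Q - (kg - 1)) / denom)
  if (model == "fixed") {
    es <- es_f; se <- sqrt(1 / sw); tau2_out <- rep(0, length(es))
  } else {
    WS <- ifelse(usable, 1 / (V + tau2), 0)
    sws <- rowSums(WS)
    es <- rowSums(WS * ifelse(usable, G, 0)) / sws
    se <- sqrt(1 / sws)
    tau2_out <- tau2
  }
  z <- es / se
  p_es <- 2 * stats::pnorm(-abs(z))

  # row-wise Fisher combination, vectorized over genes
  fisher_row <- function(pm) {
    x2 <- -2 * rowSums(log(pmax(pm, 1e-300)), na.rm = TRUE)
    stats::pchisq(x2, df = 2 * rowSums(!is.na(pm)), lower.tail = FALSE)
  }
  data.frame(
    gene = genes,
    summary_es = es, summary_se = se, z = z,
    p_es = p_es, q_es = bh_fdr(p_es),
    tau2 = tau2_out, cochran_q = Q,
    p_fisher_up = fisher_row(PU), p_fisher_down = fisher_row(PD),
    n_studies = kg,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Leave-one-dataset-out robustness filter
#'
#' Re-runs the meta-analysis on each of the k subsets with one cohort
#' removed. A gene passes only if its FDR is below `fdr_threshold` and the
#' sign of its summary effect size is identical in the full analysis and in
#' every leave-one-out run.
#'
#' @param datasets List of `ExpressionDataset`s (>= 3 so every subset has
#'   >= 2).
#' @param model Pooling model.
#' @param fdr_threshold FDR cut applied in the full run and every subset
#'   run; default 0.01.
#' @param full Optional precomputed full-run [run_meta()] table (saves one
#'   run when the caller already has it).
#' @return Named logical vector over the genes of the full analysis.
#' @export
lodo_filter <- function(datasets, model = c("random_dl", "fixed"),
                        fdr_threshold = 0.01, full = NULL) {
  model <- match.arg(model)
  k <- length(datasets)
  if (k < 3L) stop("leave-one-dataset-out needs >= 3 datasets")
  if (is.null(full)) full <- run_meta(datasets, model)
  pass <- full$q_es < fdr_threshold
  sgn <- sign(full$summary_es)
  names(pass) <- full$gene
  for (i in seq_len(k)) {
    sub <- run_meta(datasets[-i], model)
    m <- match(full$gene, sub$gene)
    ok <- !is.na(m) & sub$q_es[m] < fdr_threshold &
      sign(sub$summary_es[m]) == sgn
    pass <- pass & ok
  }
  pass
}

#' Select the disease gene signature
#'
#' Keeps genes with `q_es < fdr`, `|summary_es| >= abs_es` and a passing
#' leave-one-dataset-out flag; partitions by effect sign and sorts by
#' decreasing absolute effect size (ties broken lexicographically by gene).
#'
#' @param meta [run_meta()] table.
#' @param lodo Named logical vector from [lodo_filter()], or `NULL` to skip
#'   the robustness requirement.
#' @param fdr FDR threshold (default 0.01).
#' @param abs_es Absolute summary-effect-size floor (default 0).
#' @return Object of class `GeneSignature`: list with data frames `up` and
#'   `down` (`gene`, `summary_es`) and a `thresholds` list.
#' @export
select_signature <- function(meta, lodo = NULL, fdr = 0.01, abs_es = 0) {
  keep <- meta$q_es < fdr & abs(meta$summary_es) >= abs_es
  if (!is.null(lodo)) {
    lp <- lodo[meta$gene]
    keep <- keep & !is.na(lp) & lp
  }
  sel <- meta[keep, c("gene", "summary_es")]
  sel <- sel[order(-abs(sel$summary_es), sel$gene), ]
  if (nrow(sel) == 0L) warning("empty signature at fdr=", fdr,
                               ", abs_es=", abs_es)
  structure(
    list(up = sel[sel$summary_es > 0, , drop = FALSE],
         down = sel[sel$summary_es < 0, , drop = FALSE],
         thresholds = list(fdr = fdr, abs_es = abs_es)),
    class = "GeneSignature"
  )
}

#' Build a GeneSignature from a named effect-size vector
#'
#' Convenience constructor for signatures that do not come from
#' [select_signature()] (e.g. external effect tables or simulations).
#' Genes with effect 0 are dropped.
#'
#' @param effects Named numeric vector of summary effect sizes.
#' @param fdr,abs_es Threshold metadata recorded on the signature.
#' @return A `GeneSignature`.
#' @export
gene_signature <- function(effects, fdr = NA_real_, abs_es = 0) {
  stopifnot(!is.null(names(effects)))
  df <- data.frame(gene = names(effects), summary_es = unname(effects),
                   stringsAsFactors = FALSE)
  df <- df[df$summary_es != 0, ]
  df <- df[order(-abs(df$summary_es), df$gene), ]
  structure(list(up = df[df$summary_es > 0, , drop = FALSE],
                 down = df[df$summary_es < 0, , drop = FALSE],
                 thresholds = list(fdr = fdr, abs_es = abs_es)),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature: %d up, %d down (fdr < %g, |ES| >= %g)\n",
              nrow(x$up), nrow(x$down), x$thresholds$fdr, x$thresholds$abs_es))
  invisible(x)
}

#' Effect-size vector of a signature
#'
#' @param sig A `GeneSignature`.
#' @return Named numeric vector of summary effect sizes (up then down).
#' @export
signature_effects <- function(sig) {
  both <- rbind(sig$up, sig$down)
  stats::setNames(both$summary_es, both$gene)
}

#' Per-sample signature score
#'
#' After shifting the dataset so its minimum value is at least 1, each
#' sample is scored as the geometric mean of its up-gene values minus the
#' geometric mean of its down-gene values; scores are then z-scored across
#' samples within the dataset. Zero score variance yields all-zero scores
#' with a warning.
#'
#' @param ds An `ExpressionDataset`.
#' @param sig A `GeneSignature` with at least one gene present in `ds`.
#' @return Named numeric vector of z-scored sample scores.
#' @export
signature_score <- function(ds, sig) {
  up <- intersect(sig$up$gene, rownames(ds$expr))
  dn <- intersect(sig$down$gene, rownames(ds$expr))
  if (length(up) + length(dn) == 0L)
    stop("no signature genes present in dataset '", ds$dataset_id, "'")
  lo <- min(ds$expr, na.rm = TRUE)
  expr <- if (lo < 1) ds$expr + (1 - lo) else ds$expr
  gm <- function(genes) {
    if (length(genes) == 0L) return(rep(0, ncol(expr)))
    exp(colMeans(log(expr[genes, , drop = FALSE]), na.rm = TRUE))
  }
  raw <- gm(up) - gm(dn)
  s <- stats::sd(raw)
  if (is.na(s) || s == 0) {
    warning("degenerate signature score variance; returning zeros")
    return(stats::setNames(rep(0, length(raw)), colnames(expr)))
  }
  stats::setNames((raw - mean(raw)) / s, colnames(expr))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via mid-ranks; ties count one half.
#'
#' @param scores Numeric vector.
#' @param labels Vector with classes `"case"` (positive) and `"control"`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == "case"
  n1 <- sum(pos); n0 <- sum(!pos)
  stopifnot(n1 > 0L, n0 > 0L, length(scores) == length(labels))
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
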