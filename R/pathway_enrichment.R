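#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are counted once.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; the `description` attribute on
#'   each element holds the second field.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT format error at line ", i, ": fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    attr(genes, "description") <- f[2]
    sets[[i]] <- genes
    nms[i] <- f[1]
  }
  stats::setNames(sets, nms)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection Named list of gene vectors (optionally carrying a
#'   `description` attribute).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    g <- collection[[nm]]
    d <- attr(g, "description")
    if (is.null(d)) d <- "na"
    paste(c(nm, d, as.character(g)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided overrepresentation test for a gene set
#'
#' Hypergeometric upper tail \eqn{P(X \ge k)} with N = |universe|,
#' K = |set within universe|, n = |signature|, k = |overlap|. The odds
#' ratio comes from the 2x2 table with a Haldane 0.5 correction when any
#' cell is zero.
#'
#' @param signature_genes Character vector (subset of `universe`).
#' @param gene_set Character vector; intersected with `universe` first.
#' @param universe Character vector of all measured genes.
#' @return List: `p`, `odds_ratio`, `overlap`, `overlap_genes`, `set_size`.
#' @export
ora_fisher <- function(signature_genes, gene_set, universe) {
  if (length(universe) == 0L) stop("empty gene universe")
  signature_genes <- intersect(unique(signature_genes), universe)
  set_u <- intersect(unique(gene_set), universe)
  N <- length(universe); K <- length(set_u); n <- length(signature_genes)
  hits <- intersect(signature_genes, set_u)
  k <- length(hits)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
  if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5
                               cc <- cc + 0.5; d <- d + 0.5 }
  list(p = p, odds_ratio = (a * d) / (b * cc), overlap = k,
       overlap_genes = sort(hits), set_size = K)
}

#' Overrepresentation analysis of a signature against a collection
#'
#' Sets with fewer than `min_size` genes inside the universe are excluded
#' before testing, so the Benjamini-Hochberg correction runs over exactly
#' the tested sets. Results are sorted by q then p.
#'
#' @param signature A `GeneSignature` (up and down genes are combined) or a
#'   plain character vector of genes.
#' @param collection Named list of gene sets ([read_gmt()]).
#' @param universe All measured genes.
#' @param min_size Minimum in-universe set size (default 5).
#' @param fdr_threshold Significance flag threshold on q (default 0.05).
#' @return `data.frame`: `set_name`, `set_size`, `overlap`, `odds_ratio`,
#'   `p`, `q`, `significant`, `overlap_genes` (comma-joined).
#' @export
enrich <- function(signature, collection, universe, min_size = 5,
                   fdr_threshold = 0.05) {
  genes <- if (inherits(signature, "GeneSignature"))
    c(signature$up$gene, signature$down$gene) else as.character(signature)
  sizes <- vapply(collection, function(s)
    length(intersect(unique(s), universe)), integer(1))
  keep <- sizes >= min_size
  if (!any(keep)) {
    warning("no gene sets with >= ", min_size, " genes in the universe")
    return(data.frame(set_name = character(), set_size = integer(),
                      overlap = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), significant = logical(),
                      overlap_genes = character(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(names(collection)[keep], function(nm) {
    o <- ora_fisher(genes, collection[[nm]], universe)
    data.frame(set_name = nm, set_size = o$set_size, overlap = o$overlap,
               odds_ratio = o$odds_ratio, p = o$p,
               overlap_genes = paste(o$overlap_genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q <= fdr_threshold
  out <- out[order(out$q, out$p, out$set_name),
             c("set_name", "set_size", "overlap", "odds_ratio",
               "p", "q", "significant", "overlap_genes")]
  rownames(out) <- NULL
  out
}
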