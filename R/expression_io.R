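#' Construct an expression dataset
#'
#' Bundles one cohort's gene-by-sample expression matrix with its two-class
#' phenotype labels. Values are expected on the log2 scale (see
#' [ensure_log_scale()]); class labels must be `"case"` or `"control"`.
#'
#' @param dataset_id Single string identifying the cohort.
#' @param expr Numeric matrix, rows = gene symbols, columns = sample ids.
#'   `NA` entries are allowed and flagged in `meta$n_missing`.
#' @param labels Named character vector (names = sample ids) or unnamed
#'   vector in column order, values in `c("case", "control")`.
#' @param platform Free-form platform string.
#' @param meta Named list of free-form annotations.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `dataset_id`, `expr`, `labels` (named, aligned to columns), `platform`
#'   and `meta`.
#' @export
expression_dataset <- function(dataset_id, expr, labels,
                               platform = "unknown", meta = list()) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop("gene symbols must be unique within a dataset (collapse probes first)")
  if (is.null(names(labels))) {
    if (length(labels) != ncol(expr))
      stop("unnamed labels must match the number of samples")
    names(labels) <- colnames(expr)
  }
  if (!all(colnames(expr) %in% names(labels)))
    stop("every sample needs exactly one label")
  labels <- labels[colnames(expr)]
  bad <- setdiff(unique(labels), c("case", "control"))
  if (length(bad))
    stop("unrecognized class token(s): ", paste(bad, collapse = ", "),
         " (allowed: case, control)")
  if (sum(labels == "case") < 1L || sum(labels == "control") < 1L)
    stop("dataset '", dataset_id, "' needs at least 1 case and 1 control")
  all_na <- colSums(!is.na(expr)) == 0L
  if (any(all_na))
    stop("sample(s) entirely missing: ",
         paste(colnames(expr)[all_na], collapse = ", "))
  meta$n_missing <- sum(is.na(expr))
  structure(
    list(dataset_id = dataset_id, expr = expr, labels = labels,
         platform = platform, meta = meta),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s': %d genes x %d samples (%d case / %d control), platform %s\n",
              x$dataset_id, nrow(x$expr), ncol(x$expr),
              sum(x$labels == "case"), sum(x$labels == "control"),
              x$platform))
  invisible(x)
}

#' Read an expression matrix and labels file into an ExpressionDataset
#'
#' The matrix is tab-separated with the first column holding feature ids and
#' the header row holding sample ids; `NA` marks missing values. The labels
#' file is a two-column TSV `sample<TAB>class` with classes `case`/`control`.
#' Samples present in the matrix but absent from the labels file are dropped
#' with a warning; samples in the labels file but not in the matrix are
#' ignored.
#'
#' @param matrix_path Path to the expression TSV.
#' @param labels_path Path to the labels TSV.
#' @param dataset_id Cohort identifier stored on the result.
#' @param platform Optional platform string.
#' @return An [expression_dataset()].
#' @export
read_expression_table <- function(matrix_path, labels_path, dataset_id,
                                  platform = "unknown") {
  header <- strsplit(readLines(matrix_path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", matrix_path,
         ": expected 'gene<TAB>sample ids...'")
  tab <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- as.character(tab[[1]])
  storage.mode(expr) <- "double"

  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("labels file must have columns sample, class")
  labels <- stats::setNames(as.character(lab[[2]]), as.character(lab[[1]]))

  unlabeled <- setdiff(colnames(expr), names(labels))
  if (length(unlabeled)) {
    warning("dropping ", length(unlabeled),
            " sample(s) absent from labels file: ",
            paste(unlabeled, collapse = ", "))
    expr <- expr[, setdiff(colnames(expr), unlabeled), drop = FALSE]
  }
  expression_dataset(dataset_id, expr, labels[colnames(expr)],
                     platform = platform)
}

#' Write an ExpressionDataset to matrix + labels TSV files
#'
#' Inverse of [read_expression_table()]; values round-trip to full double
#' precision.
#'
#' @param ds An `ExpressionDataset`.
#' @param matrix_path,labels_path Output paths.
#' @return Invisibly, `ds`.
#' @export
write_expression_table <- function(ds, matrix_path, labels_path) {
  tab <- data.frame(gene = rownames(ds$expr), ds$expr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- data.frame(sample = names(ds$labels), class = unname(ds$labels),
                    stringsAsFactors = FALSE)
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Multiple probes mapping to one gene are summarized by the per-sample
#' arithmetic mean; probes absent from the map are dropped.
#'
#' @param expr Feature-by-sample numeric matrix with probe rownames.
#' @param probe_to_gene Named character vector `probe -> gene`, or a
#'   two-column data frame (probe, gene). Many-to-one allowed.
#' @return Gene-by-sample matrix with unique gene rownames, genes sorted.
#' @export
collapse_probes <- function(expr, probe_to_gene) {
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2]]),
                                     as.character(probe_to_gene[[1]]))
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  keep <- rownames(expr) %in% names(probe_to_gene)
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0L)
    return(matrix(numeric(0), 0, ncol(expr),
                  dimnames = list(NULL, colnames(expr))))
  gene <- probe_to_gene[rownames(expr)]
  out <- rowsum(expr, group = gene, na.rm = FALSE)
  out <- out / as.vector(table(gene)[rownames(out)])
  out[order(rownames(out)), , drop = FALSE]
}

#' Ensure a dataset is on the log2 scale
#'
#' Heuristic: if the 99th percentile of finite values exceeds `threshold`
#' (default 50), the data are taken to be linear-scale intensities and
#' transformed by `log2(x + 1)`. The decision is recorded in
#' `meta$log_transformed`.
#'
#' @param ds An `ExpressionDataset`.
#' @param threshold 99th-percentile cutoff separating linear from log2 data.
#' @return The (possibly transformed) `ExpressionDataset`. Idempotent.
#' @export
ensure_log_scale <- function(ds, threshold = 50) {
  q99 <- stats::quantile(ds$expr, 0.99, na.rm = TRUE, names = FALSE)
  if (is.na(q99) || q99 <= threshold) {
    ds$meta$log_transformed <- isTRUE(ds$meta$log_transformed)
    return(ds)
  }
  if (min(ds$expr, na.rm = TRUE) < 0)
    stop("dataset '", ds$dataset_id,
         "' looks linear-scale (q99 > ", threshold,
         ") but has negative values; cannot log-transform")
  message("ensure_log_scale: log2(x+1)-transforming dataset '",
          ds$dataset_id, "' (q99 = ", signif(q99, 4), ")")
  ds$expr <- log2(ds$expr + 1)
  ds$meta$log_transformed <- TRUE
  ds
}

#' Genes measured in a sufficient fraction of datasets
#'
#' @param datasets List of `ExpressionDataset`s (at least 2).
#' @param min_fraction Gene must appear in at least
#'   `ceiling(min_fraction * n_datasets)` datasets; default 1 (all).
#' @return Lexicographically sorted character vector of gene symbols
#'   (possibly empty).
#' @export
shared_gene_universe <- function(datasets, min_fraction = 1) {
  stopifnot(length(datasets) >= 2L, min_fraction > 0, min_fraction <= 1)
  counts <- table(unlist(lapply(datasets, function(d) rownames(d$expr))))
  need <- ceiling(min_fraction * length(datasets))
  sort(names(counts)[counts >= need])
}
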