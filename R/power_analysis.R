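#' Sampling variance of a standardized mean difference
#'
#' \eqn{v = (n_1+n_2)/(n_1 n_2) + es^2 / (2 (n_1+n_2))}; the large-sample
#' variance of Hedges' g at effect size `es`.
#'
#' @param n_case,n_ctrl Per-group sample sizes (>= 2). Vectorized.
#' @param es Assumed effect size.
#' @return Numeric vector of variances.
#' @export
study_variance <- function(n_case, n_ctrl, es) {
  stopifnot(all(n_case >= 2), all(n_ctrl >= 2))
  (n_case + n_ctrl) / (n_case * n_ctrl) + es^2 / (2 * (n_case + n_ctrl))
}

#' Analytic power of an inverse-variance meta-analysis
#'
#' Power to detect a summary effect size `target_es` in a k-study
#' meta-analysis at two-sided level `alpha`, following the Hedges & Pigott
#' approach. Between-study heterogeneity is specified either as a level
#' (\eqn{\tau^2 = c \bar v} with c = 0, 1/3, 2/3, 1 for none/low/moderate/
#' high, \eqn{\bar v} the mean within-study variance at `target_es`) or as
#' an explicit `tau2`. The summary variance is
#' \eqn{V = 1/\sum 1/(v_i + \tau^2)}, the noncentrality
#' \eqn{\lambda = es/\sqrt V}, and
#' \eqn{power = 1 - \Phi(z_{1-\alpha/2} - \lambda) +
#'              \Phi(-z_{1-\alpha/2} - \lambda)}.
#'
#' @param sizes Two-column data frame or matrix of per-study `n_case`,
#'   `n_ctrl`.
#' @param target_es Summary effect size to detect.
#' @param alpha Two-sided type-I error (default 0.01).
#' @param heterogeneity One of `"none"`, `"low"`, `"moderate"`, `"high"`.
#' @param tau2 Optional explicit between-study variance; overrides
#'   `heterogeneity`.
#' @return Power in `[0, 1]`.
#' @export
meta_power <- function(sizes, target_es, alpha = 0.01,
                       heterogeneity = c("none", "low", "moderate", "high"),
                       tau2 = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  sizes <- as.matrix(sizes)
  v <- study_variance(sizes[, 1], sizes[, 2], target_es)
  if (is.null(tau2)) {
    cc <- c(none = 0, low = 1 / 3, moderate = 2 / 3, high = 1)
    tau2 <- cc[[match.arg(heterogeneity)]] * mean(v)
  }
  stopifnot(tau2 >= 0)
  V <- 1 / sum(1 / (v + tau2))
  lambda <- target_es / sqrt(V)
  zc <- stats::qnorm(1 - alpha / 2)
  1 - stats::pnorm(zc - lambda) + stats::pnorm(-zc - lambda)
}

#' Per-study case/control sizes of the 11 ulcerative-colitis cohorts
#'
#' Reads the packaged fixture of the 11 colon-biopsy expression cohorts
#' used for signature discovery (171 cases, 101 controls, 272 samples).
#'
#' @return `data.frame` with columns `dataset_id`, `n_case`, `n_ctrl`.
#' @export
uc_cohort_sizes <- function() {
  path <- system.file("extdata", "table1_sizes.tsv", package = "drugrepos",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
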