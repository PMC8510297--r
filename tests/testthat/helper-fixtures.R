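# Small in-code fixtures shared across test files.

# a tiny deterministic ExpressionDataset
toy_dataset <- function(id = "toy", n_genes = 3, n_case = 2, n_ctrl = 2,
                        seed = 1) {
  set.seed(seed)
  n <- n_case + n_ctrl
  expr <- matrix(rnorm(n_genes * n, 8, 1), n_genes, n,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 sprintf("s%d", seq_len(n))))
  expression_dataset(id, expr,
                     c(rep("case", n_case), rep("control", n_ctrl)))
}

# write a dataset to temp TSVs; returns c(matrix=, labels=)
write_toy_files <- function(ds, dir = withr::local_tempdir(.local_envir =
                                                            parent.frame())) {
  mp <- file.path(dir, paste0(ds$dataset_id, "_expr.tsv"))
  lp <- file.path(dir, paste0(ds$dataset_id, "_labels.tsv"))
  write_expression_table(ds, mp, lp)
  c(matrix = mp, labels = lp)
}

# independent BH step-up oracle (kept separate from the implementation)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# brute-force hypergeometric upper tail by pmf enumeration
hyper_tail_oracle <- function(k, N, K, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# hand-written Cox partial likelihood (no ties) for a single covariate
cox_loglik_1d <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# signature straight from a named effect vector
sig_from_effects <- function(effects) gene_signature(effects)

# a small six-subject event stream exercising every cohort-assembly rule:
#  s1 qualifies (treatment), s2 qualifies (comparator),
#  s3 has no qualifying diagnosis, s4 carries an exclusion diagnosis,
#  s5's only prescription predates diagnosis, s6 has the outcome before index
cohort_fixture_events <- function() {
  data.frame(
    subject_id = c("s1", "s1", "s1", "s1",
                   "s2", "s2", "s2",
                   "s3", "s3",
                   "s4", "s4", "s4",
                   "s5", "s5", "s5",
                   "s6", "s6", "s6"),
    date = c("2010-01-01", "2010-03-01", "2011-03-01", "2012-01-01",
             "2010-01-01", "2010-02-01", "2013-02-01",
             "2010-01-01", "2010-06-01",
             "2010-01-01", "2010-02-01", "2010-06-01",
             "2010-06-01", "2010-01-01", "2011-01-01",
             "2010-01-01", "2010-02-01", "2010-03-01"),
    kind = c("dx", "rx", "px", "visit",
             "dx", "rx", "visit",
             "dx", "rx",
             "dx", "dx", "rx",
             "dx", "rx", "visit",
             "dx", "px", "rx"),
    code = c("556", "atorvastatin", "45.8", "V70",
             "556", "niacin", "V70",
             "401", "atorvastatin",
             "556", "555.9", "atorvastatin",
             "556", "atorvastatin", "V70",
             "556", "45.8", "atorvastatin"),
    stringsAsFactors = FALSE)
}
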