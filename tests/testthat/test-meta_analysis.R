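test_that("Hedges' g matches hand computation and is antisymmetric", {
  h <- hedges_g(c(2, 3, 4), c(0, 1, 2))
  expect_equal(h$g, 1.6, tolerance = 1e-12)
  expect_equal(h$var_g, 6 / 9 + 1.6^2 / 12, tolerance = 1e-12)

  # identical groups: zero effect, variance reduces to (n1+n2)/(n1 n2)
  x <- c(1.2, 3.4, 2.2, 0.8)
  h0 <- hedges_g(x, x)
  expect_equal(h0$g, 0)
  expect_equal(h0$var_g, 8 / 16)

  # swapping groups negates g and keeps the variance
  hs <- hedges_g(c(0, 1, 2), c(2, 3, 4))
  expect_equal(hs$g, -h$g)
  expect_equal(hs$var_g, h$var_g)

  # close to metafor's SMD (which uses the exact bias correction)
  set.seed(1)
  ca <- rnorm(12, 1); co <- rnorm(9)
  esc <- metafor::escalc(measure = "SMD", m1i = mean(ca), m2i = mean(co),
                         sd1i = sd(ca), sd2i = sd(co), n1i = 12, n2i = 9)
  hm <- hedges_g(ca, co)
  expect_equal(hm$g, as.numeric(esc$yi), tolerance = 0.01)
  expect_equal(hm$var_g, as.numeric(esc$vi), tolerance = 0.01)

  expect_error(hedges_g(c(1, 1, 1), c(1, 1, 1)), "degenerate")
  expect_error(hedges_g(1, c(1, 2)), ">= 2")
})

test_that("inverse-variance pooling matches closed forms and metafor DL", {
  # four identical studies, fixed effect
  po <- pool_effects(rep(1, 4), rep(0.25, 4), "fixed")
  expect_equal(po$summary_es, 1)
  expect_equal(po$summary_se, 0.25)
  expect_equal(po$z, 4)

  # homogeneous inputs truncate tau2 at 0, so DL == fixed
  pr <- pool_effects(rep(1, 4), rep(0.25, 4), "random_dl")
  expect_equal(pr$tau2, 0)
  expect_equal(pr$summary_es, po$summary_es)
  expect_equal(pr$summary_se, po$summary_se)

  # random 11-study problems against metafor's DerSimonian-Laird
  set.seed(11)
  for (i in 1:5) {
    g <- rnorm(11, 0.5, 0.8)
    v <- runif(11, 0.05, 0.5)
    mine <- pool_effects(g, v, "random_dl")
    ref <- metafor::rma(yi = g, vi = v, method = "DL")
    expect_equal(mine$summary_es, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$summary_se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(mine$cochran_q, ref$QE, tolerance = 1e-10)
  }
  expect_error(pool_effects(1, 0.2), "2 studies")

  # fixed-model SE shrinks as studies are added
  se_k <- sapply(2:8, function(k)
    pool_effects(rep(0.5, k), rep(0.3, k), "fixed")$summary_se)
  expect_true(all(diff(se_k) < 0))
})

test_that("Fisher's method combines p-values correctly", {
  expect_equal(combine_pvalues_fisher(0.123), 0.123, tolerance = 1e-12)
  # X2 = -4 ln(0.5) = 2.7726 on 4 df
  expect_equal(combine_pvalues_fisher(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  expect_warning(p0 <- combine_pvalues_fisher(c(0, 0.5)), "clamped")
  expect_true(p0 < 1e-100)

  # null calibration: combined p of k uniforms is uniform
  set.seed(5)
  combined <- replicate(2000, combine_pvalues_fisher(runif(5)))
  expect_gt(ks.test(combined, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches an independent step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(3)
  for (i in 1:5) {
    p <- runif(sample(5:200, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-14)
  }
  # invariant to permutation (up to reordering)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("run_meta composes per-study g with pooling", {
  d1 <- toy_dataset("a", n_genes = 1, n_case = 5, n_ctrl = 5, seed = 1)
  d2 <- toy_dataset("b", n_genes = 1, n_case = 5, n_ctrl = 5, seed = 2)
  m <- run_meta(list(d1, d2))
  h1 <- hedges_g(d1$expr[1, d1$labels == "case"],
                 d1$expr[1, d1$labels == "control"])
  h2 <- hedges_g(d2$expr[1, d2$labels == "case"],
                 d2$expr[1, d2$labels == "control"])
  po <- pool_effects(c(h1$g, h2$g), c(h1$var_g, h2$var_g), "random_dl")
  expect_equal(m$summary_es, po$summary_es, tolerance = 1e-12)
  expect_equal(m$p_es, po$p, tolerance = 1e-12)
  expect_equal(m$n_studies, 2L)
})

test_that("type-I error of the pooled z is near nominal on null data", {
  sim <- gen_multicohort(
    sim_config(11, as.matrix(uc_cohort_sizes()[, 2:3]), 2000, 0, seed = 1))
  m <- run_meta(sim$datasets, model = "fixed")
  expect_lt(abs(mean(m$p_es < 0.05) - 0.05), 0.01)
})

test_that("label swap negates every effect and mirrors the signature", {
  sim <- gen_multicohort(sim_config(3, cbind(rep(8, 3), rep(8, 3)),
                                    300, 30, de_effect_mean = 1.5,
                                    seed = 9))
  m <- run_meta(sim$datasets)
  flipped <- lapply(sim$datasets, function(d) {
    d$labels[] <- ifelse(d$labels == "case", "control", "case")
    d
  })
  mf <- run_meta(flipped)
  expect_equal(mf$summary_es, -m$summary_es, tolerance = 1e-12)
  s1 <- select_signature(m, NULL, 0.01, 0)
  s2 <- select_signature(mf, NULL, 0.01, 0)
  expect_identical(s1$up$gene, s2$down$gene)
  expect_identical(s1$down$gene, s2$up$gene)
})

test_that("LODO removes genes driven by a single cohort", {
  set.seed(21)
  sizes <- cbind(rep(12, 5), rep(12, 5))
  sim <- gen_multicohort(sim_config(5, sizes, 500, 40,
                                    de_effect_mean = 1.5, seed = 13))
  # plant a gene DE in exactly one cohort
  ds <- sim$datasets
  null_gene <- setdiff(rownames(ds[[1]]$expr),
                       names(sim$truth$de_genes))[1]
  ds[[1]]$expr[null_gene, ds[[1]]$labels == "case"] <-
    ds[[1]]$expr[null_gene, ds[[1]]$labels == "case"] + 6
  full <- run_meta(ds)
  lodo <- lodo_filter(ds, fdr_threshold = 0.01, full = full)
  expect_false(lodo[[null_gene]])
  # whereas genes DE everywhere pass
  expect_gt(mean(lodo[names(sim$truth$de_genes)]), 0.9)
  # passing genes are a subset of full-analysis significance
  expect_true(all(full$q_es[match(names(lodo)[lodo], full$gene)] < 0.01))
  expect_error(lodo_filter(ds[1:2]), ">= 3")
})

test_that("signature selection applies thresholds and ordering", {
  sim <- gen_multicohort(sim_config(3, cbind(rep(10, 3), rep(10, 3)),
                                    100, 10, de_effect_mean = 1.5,
                                    seed = 2))
  m <- run_meta(sim$datasets)
  all_in <- select_signature(m, NULL, fdr = 1.000001, abs_es = 0)
  expect_equal(nrow(all_in$up) + nrow(all_in$down), nrow(m))
  expect_warning(none <- select_signature(m, NULL, fdr = 0.01,
                                          abs_es = max(abs(m$summary_es)) + 1),
                 "empty")
  expect_equal(nrow(none$up) + nrow(none$down), 0L)
  # ordering: decreasing |ES|
  sig <- select_signature(m, NULL, 0.05, 0)
  expect_true(all(diff(abs(sig$up$summary_es)) <= 0))
  expect_true(all(diff(abs(sig$down$summary_es)) <= 0))
})

test_that("signature scores separate cases from controls", {
  sim <- gen_multicohort(sim_config(3, cbind(rep(15, 3), rep(15, 3)),
                                    400, 40, de_effect_mean = 1.5,
                                    seed = 4))
  m <- run_meta(sim$datasets)
  sig <- select_signature(m, NULL, 0.01, 0)
  ds <- sim$datasets[[1]]
  sc <- signature_score(ds, sig)
  expect_equal(mean(sc), 0, tolerance = 1e-12)
  expect_gt(mean(sc[ds$labels == "case"]),
            mean(sc[ds$labels == "control"]))
  expect_gt(auroc(sc, ds$labels), 0.9)

  # constant up-only signature degenerates to zero scores with a warning
  expr <- matrix(5, 2, 4, dimnames = list(c("u1", "u2"), paste0("s", 1:4)))
  cds <- expression_dataset("const", expr,
                            c("case", "case", "control", "control"))
  csig <- sig_from_effects(c(u1 = 1, u2 = 2))
  expect_warning(sc0 <- signature_score(cds, csig), "degenerate")
  expect_equal(unname(sc0), rep(0, 4))
  expect_error(signature_score(cds, sig_from_effects(c(zz = 1))),
               "no signature genes")
})

test_that("AUROC equals brute-force pair counting", {
  expect_equal(auroc(c(1, 2, 3, 10, 11), c("control", "control", "control",
                                           "case", "case")), 1)
  sc <- c(3, 1, 2, 5, 4)
  lb <- c("case", "control", "control", "case", "control")
  pairs <- expand.grid(i = which(lb == "case"), j = which(lb == "control"))
  brute <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                       ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
  expect_equal(auroc(sc, lb), brute)
  # shuffled labels at large n are near chance
  set.seed(8)
  s <- rnorm(4000)
  l <- sample(rep(c("case", "control"), 2000))
  expect_lt(abs(auroc(s, l) - 0.5), 0.03)
})
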