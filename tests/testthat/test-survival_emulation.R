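library(survival)

test_that("cohort assembly applies every eligibility rule", {
  co <- build_cohort(cohort_fixture_events(),
                     diagnosis_codes = "556",
                     exposure_drugs = "atorvastatin",
                     comparator_drugs = c("niacin", "losartan"),
                     exclusion_dx = c("153", "555"),
                     outcome_codes = "45.8")
  expect_equal(sort(co$subject_id), c("s1", "s2"))
  att <- attr(co, "attrition")
  expect_equal(unname(att["no_diagnosis"]), 1L)          # s3
  expect_equal(unname(att["excluded_dx"]), 1L)           # s4 (Crohn's 555.9)
  expect_equal(unname(att["no_qualifying_rx"]), 1L)      # s5 (rx before dx)
  expect_equal(unname(att["prior_or_same_day_outcome"]), 1L)  # s6

  s1 <- co[co$subject_id == "s1", ]
  expect_equal(s1$exposure, "treatment")
  expect_equal(s1$index_date,
               as.numeric(as.Date("2010-03-01")))
  expect_true(s1$event)
  expect_equal(s1$time_days, 365)                        # to 2011-03-01
  s2 <- co[co$subject_id == "s2", ]
  expect_equal(s2$exposure, "comparator")
  expect_false(s2$event)
  expect_equal(s2$time_days, 1096)                       # censored at last visit
  expect_equal(s2$rx_niacin, 1L)
})

test_that("Kaplan-Meier estimator matches hand values and survfit", {
  km <- km_estimator(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # no events: the curve never steps
  expect_equal(nrow(km_estimator(c(1, 2), c(FALSE, FALSE))), 0L)
  # non-increasing, bounded by 1
  set.seed(14)
  t <- round(rexp(300, 1 / 50)) + 1
  e <- rbinom(300, 1, 0.7) == 1
  km <- km_estimator(t, e)
  expect_true(all(diff(km$surv) <= 0) && all(km$surv <= 1))
  sf <- survfit(Surv(t, e) ~ 1)
  idx <- sf$n.event > 0
  expect_equal(km$surv, sf$surv[idx], tolerance = 1e-12)
  expect_equal(km$se, (sf$std.err * sf$surv)[idx], tolerance = 1e-12)
  expect_equal(km$n_risk, sf$n.risk[idx])
})

test_that("Cox fit maximizes the written-out partial likelihood", {
  # 8-subject toy, no ties, single binary covariate
  toy <- data.frame(time_days = c(2, 5, 7, 9, 12, 14, 20, 25),
                    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE,
                              TRUE, TRUE),
                    x = c(1, 1, 0, 1, 0, 1, 0, 0))
  fit <- cox_fit(toy, "x")
  brute <- optimize(function(b) cox_loglik_1d(b, toy$x, toy$time_days,
                                              toy$event),
                    c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$coef), brute$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik, brute$objective, tolerance = 1e-9)

  # the score-test direction agrees with logrank observed - expected
  lr <- survdiff(Surv(time_days, event) ~ x, toy)
  expect_equal(sign(unname(fit$coef)),
               sign(lr$obs[2] - lr$exp[2]))

  # duplicated covariate: singular information
  toy$x2 <- toy$x
  expect_error(cox_fit(toy, c("x", "x2")), "singular")
  # constant covariate rejected
  toy$c1 <- 1
  expect_error(cox_fit(toy, "c1"), "constant")
})

test_that("Cox fit agrees with coxph under both tie methods", {
  gs <- gen_survival_cohort(600, true_hr = 0.6, exposure_prob = 0.4,
                            confounders = list(
                              exposure = c(age_std = 0.5, comorbidity_1 = 0.7),
                              hazard = c(age_std = 0.4, comorbidity_1 = 0.6)),
                            censor_rate = 0.3, seed = 11)
  ch <- gs$cohort
  ch$time_days <- ceiling(ch$time_days / 30)   # heavy date ties
  ch$treated <- as.integer(ch$exposure == "treatment")
  covs <- c("exposure", "age_std", "sex", "comorbidity_1")
  for (tie in c("efron", "breslow")) {
    fit <- cox_fit(ch, covs, ties = tie)
    ref <- coxph(Surv(time_days, event) ~ treated + age_std + sex +
                   comorbidity_1, data = ch, ties = tie)
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-8)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  }
  # rank invariance: doubling all times leaves coefficients unchanged
  ch2 <- ch; ch2$time_days <- ch2$time_days * 2
  expect_equal(cox_fit(ch2, covs)$coef, cox_fit(ch, covs)$coef,
               tolerance = 1e-10)
  # hr = exp(coef), CI ordered
  fit <- cox_fit(ch, covs)
  expect_equal(fit$hr, exp(fit$coef))
  expect_true(all(fit$ci95[, "lo"] < fit$ci95[, "hi"]))
})

test_that("PH diagnostic agrees with cox.zph and flags violations", {
  gs <- gen_survival_cohort(400, true_hr = 0.7, exposure_prob = 0.4,
                            censor_rate = 0.25, seed = 3)
  ch <- gs$cohort
  ch$treated <- as.integer(ch$exposure == "treatment")
  fit <- cox_fit(ch, c("exposure", "age_std"))
  ref <- coxph(Surv(time_days, event) ~ treated + age_std, data = ch)
  pz <- ph_test(fit, ch)
  cz <- cox.zph(ref, transform = "km")
  expect_equal(pz$p[1:2], unname(cz$table[1:2, "p"]), tolerance = 1e-6)
  expect_equal(pz$p[3], unname(cz$table["GLOBAL", "p"]), tolerance = 1e-6)

  # a time-varying exposure effect is detected most of the time
  set.seed(77)
  detected <- replicate(20, {
    n <- 400
    x <- rbinom(n, 1, 0.5)
    # effect reverses after t0: strong violation of proportionality
    t0 <- 30
    rate1 <- exp(-1.2 * x) / 60
    rate2 <- exp(+1.2 * x) / 60
    t1 <- rexp(n, rate1)
    tt <- ifelse(t1 < t0, t1, t0 + rexp(n, rate2))
    cens <- runif(n, 50, 250)
    d <- data.frame(time_days = pmin(tt, cens), event = tt <= cens, x = x)
    f <- cox_fit(d, "x")
    ph_test(f, d)$p[1] < 0.05
  })
  expect_gte(mean(detected), 0.8)
})

test_that("propensity matching balances confounded covariates", {
  gs <- gen_survival_cohort(3000, true_hr = 0.6, exposure_prob = 0.15,
                            confounders = list(
                              exposure = c(age_std = 0.8, comorbidity_1 = 0.8),
                              hazard = c(age_std = 0.5)),
                            censor_rate = 0.3, seed = 3)
  covs <- c("age_std", "sex", "comorbidity_1", "comorbidity_2")
  pm <- propensity_match(gs$cohort, covs, seed = 4)
  bal <- attr(pm, "balance")
  expect_gt(max(abs(bal$smd_before)), 0.3)
  expect_true(all(abs(bal$smd_after) < 0.1))
  # 1:1 without replacement
  expect_equal(sum(pm$exposure == "treatment"),
               sum(pm$exposure == "comparator"))
  expect_false(anyDuplicated(pm$subject_id) > 0)

  # no confounding: already balanced, matching keeps it that way
  gs0 <- gen_survival_cohort(1500, true_hr = 1, exposure_prob = 0.5,
                             censor_rate = 0.3, seed = 5)
  pm0 <- propensity_match(gs0$cohort, covs, seed = 6)
  bal0 <- attr(pm0, "balance")
  expect_true(all(abs(bal0$smd_before) < 0.12))
  expect_true(all(abs(bal0$smd_after) < 0.15))

  # treated majority: every comparator used at most once
  gs2 <- gen_survival_cohort(400, true_hr = 1, exposure_prob = 0.7,
                             censor_rate = 0.3, seed = 7)
  pm2 <- propensity_match(gs2$cohort, covs, seed = 8)
  n_comp <- sum(gs2$cohort$exposure == "comparator")
  expect_equal(attr(pm2, "n_pairs"), n_comp)
  expect_equal(sum(pm2$exposure == "comparator"), n_comp)
})

test_that("duration analyses preserve the unrestricted fit at threshold 0", {
  gs <- gen_survival_cohort(1200, true_hr = 0.6, exposure_prob = 0.4,
                            censor_rate = 0.3, seed = 21)
  ch <- gs$cohort
  ds <- duration_sensitivity(ch, "rx_duration_days",
                             min_duration_grid = c(0, 90, 180),
                             covariate_names = c("exposure", "age_std"))
  base <- cox_fit(ch, c("exposure", "age_std"))
  expect_equal(ds$grid$hr[1], base$hr[["exposure"]], tolerance = 1e-10)
  expect_true(all(ds$grid$stable))
  # a threshold leaving < 5 treated subjects is marked unstable
  ds2 <- duration_sensitivity(ch, "rx_duration_days",
                              min_duration_grid = max(ch$rx_duration_days),
                              covariate_names = c("exposure", "age_std"))
  expect_false(ds2$grid$stable[1])

  # when only long exposure lowers hazard, the contrast shows it
  set.seed(31)
  n <- 1500
  dur <- rexp(n, 1 / 400)
  long <- as.integer(dur >= 183)
  tt <- rexp(n, exp(log(0.35) * long) / 800)
  cens <- rexp(n, 1 / 2500)
  sim <- data.frame(subject_id = sprintf("L%04d", 1:n),
                    exposure = "treatment",
                    time_days = pmin(tt, cens) + 720,  # all followed >= 720d
                    event = tt <= cens,
                    rx_duration_days = dur,
                    stringsAsFactors = FALSE)
  dsl <- duration_sensitivity(sim, "rx_duration_days",
                              min_duration_grid = 0,
                              covariate_names = "exposure",
                              min_followup = 720)
  expect_lt(dsl$contrast$hr[["long_term"]], 1)
  expect_lt(dsl$contrast$ci95["long_term", "hi"], 1)
})

test_that("negative-control outcome separates effect from confounding", {
  # effect on the primary outcome only: control HR CI covers 1
  gs <- gen_survival_cohort(2500, true_hr = 0.5, exposure_prob = 0.4,
                            censor_rate = 0.3, seed = 41)
  nc <- negative_control(gs$cohort, "exposure")
  expect_gt(nc$ci95["exposure", "hi"], 1)
  expect_lt(nc$ci95["exposure", "lo"], 1)
  # identical outcome columns give the identical fit
  ch <- gs$cohort
  ch$control_time_days <- ch$time_days
  ch$control_event <- ch$event
  expect_equal(negative_control(ch, "exposure")$coef,
               cox_fit(ch, "exposure")$coef)
})
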