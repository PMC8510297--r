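# Target-trial-style retrospective cohort construction and survival
# analysis: cohort assembly from subject event streams, Kaplan-Meier
# estimation, Cox proportional-hazards fitting from the partial likelihood
# (Efron ties), Schoenfeld-based PH diagnostics, propensity matching, and
# duration / negative-control sensitivity analyses.

# prefix match of event codes against a code list ("153" matches "153.4")
.code_match <- function(codes, code_list) {
  if (length(code_list) == 0L) return(rep(FALSE, length(codes)))
  pat <- paste0("^(", paste(gsub("([.\\\\])", "\\\\\\1", code_list),
                            collapse = "|"), ")")
  grepl(pat, codes)
}

#' Assemble an analysis cohort from a subject-level event stream
#'
#' Implements a new-user, active-comparator design: keeps subjects with a
#' qualifying diagnosis, no exclusion diagnosis, and a qualifying
#' prescription dated strictly after the first diagnosis. Exposure is
#' `"treatment"` if the subject has any exposure-drug prescription after
#' first diagnosis (index = first such date, intention-to-treat at
#' initiation, even when comparator drugs were also prescribed), else
#' `"comparator"` (index = first comparator prescription after diagnosis).
#' Follow-up runs from index to the first outcome code, else censoring at
#' the last recorded event of any kind. Subjects with an outcome on or
#' before the index date are excluded (time must be positive). All code
#' matching is by prefix.
#'
#' @param events Data frame with columns `subject_id`, `date`
#'   (Date/ISO-8601 string/day number), `kind` (`dx`, `rx`, `px`, `visit`),
#'   `code`.
#' @param diagnosis_codes Codes defining the qualifying diagnosis.
#' @param exposure_drugs,comparator_drugs Drug code lists.
#' @param exclusion_dx Diagnosis codes that exclude a subject outright.
#' @param outcome_codes Codes defining the outcome event.
#' @param comorbidity_codes Optional named list of diagnosis-code lists;
#'   each yields a 0/1 flag for any occurrence on or before index.
#' @param subjects Optional data frame `subject_id`, `birth_date`, `sex`
#'   supplying demographics (`age` at index in years, `sex` as 0/1 with
#'   male = 1).
#' @return `data.frame` (class `CohortTable`): `subject_id`, `exposure`,
#'   `index_date`, `time_days`, `event`, per-comparator-drug 0/1 flags,
#'   comorbidity flags, and demographics when available. The attrition
#'   report (counts removed per rule) is in `attr(, "attrition")`.
#' @export
build_cohort <- function(events, diagnosis_codes, exposure_drugs,
                         comparator_drugs, exclusion_dx, outcome_codes,
                         comorbidity_codes = list(), subjects = NULL) {
  ev <- data.frame(subject_id = as.character(events$subject_id),
                   date = as.numeric(as.Date(events$date, origin = "1970-01-01")),
                   kind = as.character(events$kind),
                   code = as.character(events$code),
                   stringsAsFactors = FALSE)
  split_ev <- split(ev, ev$subject_id)
  attrition <- c(input = length(split_ev), no_diagnosis = 0L,
                 excluded_dx = 0L, no_qualifying_rx = 0L,
                 prior_or_same_day_outcome = 0L, zero_followup = 0L,
                 kept = 0L)
  rows <- list()
  for (sid in names(split_ev)) {
    e <- split_ev[[sid]]
    dx <- e[e$kind == "dx", ]
    qual_dx <- dx$date[.code_match(dx$code, diagnosis_codes)]
    if (length(qual_dx) == 0L) {
      attrition["no_diagnosis"] <- attrition["no_diagnosis"] + 1L; next
    }
    if (any(.code_match(dx$code, exclusion_dx))) {
      attrition["excluded_dx"] <- attrition["excluded_dx"] + 1L; next
    }
    dx0 <- min(qual_dx)
    rx <- e[e$kind == "rx", ]
    expo_dates <- rx$date[.code_match(rx$code, exposure_drugs) & rx$date > dx0]
    comp_dates <- rx$date[.code_match(rx$code, comparator_drugs) & rx$date > dx0]
    if (length(expo_dates) == 0L && length(comp_dates) == 0L) {
      attrition["no_qualifying_rx"] <- attrition["no_qualifying_rx"] + 1L; next
    }
    if (length(expo_dates)) {
      exposure <- "treatment"; index <- min(expo_dates)
    } else {
      exposure <- "comparator"; index <- min(comp_dates)
    }
    out_dates <- e$date[.code_match(e$code, outcome_codes)]
    if (any(out_dates <= index)) {
      attrition["prior_or_same_day_outcome"] <-
        attrition["prior_or_same_day_outcome"] + 1L; next
    }
    if (length(out_dates)) {
      time <- min(out_dates) - index; event <- TRUE
    } else {
      time <- max(e$date) - index; event <- FALSE
    }
    if (time <= 0) {
      attrition["zero_followup"] <- attrition["zero_followup"] + 1L; next
    }
    row <- data.frame(subject_id = sid, exposure = exposure,
                      index_date = index, time_days = time, event = event,
                      stringsAsFactors = FALSE)
    for (drug in comparator_drugs)
      row[[paste0("rx_", drug)]] <-
        as.integer(any(.code_match(rx$code, drug) & rx$date <= index))
    for (nm in names(comorbidity_codes))
      row[[nm]] <- as.integer(any(.code_match(dx$code,
                                              comorbidity_codes[[nm]]) &
                                  dx$date <= index))
    rows[[sid]] <- row
  }
  attrition["kept"] <- length(rows)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), exposure = character(),
               index_date = numeric(), time_days = numeric(),
               event = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(subjects) && nrow(out)) {
    m <- match(out$subject_id, as.character(subjects$subject_id))
    if ("birth_date" %in% names(subjects))
      out$age <- (out$index_date -
                  as.numeric(as.Date(subjects$birth_date[m],
                                     origin = "1970-01-01"))) / 365.25
    if ("sex" %in% names(subjects)) {
      sx <- subjects$sex[m]
      out$sex <- if (is.numeric(sx)) sx else as.integer(sx %in% c("male", "M", "1"))
    }
  }
  attr(out, "attrition") <- attrition
  class(out) <- c("CohortTable", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival is stepped down at each distinct event time; censored-only
#' times shrink the risk set without a step. The variance is Greenwood's
#' formula.
#'
#' @param time Follow-up times (> 0).
#' @param event Logical/0-1 event indicators.
#' @return `data.frame`: `time` (distinct event times), `n_risk`,
#'   `n_event`, `surv`, `var` (Greenwood), `se`.
#' @export
km_estimator <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0))
  event <- as.logical(event)
  tt <- sort(unique(time[event]))
  n_risk <- vapply(tt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- surv^2 * cumsum(n_event / (n_risk * (n_risk - n_event)))
  data.frame(time = tt, n_risk = n_risk, n_event = n_event,
             surv = surv, var = gw, se = sqrt(gw))
}

# Efron/Breslow partial-likelihood value, score and observed information
# at beta. When want_sch, also returns per-distinct-event-time summed
# Schoenfeld residuals (sch) and information slices (vk, p x p x T), both
# ordered by decreasing event time.
.cox_deriv <- function(beta, X, time, event, ties, want_sch = FALSE) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  loglik <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  # sweep from latest to earliest time, accumulating risk-set sums
  ord <- order(-time)
  ev_ord <- ord[event[ord]]          # events, latest first
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  utimes <- sort(unique(time[event]), decreasing = TRUE)
  nt <- length(utimes)
  sch <- if (want_sch) matrix(0, nt, p) else NULL
  vk <- if (want_sch) array(0, c(p, p, nt)) else NULL
  d_at <- numeric(nt)
  j <- 1L; jd <- 1L
  for (ki in seq_len(nt)) {
    ti <- utimes[ki]
    j2 <- j
    while (j2 <= n && time[ord[j2]] >= ti) j2 <- j2 + 1L
    if (j2 > j) {
      blk <- ord[j:(j2 - 1L)]
      Xb <- X[blk, , drop = FALSE]
      S0 <- S0 + sum(w[blk])
      S1 <- S1 + drop(crossprod(Xb, w[blk]))
      S2 <- S2 + crossprod(Xb * w[blk], Xb)
      j <- j2
    }
    jd2 <- jd
    while (jd2 <= length(ev_ord) && time[ev_ord[jd2]] == ti) jd2 <- jd2 + 1L
    dead <- ev_ord[jd:(jd2 - 1L)]
    jd <- jd2
    d <- length(dead)
    wd <- w[dead]
    S0d <- sum(wd)
    S1d <- drop(crossprod(X[dead, , drop = FALSE], wd))
    S2d <- crossprod(X[dead, , drop = FALSE] * wd, X[dead, , drop = FALSE])
    xsum <- colSums(X[dead, , drop = FALSE])
    loglik <- loglik + sum(eta[dead])
    U <- U + xsum
    zbar_acc <- numeric(p)
    Ik <- matrix(0, p, p)
    for (l in seq_len(d) - 1L) {
      frac <- if (ties == "efron") l / d else 0
      s0 <- S0 - frac * S0d
      s1 <- S1 - frac * S1d
      s2 <- S2 - frac * S2d
      zb <- s1 / s0
      loglik <- loglik - log(s0)
      U <- U - zb
      Ik <- Ik + s2 / s0 - tcrossprod(zb)
      zbar_acc <- zbar_acc + zb
    }
    I <- I + Ik
    if (want_sch) { sch[ki, ] <- xsum - zbar_acc; vk[, , ki] <- Ik }
    d_at[ki] <- d
  }
  list(loglik = loglik, U = U, I = I, sch = sch, vk = vk,
       event_times = utimes, d_at = d_at)
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Cox partial likelihood with the Efron correction for tied
#' event times (Breslow available), using the analytic score and observed
#' information. Convergence when the maximum absolute score component
#' drops below 1e-9, capped at 25 iterations. Standard errors come from
#' the inverse observed information; confidence intervals and p-values are
#' Wald-based.
#'
#' @param cohort A `CohortTable` (or data frame) with `time_days`, `event`
#'   and covariate columns. An `exposure` column with values
#'   `treatment`/`comparator` is converted to a 0/1 covariate named
#'   `exposure`.
#' @param covariate_names Columns to include as covariates.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param time_col,event_col Column names for follow-up and event status.
#' @return Object of class `SurvivalFit`: list with `coef`, `hr`, `se`,
#'   `ci95` (matrix lo/hi), `p`, `loglik`, `loglik_null`, `n`, `n_events`,
#'   `var` (covariance matrix), `ties`.
#' @export
cox_fit <- function(cohort, covariate_names, ties = c("efron", "breslow"),
                    time_col = "time_days", event_col = "event") {
  ties <- match.arg(ties)
  X <- .design_matrix(cohort, covariate_names)
  time <- as.numeric(cohort[[time_col]])
  event <- as.logical(cohort[[event_col]])
  if (sum(event) < 1L) stop("no events in cohort")
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(colnames(X)[const], collapse = ", "))
  p <- ncol(X)
  beta <- numeric(p)
  dv <- .cox_deriv(beta, X, time, event, ties)
  loglik_null <- dv$loglik
  for (iter in seq_len(25L)) {
    Ichol <- tryCatch(chol(dv$I), error = function(e)
      stop("singular information matrix (collinear covariates?)"))
    step <- backsolve(Ichol, forwardsolve(t(Ichol), dv$U))
    beta_new <- beta + step
    dv_new <- .cox_deriv(beta_new, X, time, event, ties)
    # step-halving if the likelihood went down
    h <- 0L
    while (dv_new$loglik < dv$loglik - 1e-12 && h < 10L) {
      beta_new <- (beta + beta_new) / 2
      dv_new <- .cox_deriv(beta_new, X, time, event, ties)
      h <- h + 1L
    }
    ll_change <- abs(dv_new$loglik - dv$loglik)
    beta <- beta_new; dv <- dv_new
    # converged when the score vanishes or the partial likelihood has
    # stopped moving at floating-point resolution
    if (max(abs(dv$U)) < 1e-9 ||
        ll_change < 1e-10 * (abs(dv$loglik) + 1)) break
    if (iter == 25L)
      stop("Newton-Raphson failed to converge in 25 iterations ",
           "(max |score| = ", signif(max(abs(dv$U)), 3), ")")
  }
  if (max(abs(beta)) > 15)
    stop("monotone partial likelihood (perfect separation); ",
         "a Firth-type penalty would be needed (not implemented)")
  V <- chol2inv(chol(dv$I))
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  zq <- stats::qnorm(0.975)
  ci <- cbind(lo = exp(beta - zq * se), hi = exp(beta + zq * se))
  rownames(ci) <- colnames(X)
  structure(
    list(coef = stats::setNames(beta, colnames(X)),
         hr = stats::setNames(exp(beta), colnames(X)),
         se = stats::setNames(se, colnames(X)),
         ci95 = ci,
         p = stats::setNames(2 * stats::pnorm(-abs(beta / se)), colnames(X)),
         loglik = dv$loglik, loglik_null = loglik_null,
         n = nrow(X), n_events = sum(event), var = V, ties = ties,
         covariate_names = colnames(X),
         time_col = time_col, event_col = event_col),
    class = "SurvivalFit"
  )
}

.design_matrix <- function(cohort, covariate_names) {
  cols <- lapply(covariate_names, function(nm) {
    v <- cohort[[nm]]
    if (is.null(v)) stop("covariate '", nm, "' not found")
    if (nm == "exposure" && !is.numeric(v))
      v <- as.integer(v == "treatment")
    as.numeric(v)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariate_names
  X
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- data.frame(coef = x$coef, HR = x$hr,
                    lo95 = x$ci95[, "lo"], hi95 = x$ci95[, "hi"],
                    p = signif(x$p, 3))
  print(tab, digits = 4)
  invisible(x)
}

#' Proportional-hazards diagnostic from scaled Schoenfeld residuals
#'
#' Score-type test of a time-varying coefficient \eqn{\beta(t) = \beta +
#' \theta g(t)}: the Schoenfeld residuals are correlated with a transform
#' of event time (default the left-continuous Kaplan-Meier scale
#' \eqn{g(t) = 1 - \hat S(t^-)}), giving a 1-df chi-squared test per
#' covariate plus a global test on all covariates.
#'
#' @param fit A `SurvivalFit` from [cox_fit()].
#' @param cohort The cohort the fit came from.
#' @param transform `"km"` (default), `"identity"`, or `"rank"`.
#' @return `data.frame` with rows per covariate plus `GLOBAL`: `chisq`,
#'   `df`, `p`.
#' @export
ph_test <- function(fit, cohort, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  X <- .design_matrix(cohort, fit$covariate_names)
  time <- as.numeric(cohort[[fit$time_col]])
  event <- as.logical(cohort[[fit$event_col]])
  dv <- .cox_deriv(fit$coef, X, time, event, fit$ties, want_sch = TRUE)
  ut <- dv$event_times           # decreasing
  ord <- order(ut)
  ut <- ut[ord]
  sch <- dv$sch[ord, , drop = FALSE]
  vk <- dv$vk[, , ord, drop = FALSE]
  d_at <- dv$d_at[ord]
  g <- switch(transform,
    identity = ut,
    rank = rank(ut),
    km = {
      km <- km_estimator(time, event)
      s_prev <- c(1, utils::head(km$surv, -1))   # S(t-)
      1 - s_prev[match(ut, km$time)]
    })
  d <- sum(d_at)
  gbar <- sum(g * d_at) / d
  gc_ <- g - gbar
  p <- length(fit$coef)
  # score test for beta(t) = beta + theta * g(t): the efficient information
  # for theta accounts for the correlation with the main-effect block
  u <- drop(crossprod(sch, gc_))
  A <- matrix(0, p, p)   # sum g^2 V_k
  B <- matrix(0, p, p)   # sum g   V_k
  for (ki in seq_along(gc_)) {
    A <- A + gc_[ki]^2 * vk[, , ki]
    B <- B + gc_[ki] * vk[, , ki]
  }
  Iinv <- fit$var
  Eff <- A - B %*% Iinv %*% B    # efficient information for theta
  per_chisq <- vapply(seq_len(p), function(j) u[j]^2 / Eff[j, j], numeric(1))
  global <- drop(crossprod(u, solve(Eff, u)))
  res <- data.frame(
    covariate = c(fit$covariate_names, "GLOBAL"),
    chisq = c(per_chisq, global),
    df = c(rep(1L, p), p),
    stringsAsFactors = FALSE)
  res$p <- stats::pchisq(res$chisq, res$df, lower.tail = FALSE)
  res
}

#' 1:1 propensity-score matching without replacement
#'
#' The propensity score is estimated by L1-regularized logistic regression
#' of exposure on the covariates (penalty by 5-fold cross-validated
#' deviance; plain logistic regression when there are fewer than two
#' covariates). Matching is greedy nearest-neighbor on the logit of the
#' propensity, processing treated subjects in descending propensity order,
#' each comparator used at most once. A caliper of 0 means no caliper; a
#' positive `caliper_logit` discards pairs further apart than that on the
#' logit scale.
#'
#' @param cohort A `CohortTable`.
#' @param covariate_names Covariates entering the propensity model.
#' @param caliper_logit Caliper on the logit scale; 0 (default) = none.
#' @param seed Seed for the cross-validation folds.
#' @return The matched `CohortTable` subset, with `attr(, "balance")` — a
#'   data frame of standardized mean differences before/after matching —
#'   and `attr(, "propensity")` the full-cohort logit scores.
#' @export
propensity_match <- function(cohort, covariate_names, caliper_logit = 0,
                             seed = 1L) {
  treated <- cohort$exposure == "treatment"
  if (!any(!treated)) stop("no comparator subjects to match against")
  if (!any(treated)) stop("no treated subjects to match")
  X <- .design_matrix(cohort, covariate_names)
  y <- as.integer(treated)
  if (ncol(X) >= 2L) {
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                               nfolds = 5)
    lp <- drop(stats::predict(cvfit, newx = X, s = "lambda.min",
                              type = "link"))
  } else {
    gfit <- stats::glm(y ~ X, family = stats::binomial())
    lp <- drop(stats::predict(gfit, type = "link"))
  }
  t_idx <- which(treated)[order(-lp[treated])]
  c_idx <- which(!treated)
  c_free <- rep(TRUE, length(c_idx))
  pairs_t <- integer(0); pairs_c <- integer(0)
  for (ti in t_idx) {
    if (!any(c_free)) break
    cand <- c_idx[c_free]
    dist <- abs(lp[cand] - lp[ti])
    bi <- which.min(dist)
    if (caliper_logit > 0 && dist[bi] > caliper_logit) next
    chosen <- cand[bi]
    c_free[match(chosen, c_idx)] <- FALSE
    pairs_t <- c(pairs_t, ti); pairs_c <- c(pairs_c, chosen)
  }
  keep <- sort(c(pairs_t, pairs_c))
  matched <- cohort[keep, , drop = FALSE]
  smd <- function(dat) {
    tr <- dat$exposure == "treatment"
    vapply(covariate_names, function(nm) {
      v <- .design_matrix(dat, nm)[, 1]
      s <- sqrt((stats::var(v[tr]) + stats::var(v[!tr])) / 2)
      if (is.na(s) || s == 0) 0 else (mean(v[tr]) - mean(v[!tr])) / s
    }, numeric(1))
  }
  attr(matched, "balance") <- data.frame(
    covariate = covariate_names,
    smd_before = smd(cohort), smd_after = smd(matched),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(matched, "propensity") <- lp
  attr(matched, "n_pairs") <- length(pairs_t)
  matched
}

#' Treatment-duration sensitivity analysis
#'
#' For each minimum-duration threshold, the treated arm is restricted to
#' subjects whose prescription duration meets it (the comparator arm is
#' untouched) and the Cox model is refitted. Grid points leaving fewer
#' than 5 treated subjects are marked unstable. When `min_followup` and
#' `long_term_days` are supplied, an additional short- vs long-term
#' contrast is fitted among treated subjects followed at least
#' `min_followup` days: long-term (duration >= `long_term_days`) vs
#' short-term exposure.
#'
#' @param cohort A `CohortTable`.
#' @param rx_durations Named numeric vector (names = subject ids) or a
#'   column name in `cohort` holding per-subject days on therapy.
#' @param min_duration_grid Thresholds in days (0 = unrestricted).
#' @param covariate_names Covariates for the refits (must include
#'   `exposure`).
#' @param min_followup,long_term_days Parameters of the short/long
#'   contrast (defaults 720 and 183 days); `NULL` skips it.
#' @param ties Passed to [cox_fit()].
#' @return List: `grid` (data.frame with `min_duration`, `n_treated`,
#'   `hr`, `lo95`, `hi95`, `p`, `stable`) and `contrast` (a `SurvivalFit`
#'   of long vs short among treated, or `NULL`).
#' @export
duration_sensitivity <- function(cohort, rx_durations, min_duration_grid,
                                 covariate_names = "exposure",
                                 min_followup = 720, long_term_days = 183,
                                 ties = "efron") {
  dur <- if (is.character(rx_durations) && length(rx_durations) == 1L)
    stats::setNames(cohort[[rx_durations]], cohort$subject_id)
  else rx_durations
  dur <- dur[cohort$subject_id]
  treated <- cohort$exposure == "treatment"
  rows <- lapply(min_duration_grid, function(th) {
    keep <- !treated | (!is.na(dur) & dur >= th)
    nt <- sum(treated & keep)
    fit <- if (nt >= 5L)
      tryCatch(cox_fit(cohort[keep, ], covariate_names, ties = ties),
               error = function(e) NULL)
    else NULL
    if (is.null(fit))
      return(data.frame(min_duration = th, n_treated = nt, hr = NA_real_,
                        lo95 = NA_real_, hi95 = NA_real_, p = NA_real_,
                        stable = FALSE))
    data.frame(min_duration = th, n_treated = nt,
               hr = fit$hr[["exposure"]],
               lo95 = fit$ci95["exposure", "lo"],
               hi95 = fit$ci95["exposure", "hi"],
               p = fit$p[["exposure"]], stable = TRUE)
  })
  contrast <- NULL
  if (!is.null(min_followup)) {
    sub <- cohort[treated & cohort$time_days >= min_followup, , drop = FALSE]
    dsub <- dur[sub$subject_id]
    if (nrow(sub) >= 10L && sum(sub$event) >= 1L) {
      sub$long_term <- as.integer(dsub >= long_term_days)
      if (stats::var(sub$long_term) > 0 &&
          sum(sub$event) >= 2L)
        contrast <- tryCatch(cox_fit(sub, "long_term", ties = ties),
                             error = function(e) NULL)
    }
  }
  list(grid = do.call(rbind, rows), contrast = contrast)
}

#' Negative-control outcome analysis
#'
#' Refits the Cox model with an alternative (control) outcome believed to
#' be unaffected by treatment. A treatment hazard ratio away from 1 on the
#' control outcome flags residual confounding such as healthy-user bias.
#'
#' @param cohort A `CohortTable` carrying control-outcome columns.
#' @param covariate_names Covariates for the refit.
#' @param time_col,event_col Columns holding the control outcome's
#'   follow-up and event indicator.
#' @param ties Passed to [cox_fit()].
#' @return A `SurvivalFit` on the control outcome.
#' @export
negative_control <- function(cohort, covariate_names = "exposure",
                             time_col = "control_time_days",
                             event_col = "control_event",
                             ties = "efron") {
  cox_fit(cohort, covariate_names, ties = ties,
          time_col = time_col, event_col = event_col)
}
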