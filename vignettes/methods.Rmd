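---
title: "Methods: multi-cohort signatures, reversal ranking, and target-trial validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort signatures, reversal ranking, and target-trial validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models behind `drugrepos`, the
choices made where the design was genuinely open, and what the synthetic
generators do and do not emulate.

## Disease-signature discovery

For each gene in each cohort, the disease effect is the standardized mean
difference between cases and controls on the pooled standard deviation,
with Hedges' small-sample correction $J = 1 - 3/(4\,df - 1)$,
$df = n_1 + n_2 - 2$, and sampling variance
$v = (n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2))$. Per-study effects are
combined by inverse-variance weighting. The default pooling model is
DerSimonian–Laird random effects: Cochran's
$Q = \sum w_i (g_i - \bar g_F)^2$ gives the method-of-moments
$\hat\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum
w_i)\big)$ and the summary effect re-pools with weights
$1/(v_i + \hat\tau^2)$. Random effects is the default because the
pipeline's own power analysis reasons over between-study heterogeneity
levels; a fixed-effect model is available (`model = "fixed"`), and every
result table records which was used. The per-gene p-value is the
two-sided normal tail of $z = \hat\mu/\widehat{SE}$; genes are corrected
across the universe by Benjamini–Hochberg.

Alongside the effect-size branch, one-sided p-values per direction are
combined across studies by Fisher's method ($-2\sum\ln p_i \sim
\chi^2_{2k}$). The within-study statistic for this branch is the
pooled-variance two-sample t (the natural companion of the pooled-SD
effect size). These combined p-values are reported but not used for
selection: selection is anchored to the FDR on the effect-size analysis,
which is the quantity the robustness filter also sees.

**Leave-one-dataset-out (LODO).** A gene enters the signature only if its
FDR stays below the threshold and its summary-effect sign is unchanged in
the full analysis and in all $k$ reruns with one cohort removed. This is
deliberately conservative: it removes genes whose significance is driven
by a single cohort.

**Gene universe.** By default a gene must be measured in every cohort
(`min_fraction = 1`); pooling over the subset of cohorts that measure a
gene is opt-in. With partially overlapping platforms the strict default
trades coverage for comparability, which is the safer default when
nothing is known about why a gene is absent from a platform.

**Defaults.** FDR threshold 0.01, no absolute effect-size floor
(`abs_es = 0`); both are exposed because the appropriate effect-size floor
depends on the heterogeneity actually observed, and the drug-ranking
stage has a sensitivity grid precisely to show the downstream conclusions
do not hinge on these two knobs.

**Degenerate inputs.** A gene with zero pooled SD in some cohort is pooled
over the remaining cohorts (`n_studies` records how many); genes usable in
fewer than two cohorts are dropped. Signature ordering breaks ties by
gene symbol after decreasing $|ES|$, so output is deterministic.

**Signature scoring.** A sample's score is the geometric mean of its
up-gene values minus the geometric mean of its down-gene values, computed
after shifting the dataset minimum to 1 so logs are defined, then
z-scored within the dataset. Degenerate (zero-variance) scores are
defined as all-zero with a warning rather than an error, since held-out
scoring of a tiny panel can legitimately collapse.

## Power analysis

Power for detecting a summary effect $\delta$ at two-sided level $\alpha$
uses the Hedges & Pigott approach: with per-study variances $v_i$
evaluated at $\delta$ and $\bar v$ their mean, heterogeneity levels
none/low/moderate/high map to $\tau^2 = c\,\bar v$ with $c = 0, 1/3, 2/3,
1$; the summary variance is $V = 1/\sum (v_i+\tau^2)^{-1}$, the
noncentrality $\lambda = \delta/\sqrt V$, and
$\text{power} = 1 - \Phi(z_{1-\alpha/2} - \lambda) + \Phi(-z_{1-\alpha/2}
- \lambda)$. The $c$ convention is the standard one; an explicit
$\tau^2$ override exists because published analyses do not always state
their $c$. With the packaged 11-cohort sizes the design has 99.15% power
for $\delta = 0.66$ at $\alpha = 0.01$ under homogeneity, and >99.99% for
$\delta = 1.41$ at $\tau^2 = \bar v$ — the suite cross-checks the
zero-heterogeneity value against a 5000-replicate simulation that draws
raw two-group data, estimates $g$ and $v$, and pools.

## Pathway overrepresentation

Enrichment of the signature (up and down genes jointly, since directional
testing is a separate question) in a gene set is the one-sided
hypergeometric upper tail on the 2×2 table restricted to the measured
universe. Using the measured universe rather than the whole genome avoids
the classic inflation when the background contains genes that could never
have been selected. Sets with fewer than 5 in-universe genes are removed
*before* testing so the BH correction runs over exactly the tested sets.
Odds ratios use a Haldane 0.5 correction only when a cell is zero.

## Signature-reversal drug ranking

Each drug profile is correlated (Pearson) with the signature's summary
effect sizes over the genes present in both, restricted by default to the
compendium's reliable-gene ("gold") mask; p-values come from the t
transform with $n-2$ df and are BH-corrected across drugs. Rank 1 is the
most negative $r$: the hypothesis is that a drug whose transcriptional
response opposes the disease signature may revert the disease state. A
profile constant across the shared genes has no defined correlation and
is flagged and excluded from ranking rather than erroring the run.
Requiring at least 3 shared genes is a hard error because a correlation
on fewer is meaningless.

The sensitivity grid reselects the signature over an FDR grid (default
1–20%) crossed with an absolute effect-size grid (default 0.6–1.2),
re-ranks, and summarizes stability as the mean pairwise Jaccard
similarity of the per-cell top-10 *sets* (membership, not order; a single
evaluable cell has stability 1 by convention; cells whose signature has
fewer than 3 genes are excluded). The grid is applied to $|g|$ — the
summary effect is a standardized mean difference, and the grid bounds are
interpreted on that scale.

## Target-trial emulation

`build_cohort` encodes a new-user active-comparator design: subjects need
a qualifying diagnosis, no exclusion diagnosis, and a qualifying
prescription strictly after first diagnosis; the index date is the first
qualifying prescription, so person-time before initiation is never
attributed to either arm (no immortal time). Subjects on both exposure
and comparator drugs go to the treatment arm with index at the first
exposure prescription — intention-to-treat at initiation; the attrition
report counts every exclusion rule. Follow-up ends at the first outcome
code or censoring at the last recorded event. Outcomes on or before index
exclude the subject (time must be positive). Code matching is by prefix,
which covers ICD-9/10 family codes ("153.x") without a code-hierarchy
dependency.

**Cox fitting.** The partial likelihood with the Efron tie correction
(the default, because claims dates are heavily tied; Breslow is available
for cross-checks) is maximized by Newton–Raphson with the analytic score
and observed information, from $\beta = 0$, with step-halving if a step
decreases the likelihood. Convergence: maximum absolute score below 1e-9,
or the log-likelihood improvement falling below 1e-10 relative — on
cohorts with thousands of events the score plateaus near float
resolution (~1e-7) at the optimum, so the likelihood criterion is the one
that certifies convergence there; 25 iterations is a hard cap with an
error. Coefficients beyond |15| are treated as monotone-likelihood
(separation) failures. Standard errors come from the inverse observed
information; CIs and p-values are Wald.

**PH diagnostics.** The score test for $\beta(t) = \beta + \theta g(t)$
uses per-event-time Schoenfeld residuals and the efficient information
for $\theta$ (accounting for the main-effect block), with the
left-continuous Kaplan–Meier transform $g(t) = 1 - \hat S(t^-)$ by
default. This reproduces `survival::cox.zph` to numerical precision on
shared examples and is calibrated (uniform p under PH-true simulation) in
the suite.

**Propensity matching.** The propensity model is L1-penalized logistic
regression (5-fold cross-validated penalty); matching is greedy 1:1
nearest-neighbor without replacement on the logit, processing treated
subjects in descending propensity so the hardest-to-match are matched
first. A caliper of 0 is read as "no caliper" (the convention of the
matching tools this mirrors); a positive caliper is honored. The balance
report gives standardized mean differences before/after.

**Sensitivity and bias checks.** The duration analysis restricts the
treated arm to increasing minimum prescription durations (comparator
untouched) and refits; grid points with fewer than 5 treated subjects, or
whose refit fails, are marked unstable rather than erroring the grid. The
short/long-term contrast compares treated subjects followed at least 720
days with under vs at least ~6 months (183 days) on therapy. The
negative-control analysis refits against an outcome the treatment should
not affect: an interval excluding 1 there flags residual confounding of
the healthy-user type.

## Synthetic generators: what they emulate, and what they do not

The expression generator plants differential expression on the Hedges-g
scale directly: unit within-group variance makes the planted mean shift
$\delta$ interpretable as the true $g$. Between-study heterogeneity is
injected on the true effects ($\delta_{ij} \sim N(\pm\mu, \tau^2)$), the
random-effects generating model. The study-scale default is 11 cohorts
with the packaged per-study sizes, 10000 genes, 500 planted at mean
$|g| = 1$, and $\tau^2 = 0.05$ — low heterogeneity, chosen once because
robust signature genes in this setting empirically show low
between-study heterogeneity; the recovery checks measure against the full
planted truth, so the default panel has no dropout (dropout is exercised
separately). The generator does **not** emulate probe-level noise,
cross-hybridization, batch effects, or correlated co-expression — passing
recovery tests show the statistics behave as designed, not that real
microarray data are this clean.

The compendium generator plants one perfect reverser ($-$signature plus
noise) and one mimic among i.i.d. null drugs, with a gene-level gold mask
covering 60% of genes. Real perturbation compendia have correlated drug
classes and cell-context structure that this does not model; per-context
averaging is therefore out of scope of the generator even though the
ranking operates on whatever profiles it is given.

The survival generator draws exponential event times with hazard
$h_0 e^{\log(HR)\cdot A + x^\top\gamma}$ — proportional hazards hold by
construction — with logistic exposure assignment whose intercept is
solved numerically so the marginal exposure rate matches the target, and
independent exponential censoring tuned the same way. Healthy-user-type
confounding is a knob: the same covariates can be given effects on both
exposure and hazard (for both the primary and the control outcome).
Prescription duration is drawn independently of outcome (a prescription
length, not observed persistence), which is what makes the
duration-threshold grid a clean null. The generator emits the analysis
table directly; code-level event-stream extraction is exercised on a
hand-written fixture instead. It does not model time-varying hazards,
competing risks, or informative censoring.

All generators are bit-reproducible from (configuration, seed); the run
seed fans out to per-component child seeds by fixed offsets (cohort $i$
uses seed $+ 1000i$), so regenerating one component does not disturb the
others.

## Problem sizes in the test suite

The suite verifies each primitive against an independent oracle on small
instances (metafor for DerSimonian–Laird, `survival` for KM/Cox/PH, exact
enumeration for the hypergeometric, a hand-written step-up for BH, a
written-out partial likelihood for the Cox toy) and runs the
recovery/calibration checks at: 10 seeds of the 11-cohort study-scale
simulation (10000 genes) for signature recovery with LODO; 100 seeded
781-drug compendia for reverser ranking; a 5000-subject cohort for
hazard-ratio recovery; 50 all-null simulations for FDR calibration; and
200 replicates for PH-test uniformity. These sizes give stable pass/fail
behaviour at the stated thresholds while keeping a full run around two
minutes.

## Known limitations

- The meta-analysis assumes approximately normal per-study effect
  estimates; very small cohorts (fewer than ~5 per arm) make the z-based
  p-values only approximate (the type-I calibration check runs at the
  packaged cohort sizes, whose smallest arm is 5).
- The Fisher-combination branch assumes independent cohorts; shared
  controls across datasets would violate it.
- No moderated (limma-style) within-study variance shrinkage, gene-level
  covariate adjustment, or meta-regression.
- Drug ranking treats profiles as given; cell-context collapsing and
  KS-based connectivity scores are out of scope.
- The Cox implementation handles right censoring only — no delayed entry,
  time-varying covariates, stratification, or Firth penalty (separation
  is an error by design).
- ICD matching is prefix-based; no hierarchy expansion.
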