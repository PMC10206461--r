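---
title: "Methods: spatial personality traits from aviary zone tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial personality traits from aviary zone tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, the synthetic
flock generator, and the design and numerical choices behind
`aviarytraits`. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## 1. From transition streams to daily behaviours

The raw unit is a zone-transition record: hen, timestamp, new zone. Zones
are the littered floor (level 0), lower tier (1), nestbox tier (2), top
tier (3) and the winter garden (WG, no vertical level). Records are turned
into half-open occupancy intervals `[start, end)` that tile each hen's
tracked span; a transition timestamp belongs to the new zone.

Conventions the data format does not fix, and how we fixed them:

* **The behavioural day** runs 00:00-24:00 local clock time. The night is
  attributed to the day on which it starts (lights-off 17:00 on day *d*
  through lights-on 02:00 on day *d*+1), so a single night belongs to
  exactly one day.
* **Tracked hen-day**: intervals must cover at least 95% of the 24-h day,
  otherwise all of the day's behaviours are missing. Tracking systems drop
  out for whole days far more often than for minutes, so the exact
  threshold is uncritical; 95% guards against partially covered days
  corrupting per-hour rates. Within a tracked day, individual behaviours
  can still be missing (no nestbox use; untracked night) and are never
  imputed.
* **Dawn**: the schedule defines a 15-min dusk before lights-off; no dawn
  length is inherent to the husbandry, so the eligible window for the
  movement behaviour symmetrically excludes a configurable 15 min after
  lights-on.
* Timestamps are timezone-naive local clock time; the schedule is
  clock-based, so daylight-saving is ignored in synthetic data.

Behaviour definitions worth spelling out:

* **Vertical travelled distance** counts `|level(to) - level(from)|` per
  indoor-to-indoor transition inside the eligible window (lights-on minus
  dawn and dusk), divided by eligible hours (WG time removed from the
  denominator; WG-involving transitions contribute nothing, as the WG is
  off the vertical axis). A direct floor-to-top move therefore counts 3
  crossed zones — the zones are physically stacked, and "zones crossed"
  is the natural distance on that axis.
* **Nestbox tier timing** inverts the cumulative nestbox occupancy step
  function over 02:00-08:00 at half its total; it lies in (2, 8] and is
  kept as clock hours since midnight so the response is strictly positive,
  as the gamma family downstream requires.
* **Sleeping tier** demands a strict majority (> 50%) of the night on the
  top tier; a plurality rule would blur the behaviour's meaning on nights
  split three ways. The night excludes the preceding dusk phase.
* **Feed delivery response**: per delivery `p` (3 min), the feed-tier time
  `T_p` is contrasted with `T_pr` from comparison windows of the same
  length drawn uniformly from the eligible start set: fully inside `p`
  +/- 1 h, not intersecting `p` expanded by a 15-min buffer, not
  intersecting any other delivery. The per-window term
  `(T_p - T_pr)/(T_p + T_pr)` is defined as 0 when both times are zero (a
  hen absent from feed tiers in both windows carries no information about
  a preference). Fifty windows are drawn per delivery; draws may overlap
  one another (they are i.i.d. samples of the nearby baseline, not a
  partition). `exhaustive = TRUE` replaces the draws with every eligible
  start on a 1-s grid; this is the oracle the estimator is tested
  against. Each hen-day uses its own deterministic draw stream derived
  from the configured seed, the hen id and the date, so single hen-days
  can be recomputed bit-identically in isolation.

## 2. The analysis sets

Four contexts of three days each: EARLY/LATE are the Saturdays of the
first/last three weeks of the span; COLD days are the first day of each of
the first three runs of days whose mean hourly external temperature stays
negative throughout the WG-open hours (first days limit habituation);
VACCINATION days are given by the husbandry calendar. A day fitting more
than one context is excluded from all. Saturdays fitting no context form
the over-time series (one day a week limits day-to-day autocorrelation).

For the across-context analysis each hen contributes one observation per
context. Which of the three days is "most representative" is a judgement
call; our default is the middle day, falling back to the hen's nearest
tracked context day (ties to the earlier day), and the day used is
recorded per hen. Both the preference and the fallback are configurable.

Keel-bone-fracture severity and body mass are assessed five times; daily
values are linearly interpolated through a monotone nondecreasing envelope
(decreasing segments flattened to the running maximum, constant outside
the assessed range). Severity scores cannot heal downward on the scale
used, so the envelope reflects the measurement process; the exact
monotonisation matters little because assessments rarely decrease.

## 3. Adjusted repeatability

Each behaviour is fitted separately with a hen random intercept:
Gaussian for `vtd` and `fdr`, logit-Bernoulli for `wg` and `sleep_top`,
log-Gamma for `nest_timing`. Fixed effects (KBF severity, body mass,
class, treatment, days in barn, and feed-chain identity for `fdr` only)
absorb consistent external/internal differences that would otherwise
inflate repeatability (pseudo-repeatability); continuous covariates are
z-scored. Class is dropped from the `wg` models, mirroring the
convergence-driven removal in the original analysis; a pen random effect
is excluded by default (the original analysis removed it after an AIC
comparison, and we mirror the outcome as a configuration default rather
than re-deriving the selection).

Latent-scale decomposition: `R = Va / (Va + Vw)` with

* Gaussian: `Vw` the residual variance;
* Bernoulli-logit: `Vw = pi^2 / 3` (the logistic link variance);
* Gamma-log: `Vw = trigamma(shape)` with the shape estimated jointly by
  maximum likelihood (`glmmTMB`; the shape is `1/sigma(fit)^2`).

Confidence intervals are parametric bootstrap (default 1000 replicates):
simulate responses from the fitted model, refit, take 2.5/97.5
percentiles. The Gaussian family uses an internal exact REML profiler for
the one-random-intercept model — the REML criterion is profiled over
`lambda = Va/Vr` using per-group sufficient statistics, so a bootstrap
refit costs microseconds rather than a full `lmer` pass. It is not an
approximation: the test suite checks agreement with `lme4::lmer` to 1e-6
on unbalanced data and with the closed-form one-way ANOVA
method-of-moments estimator on balanced data. When the profile optimum
hits the lower boundary the fit reports `R = 0` with a `boundary` flag.
Binary models use `lme4::glmer` (bobyqa, Nelder-Mead fallback); gamma
models `glmmTMB` (BFGS retry when the Hessian is not positive definite).

## 4. The multivariate syndrome model

All five behaviours enter one Bayesian model: per response the same fixed
effects as above, and per hen a 5-dimensional random intercept
`u_i ~ MVN(0, Sigma)` with unstructured `Sigma`. Likelihoods keep the
univariate families. The two Gaussian responses are z-scored, the gamma
response is scaled to unit SD without centring (the log link needs
positivity), binaries enter as 0/1. The model is expressed in JAGS; the
prior on the among-individual precision is Wishart(identity, df = 6),
i.e. near-uniform marginal correlations — our reading of "uninformative"
for a covariance matrix of this size. Residual correlations between
responses are not modelled: the scientific quantity is the
among-individual correlation, and leaving observation-level correlation
unstructured keeps the likelihoods of the mixed families tractable. This
is a documented limitation: environment-driven within-day correlations do
not enter the syndrome estimates.

Desk-scale MCMC defaults: 3 chains, 1000 adaptation, 2000 burn-in, 6000
sampling iterations thinned by 4 (~4500 retained draws), roughly five
minutes for 200 hens with 4 observations each on one CPU. JAGS's `glm`
module is loaded: its block samplers for the logit likelihoods cut chain
autocorrelation several-fold, which is what makes desk-scale runs
converge.
`paper_scale = TRUE` switches to 4 chains of 300k iterations with 200k
burn-in and thinning 50 for overnight runs; the posterior summaries, not
the chain length, are the contract.

Convergence is judged on the reported quantities: every among-individual
correlation must have split-chain Gelman-Rubin statistic < 1.05, plus
Geweke z-scores as a secondary check. Variance elements of `Sigma` under
the binary likelihoods mix more slowly and may sit slightly above that
threshold at desk scale without moving the correlations. A run failing
the threshold is extended once; failing again, the fit errors with the
diagnostics attached rather than returning a doubtful posterior.

A pair is "significant" when its 95% credible interval excludes zero
after rounding to three decimals — rounding keeps intervals whose
boundary is numerically indistinguishable from zero from being
over-interpreted.

## 5. Eigen axes and behavioural profiles

Per posterior draw, the correlation submatrix of the four syndrome
behaviours (`nest_timing`, uncorrelated by design of the analysis, is
left out) is eigendecomposed; using the correlation rather than the
covariance matrix gives each behaviour equal weight despite their
different scales. Eigenvector signs are arbitrary per draw, so each
component is aligned to a nonnegative `vtd` loading before averaging —
any fixed reference trait works; `vtd` is the behaviour with the
strongest correlations in practice. Components with mean eigenvalue > 1
are retained; loading SDs across draws quantify axis uncertainty;
variance explained is eigenvalue over the number of traits.

Hen-days are scored on the first component by standardising the four
observed behaviours with the model's scaling parameters — binaries as 0/1
z-scored by their observed mean/SD; whether to standardise binaries before
projection is genuinely open, and we chose z-scoring so that no behaviour
dominates the score by units alone — and projecting onto the mean
loadings. Per-hen mean scores define the 15% extremes, from which a seeded
sample of three hens per side is reported with mean observed
(unstandardised) behaviours, including nest timing for display.

## 6. The synthetic flock

Two generators, two purposes.

**Behaviour-level** (`simulate_behaviour_table`): hen types
`u_i ~ MVN(0, sigma_A)`, linear predictors `mu_k + x' beta_k + u_ik`, and
family-appropriate noise (Gaussian residual variance; Bernoulli-logit;
Gamma with log-link mean and fixed shape). It returns the exact types,
variance components and true latent repeatabilities, making estimator
recovery checkable. Defaults are chosen once to resemble a commercial
flock: 194 hens, 242 days, latent-scale repeatabilities of about 0.67
(vtd), 0.38 (fdr), 0.52 (nest timing), 0.40 (WG), 0.50 (sleeping tier),
an among-individual correlation structure with a positively correlated
movement/outdoor/feeding cluster (0.5, 0.47, 0.27), weak negative
correlations of those with the sleeping tier (-0.23, -0.21), and a nesting
behaviour uncorrelated with the rest; small nonzero covariate effects so
that adjusted repeatability genuinely differs from the raw ICC; 5% of
hen-days lost to tracking failure. KBF/mass trajectories are nondecreasing
across the five assessment ages with noise at assessment points only.
An optional AR(1) drift of the types (`type_ar1 < 1`) makes among-
individual variance decay over long gaps, for studying the effect of
observation spacing. Residuals of the two continuous behaviours are
Gaussian — the distributional form their downstream models assume; the
generator does not emulate heavy-tailed tracking artefacts.

**Trajectory-level** (`simulate_transitions`): builds minute-grid
itineraries realizing targeted behaviour values — night roost per
`sleep_top`, a nestbox residence whose half-time equals the target (60-s
grid), an 11:00-11:30 WG excursion, floor/lower-tier visits scheduled so
eligible-window crossings match `vtd` (crossings come in pairs, so an odd
remainder is realized by one late unpaired visit lasting into dusk), and
full feed-tier occupancy of a delivery window with probability
`attraction`. Moves between day baseline and night roost happen inside
dawn/dusk, which the movement behaviour excludes by definition.
Infeasible targets are realized as closely as possible and reported.
The round trip extract(simulate(targets)) is exact for the binaries,
within 60 s for nest timing and within one crossing per eligible window
for `vtd` (in practice within half a crossing: rounding to a feasible
crossing count is the only error source left). The feed response has no
exact trajectory realisation — `attraction` maps a positive tendency onto
the stream, and only direction is asserted. Nest-timing targets must lie
in the realizable (2, 8] window; `behaviour_targets` clips the gamma
draws to [2.05, 7.95].

What passing these tests shows — and does not. They validate the
estimators under the generating model's assumptions (correct families,
exchangeable residuals, schedule-faithful itineraries). They cannot
certify behaviour on real tracking data with zone-inference errors,
device dropouts within days, or non-Gaussian residuals; those enter
through the raw-record quality checks, not the statistics.

## 7. Problem sizes and numerical choices

* The acceptance-style checks in `tests/testthat/test-acceptance.R` run
  at the sizes the recovery claims refer to (200 hens; 30 days for
  univariate recovery, 4 observations for the multivariate model; 100
  replicates with 200 bootstrap draws for coverage). The multivariate
  known-truth *property* check in `test-syndromes.R` runs at 70 hens with
  shortened chains — the full-size recovery lives in the acceptance
  suite, and posterior means stabilise far earlier than strict
  convergence thresholds.
* The 50-draw feed-response estimator is compared with the exhaustive
  oracle as a mean absolute difference over 100 synthetic hen-days
  (< 0.05, with a 0.15 cap on any single day): the estimator is itself a
  50-sample Monte Carlo average, so per-day agreement is statistical, not
  exact.
* REML profiling searches `log lambda` in [-16, 16] (`optimize`,
  tolerance 1e-10); a Cholesky failure of the fixed-effects normal
  equations marks the candidate infeasible. Boundary fits are reported as
  `R = 0` with a flag, not as a small positive artefact.
* Ties in the across-context fallback go to the earlier day;
  equal-distance comparison windows are all eligible (no deduplication).
* All randomness flows through named streams derived from one seed
  (hen/date for window draws; purpose-tagged streams for types,
  responses, bootstrap, chains), so every artefact is reproducible in
  isolation.
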