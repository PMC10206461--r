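# Latent-scale adjusted repeatability: estimator cross-checks, the
# adjustment itself, boundary handling and the grid.

test_that("the Gaussian REML core agrees with lme4::lmer on unbalanced data", {
  set.seed(21)
  n_h <- 60; n_o <- 8
  u <- rnorm(n_h, 0, sqrt(1.5))
  d <- data.frame(hen_id = rep(sprintf("h%02d", 1:n_h), each = n_o),
                  days_in_barn = rnorm(n_h * n_o))
  d$vtd <- 2 + 0.4 * d$days_in_barn + u[rep(1:n_h, each = n_o)] +
    rnorm(nrow(d), 0, 1)
  d <- d[-sample(nrow(d), 100), ]
  r <- fit_adjusted_repeatability(
    d, model_spec("vtd", "gaussian", "days_in_barn"), n_boot = 0)
  m <- lme4::lmer(vtd ~ scale(days_in_barn) + (1 | hen_id), data = d,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(r$v_among, vc$vcov[1], tolerance = 1e-6)
  expect_equal(r$v_within, vc$vcov[2], tolerance = 1e-6)
  expect_equal(r$R, vc$vcov[1] / sum(vc$vcov), tolerance = 1e-6)
})

test_that("on balanced data the Gaussian estimator matches the one-way
           ANOVA method of moments", {
  set.seed(22)
  n_h <- 50; n_o <- 10
  g <- rep(1:n_h, each = n_o)
  y <- rnorm(n_h, 0, 1.2)[g] + rnorm(n_h * n_o, 0, 0.8)
  d <- data.frame(hen_id = sprintf("h%02d", g), vtd = y)
  r <- fit_adjusted_repeatability(d, model_spec("vtd", "gaussian"), n_boot = 0)
  gm <- tapply(y, g, mean)
  msb <- n_o * sum((gm - mean(y))^2) / (n_h - 1)
  msw <- sum((y - gm[g])^2) / (n_h * (n_o - 1))
  va_mom <- (msb - msw) / n_o
  expect_equal(r$v_among, va_mom, tolerance = 1e-6)
  expect_equal(r$v_within, msw, tolerance = 1e-6)
})

test_that("adjusting for a strong known fixed effect removes
           pseudo-repeatability", {
  beta <- default_beta()
  beta$vtd["days_in_barn"] <- 1.5    # strong shared time trend
  cfg <- tiny_flock(n_hens = 120, n_days = 20, seed = 31,
                    sigma_A = diag_sigma(vtd = 2),
                    resid_var = c(vtd = 1, fdr = 0.025), beta = beta)
  b <- simulate_behaviour_table(cfg)$behaviours
  adj <- fit_adjusted_repeatability(
    b, model_spec("vtd", "gaussian", c("days_in_barn", "kbf", "mass")),
    n_boot = 0)
  raw <- fit_adjusted_repeatability(b, model_spec("vtd", "gaussian"),
                                    n_boot = 0)
  expect_lt(abs(adj$R - 2 / 3), 0.06)
  # the unadjusted fit absorbs the trend into the residual: R drops
  expect_lt(raw$R, adj$R - 0.05)
})

test_that("zero among-individual variance is reported as a boundary fit", {
  # group means forced identical: the among-individual variance profile
  # has its optimum at the boundary
  set.seed(41)
  d <- data.frame(hen_id = rep(sprintf("h%02d", 1:40), each = 8))
  d$vtd <- ave(rnorm(nrow(d)), d$hen_id, FUN = function(x) x - mean(x))
  r <- fit_adjusted_repeatability(d, model_spec("vtd", "gaussian"),
                                  n_boot = 50, seed = 2)
  expect_identical(r$R, 0)
  expect_true(r$boundary)
  expect_true(r$ci95[1] <= r$ci95[2])
  # a flock with no latent individual differences: adjusted repeatability
  # of every behaviour stays near zero
  cfg <- tiny_flock(n_hens = 60, n_days = 10, seed = 41,
                    sigma_A = matrix(0, 5, 5))
  b <- simulate_behaviour_table(cfg)$behaviours
  spec <- model_spec("vtd", "gaussian", c("days_in_barn", "kbf", "mass"))
  expect_lt(fit_adjusted_repeatability(b, spec, n_boot = 0)$R, 0.1)
})

test_that("latent-scale decomposition uses the exact link-variance constants
           and the identity R = Va/(Va+Vw)", {
  cfg <- tiny_flock(n_hens = 50, n_days = 8, seed = 51, nest_shape = 6)
  b <- simulate_behaviour_table(cfg)$behaviours
  rb <- fit_adjusted_repeatability(
    b, model_spec("wg", "bernoulli_logit", "days_in_barn"), n_boot = 0)
  expect_identical(rb$v_within, pi^2 / 3)
  expect_equal(rb$R, rb$v_among / (rb$v_among + rb$v_within),
               tolerance = 1e-10)
  rg <- fit_adjusted_repeatability(
    b, model_spec("nest_timing", "gamma_log", "days_in_barn"), n_boot = 0)
  # Vw must be trigamma of the fitted shape, i.e. in trigamma's range for a
  # plausible shape, and satisfy the ratio identity
  expect_equal(rg$R, rg$v_among / (rg$v_among + rg$v_within),
               tolerance = 1e-10)
  shape <- 1
  expect_equal(trigamma(shape), pi^2 / 6)   # the gamma link-variance anchor
})

test_that("parametric-bootstrap intervals bracket the estimate", {
  cfg <- tiny_flock(n_hens = 60, n_days = 10, seed = 61,
                    sigma_A = diag_sigma(vtd = 1),
                    resid_var = c(vtd = 1, fdr = 0.025))
  b <- simulate_behaviour_table(cfg)$behaviours
  r <- fit_adjusted_repeatability(b, model_spec("vtd", "gaussian"),
                                  n_boot = 200, seed = 3)
  expect_true(r$ci95[1] < r$R && r$R < r$ci95[2])
  expect_lt(r$ci95[2] - r$ci95[1], 0.35)
})

test_that("types drifting over days lower the among-individual variance
           recovered from widely spaced observations", {
  cfg <- flock_config(n_hens = 120, n_days = 60, seed = 71,
                      prob_missing = 0, type_ar1 = 0.95,
                      sigma_A = diag_sigma(vtd = 2),
                      resid_var = c(vtd = 1, fdr = 0.025))
  b <- simulate_behaviour_table(cfg)$behaviours
  near <- b[b$date <= cfg$start_date + 4, ]
  far <- b[b$date %in% (cfg$start_date + c(0, 15, 30, 45, 59)), ]
  spec <- model_spec("vtd", "gaussian", "days_in_barn")
  va_near <- fit_adjusted_repeatability(near, spec, n_boot = 0)$v_among
  va_far <- fit_adjusted_repeatability(far, spec, n_boot = 0)$v_among
  expect_lt(va_far, va_near)
})

test_that("the repeatability grid covers behaviours x analysis sets", {
  cfg <- flock_config(n_hens = 60, n_days = 77, seed = 81,
                      prob_missing = 0.03)
  sim <- simulate_behaviour_table(cfg)
  ctx <- select_context_days(sim$calendar$dates, sim$calendar$temperature,
                             sim$calendar$vaccination_dates)
  sets <- make_analysis_sets(sim$behaviours, ctx)
  grid <- repeatability_matrix(sets, n_boot = 0, seed = 1)
  expect_equal(nrow(grid), 30L)
  expect_length(attr(grid, "skipped"), 0L)
  expect_true(all(grid$R >= 0 & grid$R <= 1))
  expect_true(all(grid$v_among >= 0))
  # day-gap bookkeeping: across-context gaps exceed within-context gaps
  gap_ctx <- grid$mean_day_gap[grid$analysis_set == "early"][1]
  gap_acr <- grid$mean_day_gap[grid$analysis_set == "across_contexts"][1]
  expect_gt(gap_acr, gap_ctx)
})
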