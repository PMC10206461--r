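# Multivariate syndrome model, eigen axes, profile projection.
#
# MCMC here runs at reduced size (60-80 hens, short chains) so the whole
# file stays within a few minutes; full-size recovery is exercised by the
# acceptance suite.

short_mcmc <- function(seed = 1, rhat_max = 1.5)
  multivariate_spec(chains = 2L, adapt = 800L, burn = 1200L, iter = 3200L,
                    thin = 4L, rhat_max = rhat_max, seed = seed)

syndrome_fixture <- function(n_hens = 70, seed = 5, r_vtd_fdr = 0.6) {
  sig <- diag(5)
  sig[1, 2] <- sig[2, 1] <- r_vtd_fdr
  cfg <- tiny_flock(n_hens = n_hens, n_days = 4, seed = seed,
                    sigma_A = sig, resid_var = c(vtd = 1, fdr = 1),
                    nest_shape = 4)
  simulate_behaviour_table(cfg)
}

test_that("posterior draws are valid correlation matrices and recover a
           strong among-individual correlation", {
  sim <- syndrome_fixture()
  fit <- fit_multivariate(sim$behaviours, short_mcmc(seed = 2))
  D <- dim(fit$corr_draws)[1]
  take <- round(seq(1, D, length.out = 50))
  for (i in take) {
    m <- fit$corr_draws[i, , ]
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(1, 5), tolerance = 1e-12)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_equal(sum(ev), 5, tolerance = 1e-8)   # trace conservation
  }
  r12 <- fit$pair_summary[fit$pair_summary$trait_i == "vtd" &
                            fit$pair_summary$trait_j == "fdr", ]
  expect_gt(r12$mean, 0.3)
  expect_true(r12$significant)
  expect_equal(dim(fit$behavioural_types), c(fit$n_hens, 5L))
  # types should track the simulated ones for the well-identified trait
  ord <- rownames(fit$behavioural_types)
  henn <- as.integer(sub("hen", "", ord))
  expect_gt(cor(fit$behavioural_types[, "vtd"], sim$truth$u[henn, "vtd"]), 0.6)
})

test_that("permuting hen labels of one response destroys its among-individual
           correlations", {
  sim <- syndrome_fixture(seed = 6)
  b <- sim$behaviours
  perm <- b
  set.seed(9)
  # shuffle vtd across hens within each day: day-level structure survives,
  # hen-level (among-individual) structure is destroyed
  perm$vtd <- ave(b$vtd, b$date, FUN = sample)
  # posterior means are all this check needs: chain precision can be loose
  fit <- fit_multivariate(perm, short_mcmc(seed = 3))
  r12 <- fit$pair_summary[fit$pair_summary$trait_i == "vtd" &
                            fit$pair_summary$trait_j == "fdr", ]
  # permuted vtd has almost no among-individual variance left, so its
  # correlations are weakly identified: the mean shrinks well below the
  # generating 0.6 and the credible interval must cover zero
  expect_lt(abs(r12$mean), 0.35)
  expect_false(r12$significant)
})

test_that("eigen axes have closed-form behaviour on reference matrices", {
  tr4 <- c("vtd", "fdr", "wg", "sleep_top")
  # identity: all eigenvalues 1, nothing retained under the strict rule
  ax <- eigen_axes(diag(4), traits = tr4)
  expect_equal(ax$eigenvalues, rep(1, 4))
  expect_false(any(ax$retained))
  # equicorrelation 0.5: top eigenvalue 1 + 3 rho, equal loadings 1/2
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  ax <- eigen_axes(m, traits = tr4)
  expect_equal(ax$eigenvalues[1], 2.5)
  expect_equal(ax$var_explained[1], 0.625)
  expect_equal(unname(ax$loadings[, 1]), rep(0.5, 4))
  expect_equal(sum(ax$retained), 1L)
  # sign alignment: the vtd loading is nonnegative
  m2 <- diag(4); m2[1, 2] <- m2[2, 1] <- -0.6; m2[3, 4] <- m2[4, 3] <- 0.4
  ax2 <- eigen_axes(m2, traits = tr4)
  expect_gte(ax2$loadings["vtd", 1], 0)
})

test_that("profile scores are linear and centre at zero for an average hen", {
  tr4 <- c("vtd", "fdr", "wg", "sleep_top")
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  ax <- eigen_axes(m, traits = tr4)
  scaling <- list(vtd = list(center = 3, scale = 1),
                  fdr = list(center = 0.2, scale = 0.1),
                  nest_timing = list(center = 0, scale = 1),
                  wg = list(center = 0.5, scale = 0.5),
                  sleep_top = list(center = 0.6, scale = 0.49))
  res <- structure(list(scaling = scaling), class = "syndrome_result")
  mkrow <- function(hen, vtd, fdr, wg, st)
    data.frame(hen_id = hen, date = DAY, vtd = vtd, fdr = fdr,
               nest_timing = 4.5, wg = wg, sleep_top = st)
  b <- rbind(mkrow("avg", 3, 0.2, 0.5, 0.6),
             mkrow("dev1", 4, 0.3, 1, 1),
             mkrow("dev2", 5, 0.4, 1.5, 1.4),   # doubled deviations
             mkrow("low", 2, 0.1, 0, 0.2))
  pr <- project_profiles(b, ax, res, quantile = 0.25, n_show = 1, seed = 1)
  sc <- setNames(pr$scores$pc1, pr$scores$hen_id)
  expect_equal(unname(sc["avg"]), 0, tolerance = 1e-12)
  expect_equal(unname(sc["dev2"]), 2 * unname(sc["dev1"]), tolerance = 1e-12)
  expect_true("dev2" %in% pr$high_hens)
  expect_true("low" %in% pr$low_hens)
})
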