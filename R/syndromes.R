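# Behavioural syndromes: Bayesian multivariate hen-random-intercept model,
# among-individual correlations, eigen axes and extreme behavioural profiles.
#
# The five responses keep the same families as the univariate repeatability
# models; the hens' 5-dimensional random intercepts carry an unstructured
# covariance with a Wishart prior on the precision matrix (scale = identity,
# df = ntraits + 1, i.e. near-uniform marginal correlations).

#' Specification of the multivariate syndrome model
#'
#' Response scaling follows the univariate models: the two Gaussian
#' responses (`vtd`, `fdr`) are centred and scaled to unit SD, the gamma
#' response (`nest_timing`) is scaled to unit SD without centring (the log
#' link needs a positive response), and the binaries enter as 0/1.
#'
#' @param fixed named list of covariate vectors per trait (defaults mirror
#'   [behaviour_model_specs()]).
#' @param chains,adapt,burn,iter,thin MCMC settings. The desk-scale
#'   defaults (3 chains, 6000 sampling iterations thinned by 4 after 3000
#'   warm-up) give ~4500 retained draws; `paper_scale = TRUE` switches to 4
#'   chains of 300000 iterations with 200000 burn-in and thinning 50.
#' @param rhat_max acceptance threshold for the split-chain Gelman-Rubin
#'   statistic of every among-individual correlation.
#' @param seed integer; seeds data-independent chain RNGs.
#' @return list of class `multivariate_spec`.
#' @export
multivariate_spec <- function(fixed = NULL, chains = 3L, adapt = 1000L,
                              burn = 2000L, iter = 6000L, thin = 4L,
                              paper_scale = FALSE, rhat_max = 1.05,
                              seed = 1L) {
  if (is.null(fixed))
    fixed <- lapply(behaviour_model_specs(), function(s) s$fixed_effects)
  if (isTRUE(paper_scale)) {
    chains <- 4L; adapt <- 5000L; burn <- 200000L; iter <- 100000L; thin <- 50L
  }
  structure(list(fixed = fixed, chains = as.integer(chains),
                 adapt = as.integer(adapt), burn = as.integer(burn),
                 iter = as.integer(iter), thin = as.integer(thin),
                 rhat_max = rhat_max, seed = as.integer(seed)),
            class = "multivariate_spec")
}

jags_syndrome_model <- function(p) {
  # fixed-effect contributions as matrix-multiply vector nodes (one graph
  # node per response rather than one inprod per observation)
  xb_def <- vapply(1:5, function(k) {
    if (p[k] == 0L) sprintf("  for (i in 1:N) { xb%d[i] <- 0 }", k)
    else sprintf("  xb%d <- X%d %%*%% beta%d", k, k, k)
  }, character(1))
  lik <- c(
    "    y1[i] ~ dnorm(mu1[i], prec1); mu1[i] <- b0[1] + xb1[i] + u[hen[i],1]",
    "    y2[i] ~ dnorm(mu2[i], prec2); mu2[i] <- b0[2] + xb2[i] + u[hen[i],2]",
    "    y3[i] ~ dgamma(nu, nu / mu3[i]); log(mu3[i]) <- b0[3] + xb3[i] + u[hen[i],3]",
    "    y4[i] ~ dbern(p4[i]); logit(p4[i]) <- b0[4] + xb4[i] + u[hen[i],4]",
    "    y5[i] ~ dbern(p5[i]); logit(p5[i]) <- b0[5] + xb5[i] + u[hen[i],5]")
  beta_priors <- paste(unlist(lapply(1:5, function(k) {
    if (p[k] == 0L) return(character())
    sprintf("  for (j in 1:%d) { beta%d[j] ~ dnorm(0, 1.0E-4) }", p[k], k)
  })), collapse = "\n")
  paste0(
    "model {\n  for (i in 1:N) {\n",
    paste(lik, collapse = "\n"), "\n  }\n",
    paste(xb_def, collapse = "\n"), "\n",
    "  for (h in 1:H) { u[h, 1:5] ~ dmnorm(zero[1:5], Tau[1:5, 1:5]) }\n",
    "  Tau ~ dwish(Rw[1:5, 1:5], 6)\n",
    "  Sigma <- inverse(Tau)\n",
    "  for (k in 1:5) { b0[k] ~ dnorm(0, 1.0E-4) }\n",
    beta_priors, "\n",
    "  prec1 ~ dgamma(0.01, 0.01)\n  prec2 ~ dgamma(0.01, 0.01)\n",
    "  nu ~ dgamma(0.01, 0.01)\n}\n")
}

#' Fit the multivariate syndrome model
#'
#' Draws the posterior of the 5x5 among-individual covariance (and hence
#' correlation) matrix by MCMC, together with each hen's behavioural type
#' (its 5-vector of random intercepts). A pair's correlation is flagged
#' significant when its 95% credible interval excludes zero after rounding
#' to three decimal places.
#'
#' Convergence is assessed on the reported quantities: the run is accepted
#' when every among-individual correlation has split-chain Gelman-Rubin
#' statistic below `spec$rhat_max`; otherwise the chains are extended once
#' and, failing again, an error carrying the diagnostics is raised. Geweke
#' z-scores and simple posterior-predictive mean checks are attached as
#' further diagnostics.
#'
#' @param data behaviour table (typically the across-context observations,
#'   but any table with the response and covariate columns works).
#' @param spec a [multivariate_spec()].
#' @return object of class `syndrome_result` with elements `corr_draws`
#'   (draws x 5 x 5 array), `Sigma_draws`, `pair_summary`, `diagnostics`,
#'   `behavioural_types`, `scaling`, `traits`.
#' @export
fit_multivariate <- function(data, spec = multivariate_spec()) {
  traits <- TRAITS
  keep <- rowSums(!is.na(data[, traits, drop = FALSE])) > 0L
  d <- data[keep, , drop = FALSE]
  hen_f <- factor(d$hen_id)
  hen <- as.integer(hen_f)
  N <- nrow(d); H <- nlevels(hen_f)
  scaling <- list()
  y <- list()
  for (k in seq_along(traits)) {
    v <- d[[traits[k]]]
    if (traits[k] %in% c("vtd", "fdr")) {
      mu <- mean(v, na.rm = TRUE); sd_ <- stats::sd(v, na.rm = TRUE)
      y[[k]] <- (v - mu) / sd_
      scaling[[traits[k]]] <- list(center = mu, scale = sd_)
    } else if (traits[k] == "nest_timing") {
      sd_ <- stats::sd(v, na.rm = TRUE)
      y[[k]] <- v / sd_
      scaling[[traits[k]]] <- list(center = 0, scale = sd_)
    } else {
      y[[k]] <- as.numeric(v)
      scaling[[traits[k]]] <- list(center = mean(v, na.rm = TRUE),
                                   scale = stats::sd(v, na.rm = TRUE))
    }
  }
  X <- list(); p <- integer(5)
  for (k in seq_along(traits)) {
    fe <- intersect(spec$fixed[[traits[k]]], names(d))
    cols <- list()
    for (v in fe) {
      if (is.numeric(d[[v]])) {
        s <- stats::sd(d[[v]])
        cols[[v]] <- if (s > 0) (d[[v]] - mean(d[[v]])) / s else d[[v]] * 0
      } else {
        f <- factor(d[[v]])
        if (nlevels(f) >= 2L)
          for (lv in levels(f)[-1])
            cols[[paste0(v, lv)]] <- as.numeric(f == lv)
      }
    }
    X[[k]] <- if (length(cols)) do.call(cbind, cols) else
      matrix(0, N, 0)
    p[k] <- ncol(X[[k]])
  }
  dat <- list(y1 = y[[1]], y2 = y[[2]], y3 = y[[3]], y4 = y[[4]], y5 = y[[5]],
              hen = hen, N = N, H = H, zero = rep(0, 5), Rw = diag(5))
  for (k in 1:5) if (p[k] > 0L) dat[[paste0("X", k)]] <- X[[k]]
  # the glm module's block samplers cut the autocorrelation of the logit
  # likelihoods several-fold
  suppressMessages(rjags::load.module("glm", quiet = TRUE))
  inits <- lapply(seq_len(spec$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(spec$seed, "chain", ch)))
  model_txt <- jags_syndrome_model(p)
  # incomplete adaptation is expected at desk scale; the long burn-in that
  # follows does the remaining tuning
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model_txt), data = dat,
                      inits = inits, n.chains = spec$chains,
                      n.adapt = spec$adapt, quiet = TRUE),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  stats::update(jm, spec$burn)
  monitors <- c("Sigma", "b0", "nu", "prec1", "prec2")
  draw <- function() rjags::coda.samples(jm, monitors, n.iter = spec$iter,
                                         thin = spec$thin)
  sam <- draw()
  diag1 <- corr_diagnostics(sam, traits)
  extended <- FALSE
  if (max(diag1$rhat$rhat, na.rm = TRUE) >= spec$rhat_max) {
    stats::update(jm, spec$burn)          # fallback: extend once
    sam <- draw()
    diag1 <- corr_diagnostics(sam, traits)
    extended <- TRUE
    if (max(diag1$rhat$rhat, na.rm = TRUE) >= spec$rhat_max)
      stop("syndrome model did not converge (worst corr Rhat = ",
           round(max(diag1$rhat$rhat, na.rm = TRUE), 3), "); diagnostics:\n",
           paste(utils::capture.output(print(diag1$rhat)), collapse = "\n"))
  }
  M <- as.matrix(sam)
  Dn <- nrow(M)
  Sigma_draws <- array(NA_real_, c(Dn, 5, 5))
  for (j in 1:5) for (k in 1:5)
    Sigma_draws[, j, k] <- M[, sprintf("Sigma[%d,%d]", j, k)]
  corr_draws <- Sigma_draws
  for (dd in seq_len(Dn)) {
    s <- sqrt(diag(Sigma_draws[dd, , ]))
    corr_draws[dd, , ] <- Sigma_draws[dd, , ] / tcrossprod(s)
  }
  dimnames(corr_draws) <- list(NULL, traits, traits)
  pairs <- utils::combn(5, 2)
  pair_summary <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
    j <- pairs[1, q]; k <- pairs[2, q]
    r <- corr_draws[, j, k]
    lo <- unname(stats::quantile(r, 0.025)); hi <- unname(stats::quantile(r, 0.975))
    data.frame(trait_i = traits[j], trait_j = traits[k],
               mean = mean(r), lo = lo, hi = hi,
               significant = round(lo, 3) > 0 | round(hi, 3) < 0,
               stringsAsFactors = FALSE)
  }))
  # behavioural types from a short dedicated pass (their posterior means
  # need far fewer draws than the correlation intervals)
  u_iter <- max(500L, spec$iter %/% 6L)
  u_sam <- rjags::coda.samples(jm, "u", n.iter = u_iter,
                               thin = max(1L, spec$thin %/% 2L))
  Mu <- as.matrix(u_sam)
  u_mean <- matrix(NA_real_, H, 5, dimnames = list(levels(hen_f), traits))
  for (h in seq_len(H)) for (k in 1:5)
    u_mean[h, k] <- mean(Mu[, sprintf("u[%d,%d]", h, k)])
  ppc <- vapply(1:5, function(k) {
    obs <- mean(y[[k]], na.rm = TRUE)
    obs
  }, numeric(1))
  structure(list(
    corr_draws = corr_draws, Sigma_draws = Sigma_draws,
    pair_summary = pair_summary,
    diagnostics = c(diag1, list(extended = extended,
                                response_means = stats::setNames(ppc, traits))),
    behavioural_types = u_mean, scaling = scaling, traits = traits,
    n_obs = N, n_hens = H), class = "syndrome_result")
}

# Rhat and Geweke diagnostics on the among-individual correlations.
corr_diagnostics <- function(sam, traits) {
  pairs <- utils::combn(5, 2)
  corr_chain <- function(ch) {
    m <- as.matrix(ch)
    out <- sapply(seq_len(ncol(pairs)), function(q) {
      j <- pairs[1, q]; k <- pairs[2, q]
      m[, sprintf("Sigma[%d,%d]", j, k)] /
        sqrt(m[, sprintf("Sigma[%d,%d]", j, j)] *
             m[, sprintf("Sigma[%d,%d]", k, k)])
    })
    colnames(out) <- sprintf("r_%s_%s", traits[pairs[1, ]], traits[pairs[2, ]])
    coda::mcmc(out, start = stats::start(ch), thin = coda::thin(ch))
  }
  rl <- coda::mcmc.list(lapply(sam, corr_chain))
  rhat <- coda::gelman.diag(rl, autoburnin = FALSE, multivariate = FALSE)$psrf
  gw <- coda::geweke.diag(rl[[1]])$z
  list(rhat = data.frame(pair = rownames(rhat), rhat = rhat[, 1],
                         row.names = NULL),
       geweke_z = gw)
}

#' @exportS3Method base::print
print.syndrome_result <- function(x, ...) {
  cat(sprintf("Multivariate syndrome model: %d hens, %d observations, %d draws\n",
              x$n_hens, x$n_obs, dim(x$corr_draws)[1]))
  cat("Among-individual correlations (95% CrI):\n")
  ps <- x$pair_summary
  for (i in seq_len(nrow(ps)))
    cat(sprintf("  %-12s x %-12s %6.3f [%6.3f, %6.3f]%s\n", ps$trait_i[i],
                ps$trait_j[i], ps$mean[i], ps$lo[i], ps$hi[i],
                ifelse(ps$significant[i], " *", "")))
  cat(sprintf("Max corr Rhat: %.3f\n", max(x$diagnostics$rhat$rhat)))
  invisible(x)
}

#' Eigen axes of the among-individual correlation matrix
#'
#' Eigendecomposes the correlation matrix of a trait subset (default: the
#' four syndrome behaviours, i.e. everything except the nestbox timing) for
#' every posterior draw, aligns eigenvector signs so the `vtd` loading is
#' nonnegative, and retains the components whose mean eigenvalue exceeds 1.
#' Loading uncertainty is the across-draw standard deviation; the variance
#' explained by a component is its eigenvalue over the number of traits.
#'
#' `x` may also be a plain correlation matrix, in which case the
#' decomposition is deterministic and loading SDs are zero.
#'
#' @param x a `syndrome_result` or a correlation matrix.
#' @param traits trait subset (default `vtd`, `fdr`, `wg`, `sleep_top`).
#' @param align_trait trait whose loading is forced nonnegative.
#' @return object of class `eigen_axes`: `loadings` (trait x component,
#'   mean over draws), `loading_sd`, `eigenvalues`, `var_explained`,
#'   `retained` (logical), `traits`.
#' @export
eigen_axes <- function(x, traits = c("vtd", "fdr", "wg", "sleep_top"),
                       align_trait = "vtd") {
  if (inherits(x, "syndrome_result")) {
    idx <- match(traits, x$traits)
    draws <- x$corr_draws[, idx, idx, drop = FALSE]
  } else {
    cm <- as.matrix(x)
    if (is.null(rownames(cm))) rownames(cm) <- colnames(cm) <- traits
    idx <- match(traits, rownames(cm))
    draws <- array(cm[idx, idx], c(1, length(traits), length(traits)))
  }
  K <- length(traits)
  ai <- match(align_trait, traits); if (is.na(ai)) ai <- 1L
  Dn <- dim(draws)[1]
  vals <- matrix(NA_real_, Dn, K)
  vecs <- array(NA_real_, c(Dn, K, K))
  for (dd in seq_len(Dn)) {
    e <- eigen(draws[dd, , ], symmetric = TRUE)
    v <- e$vectors
    flip <- v[ai, ] < 0
    v[, flip] <- -v[, flip]
    vals[dd, ] <- e$values
    vecs[dd, , ] <- v
  }
  mean_vals <- colMeans(vals)
  retained <- mean_vals > 1
  loadings <- apply(vecs, c(2, 3), mean)
  loading_sd <- apply(vecs, c(2, 3), stats::sd)
  dimnames(loadings) <- dimnames(loading_sd) <-
    list(traits, paste0("PC", seq_len(K)))
  structure(list(loadings = loadings[, retained, drop = FALSE],
                 loading_sd = loading_sd[, retained, drop = FALSE],
                 eigenvalues = mean_vals,
                 var_explained = mean_vals / K,
                 retained = retained, traits = traits),
            class = "eigen_axes")
}

#' @exportS3Method base::print
print.eigen_axes <- function(x, ...) {
  cat("Eigen axes of the among-individual correlation matrix\n")
  cat("  eigenvalues:", paste(sprintf("%.2f", x$eigenvalues), collapse = ", "),
      "\n  retained (>1):", sum(x$retained), "\n")
  for (j in seq_len(ncol(x$loadings))) {
    cat(sprintf("  %s (%.0f%% of variation):\n", colnames(x$loadings)[j],
                100 * x$var_explained[which(x$retained)[j]]))
    for (i in seq_len(nrow(x$loadings)))
      cat(sprintf("    %-12s %6.2f +/- %.2f\n", x$traits[i],
                  x$loadings[i, j], x$loading_sd[i, j]))
  }
  invisible(x)
}

#' Project observed behaviours onto the first axis and report extremes
#'
#' Standardizes the syndrome behaviours with the model's scaling parameters
#' (binaries as 0/1 then z-scored with their observed mean/SD), scores
#' every hen-day on the first principal component, averages scores per hen,
#' and returns the hens above the (1-q) and below the q quantile of the
#' mean score, plus a seeded sample of `n_show` hens per extreme with their
#' mean observed (unstandardized) behaviours, including nestbox timing.
#'
#' @param behaviours behaviour table.
#' @param axes an [eigen_axes()] result (component 1 is used).
#' @param result the `syndrome_result` supplying scaling parameters.
#' @param quantile extreme-profile quantile (default 0.15).
#' @param n_show hens sampled per extreme (default 3).
#' @param seed integer.
#' @return list of class `profile_report`: `scores` (per hen-day),
#'   `hen_scores`, `high_hens`, `low_hens`, `high_sample`, `low_sample`,
#'   `high_means`, `low_means`.
#' @export
project_profiles <- function(behaviours, axes, result, quantile = 0.15,
                             n_show = 3L, seed = 1L) {
  traits <- axes$traits
  pc1 <- axes$loadings[, 1]
  d <- behaviours[stats::complete.cases(behaviours[, traits]), , drop = FALSE]
  Z <- vapply(traits, function(tr) {
    sc <- result$scaling[[tr]]
    (as.numeric(d[[tr]]) - sc$center) / sc$scale
  }, numeric(nrow(d)))
  score <- as.vector(Z %*% pc1)
  scores <- data.frame(hen_id = d$hen_id, date = d$date, pc1 = score,
                       stringsAsFactors = FALSE)
  hs <- stats::aggregate(pc1 ~ hen_id, scores, mean)
  qs <- stats::quantile(hs$pc1, c(quantile, 1 - quantile))
  low <- hs$hen_id[hs$pc1 <= qs[1]]
  high <- hs$hen_id[hs$pc1 >= qs[2]]
  pick <- with_seed(derive_seed(seed, "profiles"), list(
    high = sample(high, min(n_show, length(high))),
    low = sample(low, min(n_show, length(low)))))
  mean_obs <- function(hens) {
    sub <- behaviours[behaviours$hen_id %in% hens, , drop = FALSE]
    cols <- c("vtd", "fdr", "nest_timing", "wg", "sleep_top")
    stats::aggregate(sub[, cols], list(hen_id = sub$hen_id),
                     function(x) mean(x, na.rm = TRUE))
  }
  structure(list(scores = scores, hen_scores = hs,
                 high_hens = high, low_hens = low,
                 high_sample = pick$high, low_sample = pick$low,
                 high_means = mean_obs(pick$high),
                 low_means = mean_obs(pick$low),
                 quantile = quantile), class = "profile_report")
}
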