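# Adjusted repeatability on the latent scale for Gaussian, binary and
# gamma responses, with parametric-bootstrap confidence intervals.
#
# Families and variance decomposition follow the standard GLMM repeatability
# methodology (Nakagawa & Schielzeth; Stoffel et al.): the among-individual
# variance Va is set against the within-individual variance, which for the
# non-Gaussian families includes the distribution-specific link-scale
# observation-level variance (pi^2/3 for the logit-Bernoulli family,
# trigamma(shape) for the log-Gamma family).

#' Model specification for one behaviour's repeatability
#'
#' @param response behaviour column name.
#' @param family one of `"gaussian"`, `"bernoulli_logit"`, `"gamma_log"`.
#' @param fixed_effects character vector drawn from `days_in_barn`, `kbf`,
#'   `mass`, `class`, `treatment`, `feed_chain`.
#' @param scale_continuous center/scale continuous fixed effects (default
#'   TRUE, so intercepts reflect average conditions).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(response,
                       family = c("gaussian", "bernoulli_logit", "gamma_log"),
                       fixed_effects = character(),
                       scale_continuous = TRUE) {
  family <- match.arg(family)
  structure(list(response = response, family = family,
                 fixed_effects = fixed_effects,
                 scale_continuous = isTRUE(scale_continuous)),
            class = "model_spec")
}

#' Default model specifications for the five behaviours
#'
#' All models adjust for keel-bone-fracture severity, body mass, class,
#' treatment and a time effect (days in barn); the feed delivery response
#' additionally controls for feed-chain identity, and class is dropped
#' from the winter-garden model (mirroring the convergence-driven removal
#' in the original analysis).
#'
#' @return named list of [model_spec()]s.
#' @export
behaviour_model_specs <- function() {
  base <- c("kbf", "mass", "class", "treatment", "days_in_barn")
  list(
    vtd = model_spec("vtd", "gaussian", base),
    fdr = model_spec("fdr", "gaussian", c(base, "feed_chain")),
    nest_timing = model_spec("nest_timing", "gamma_log", base),
    wg = model_spec("wg", "bernoulli_logit", setdiff(base, "class")),
    sleep_top = model_spec("sleep_top", "bernoulli_logit", base)
  )
}

# ---- internal exact REML for a Gaussian one-random-intercept model ------
#
# Profiles the REML criterion over lambda = Va/Vr using per-group
# sufficient statistics, so a fit costs O(G p^2) per criterion evaluation
# and a parametric-bootstrap refit only has to update the y-dependent
# cross-products. Agrees with lme4::lmer to optimizer precision.

reml_cache <- function(X, g) {
  g <- as.integer(g)
  list(X = X, g = g, G = max(g), n = nrow(X), p = ncol(X),
       XtX = crossprod(X), ng = tabulate(g, max(g)), Sx = rowsum(X, g))
}

reml_solve <- function(cache, y) {
  Xty <- crossprod(cache$X, y)
  yty <- sum(y * y)
  Sy <- rowsum(y, cache$g)[, 1]
  n <- cache$n; p <- cache$p; ng <- cache$ng
  crit <- function(loglam) {
    lam <- exp(loglam)
    w <- lam / (1 + lam * ng)
    A <- cache$XtX - crossprod(cache$Sx, cache$Sx * w)
    b <- Xty - crossprod(cache$Sx, Sy * w)
    cc <- yty - sum(w * Sy^2)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    s2 <- max(cc - sum(b * beta), 1e-12) / (n - p)
    sum(log1p(lam * ng)) + 2 * sum(log(diag(ch))) + (n - p) * log(s2)
  }
  opt <- stats::optimize(crit, c(-16, 16), tol = 1e-10)
  lam <- exp(opt$minimum)
  w <- lam / (1 + lam * ng)
  A <- cache$XtX - crossprod(cache$Sx, cache$Sx * w)
  b <- Xty - crossprod(cache$Sx, Sy * w)
  cc <- yty - sum(w * Sy^2)
  beta <- solve(A, b)
  s2 <- max(cc - sum(b * beta), 1e-12) / (n - p)
  tau2 <- lam * s2
  # conditional modes of the group effects (for parametric simulation)
  resid_g <- Sy - as.vector(cache$Sx %*% beta)
  list(beta = as.vector(beta), sigma2 = as.numeric(s2),
       tau2 = as.numeric(tau2), lambda = lam,
       u = as.vector(lam / (1 + lam * ng) * resid_g))
}

# ---- model-frame preparation --------------------------------------------

prepare_frame <- function(data, spec) {
  keep <- !is.na(data[[spec$response]])
  d <- data[keep, , drop = FALSE]
  fe <- intersect(spec$fixed_effects, names(d))
  if (length(miss <- setdiff(spec$fixed_effects, names(d))))
    stop("fixed effects absent from data: ", paste(miss, collapse = ", "))
  for (v in fe) {
    if (is.numeric(d[[v]]) && spec$scale_continuous) {
      s <- stats::sd(d[[v]])
      d[[v]] <- if (s > 0) (d[[v]] - mean(d[[v]])) / s else d[[v]] * 0
    } else if (!is.numeric(d[[v]])) {
      d[[v]] <- factor(d[[v]])
      if (nlevels(d[[v]]) < 2L) fe <- setdiff(fe, v)
    }
  }
  rhs <- if (length(fe)) paste(fe, collapse = " + ") else "1"
  list(data = d, fe = fe,
       fixed_formula = stats::as.formula(paste(spec$response, "~", rhs)),
       mixed_formula = stats::as.formula(
         paste(spec$response, "~", rhs, "+ (1 | hen_id)")))
}

# ---- the estimator ------------------------------------------------------

#' Adjusted repeatability of one behaviour
#'
#' Fits a hen-random-intercept model with the specification's family and
#' fixed effects, and decomposes variance on the latent (link) scale:
#' \itemize{
#'   \item Gaussian: `R = Va / (Va + Vr)`;
#'   \item Bernoulli (logit): `R = Va / (Va + pi^2/3)`;
#'   \item Gamma (log): `R = Va / (Va + trigamma(shape))`, with the shape
#'     estimated jointly by maximum likelihood.
#' }
#' The 95% confidence interval comes from a parametric bootstrap: new
#' responses are simulated from the fitted model, the model is refitted,
#' and the 2.5/97.5 percentiles of the bootstrap repeatabilities are
#' reported.
#'
#' The Gaussian family uses an internal exact REML profiler (identical to
#' `lme4::lmer` estimates, orders of magnitude faster over bootstrap
#' replicates); the binary family uses [lme4::glmer()] and the gamma family
#' [glmmTMB::glmmTMB()].
#'
#' @param data behaviour table with a `hen_id` column.
#' @param spec a [model_spec()].
#' @param n_boot bootstrap replicates (0 skips the interval).
#' @param seed integer seed for the bootstrap.
#' @param analysis_set label stored in the result.
#' @return object of class `repeatability_result`: fields `R`, `ci95`,
#'   `v_among`, `v_within`, `family`, `n_obs`, `n_hens`, `analysis_set`,
#'   `boundary` (TRUE when the among-individual variance collapsed to 0).
#' @export
fit_adjusted_repeatability <- function(data, spec, n_boot = 1000L,
                                       seed = 1L, analysis_set = NA_character_) {
  pf <- prepare_frame(data, spec)
  d <- pf$data
  if (nrow(d) < 4L || length(unique(d$hen_id)) < 2L)
    stop("need at least 2 observations for at least 2 hens")
  fit <- switch(spec$family,
    gaussian = fit_gaussian_R(d, pf, n_boot, seed),
    bernoulli_logit = fit_glmm_R(d, pf, n_boot, seed, family = "bernoulli"),
    gamma_log = fit_glmm_R(d, pf, n_boot, seed, family = "gamma"))
  structure(list(R = fit$R, ci95 = fit$ci, v_among = fit$va,
                 v_within = fit$vw, family = spec$family,
                 response = spec$response,
                 n_obs = nrow(d), n_hens = length(unique(d$hen_id)),
                 n_boot_ok = fit$n_boot_ok,
                 analysis_set = analysis_set,
                 boundary = fit$va < 1e-8),
            class = "repeatability_result")
}

fit_gaussian_R <- function(d, pf, n_boot, seed) {
  X <- stats::model.matrix(pf$fixed_formula, d)
  g <- as.integer(factor(d$hen_id))
  cache <- reml_cache(X, g)
  est <- reml_solve(cache, d[[all.vars(pf$fixed_formula)[1]]])
  if (est$lambda <= exp(-15.9)) est$tau2 <- 0   # profile hit the boundary
  R <- est$tau2 / (est$tau2 + est$sigma2)
  ci <- c(NA_real_, NA_real_); ok <- 0L
  if (n_boot > 0L) {
    mu_fix <- as.vector(X %*% est$beta)
    Rb <- with_seed(derive_seed(seed, "boot", "gaussian"), {
      vapply(seq_len(n_boot), function(b) {
        u <- stats::rnorm(cache$G, 0, sqrt(est$tau2))
        yb <- mu_fix + u[g] + stats::rnorm(cache$n, 0, sqrt(est$sigma2))
        eb <- reml_solve(cache, yb)
        eb$tau2 / (eb$tau2 + eb$sigma2)
      }, numeric(1))
    })
    ci <- unname(stats::quantile(Rb, c(0.025, 0.975)))
    ok <- n_boot
  }
  list(R = R, ci = ci, va = est$tau2, vw = est$sigma2, n_boot_ok = ok)
}

fit_glmm_R <- function(d, pf, n_boot, seed, family) {
  fit_once <- function(dat) {
    if (family == "bernoulli") {
      m <- suppressWarnings(tryCatch(
        lme4::glmer(pf$mixed_formula, data = dat, family = stats::binomial(),
                    control = lme4::glmerControl(optimizer = "bobyqa",
                                                 calc.derivs = FALSE)),
        error = function(e) NULL))
      if (is.null(m))
        m <- lme4::glmer(pf$mixed_formula, data = dat,
                         family = stats::binomial(),
                         control = lme4::glmerControl(optimizer = "Nelder_Mead",
                                                      calc.derivs = FALSE))
      va <- unname(lme4::VarCorr(m)$hen_id[1])
      list(m = m, va = va, vw = pi^2 / 3)
    } else {
      m <- glmmTMB::glmmTMB(pf$mixed_formula, data = dat,
                            family = stats::Gamma(link = "log"))
      if (!m$sdr$pdHess)
        m <- glmmTMB::glmmTMB(pf$mixed_formula, data = dat,
                              family = stats::Gamma(link = "log"),
                              control = glmmTMB::glmmTMBControl(
                                optimizer = stats::optim,
                                optArgs = list(method = "BFGS")))
      va <- unname(glmmTMB::VarCorr(m)$cond$hen_id[1])
      shape <- 1 / stats::sigma(m)^2
      list(m = m, va = va, vw = trigamma(shape))
    }
  }
  f0 <- fit_once(d)
  R <- f0$va / (f0$va + f0$vw)
  ci <- c(NA_real_, NA_real_); ok <- 0L
  if (n_boot > 0L) {
    resp <- all.vars(pf$mixed_formula)[1]
    sims <- with_seed(derive_seed(seed, "boot", family),
                      stats::simulate(f0$m, nsim = n_boot))
    Rb <- vapply(seq_len(n_boot), function(b) {
      db <- d
      db[[resp]] <- sims[[b]]
      fb <- tryCatch(fit_once(db), error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      fb$va / (fb$va + fb$vw)
    }, numeric(1))
    Rb <- Rb[!is.na(Rb)]
    ok <- length(Rb)
    if (ok > 0L) ci <- unname(stats::quantile(Rb, c(0.025, 0.975)))
  }
  list(R = R, ci = ci, va = f0$va, vw = f0$vw, n_boot_ok = ok)
}

#' @exportS3Method base::print
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Adjusted repeatability (%s, %s%s)\n", x$response, x$family,
              if (!is.na(x$analysis_set)) paste0(", ", x$analysis_set) else ""))
  cat(sprintf("  R = %.3f [%.3f, %.3f]\n", x$R, x$ci95[1], x$ci95[2]))
  cat(sprintf("  Va = %.4f  Vw = %.4f  (n_obs = %d, n_hens = %d)\n",
              x$v_among, x$v_within, x$n_obs, x$n_hens))
  if (x$boundary) cat("  note: among-individual variance at boundary (0)\n")
  invisible(x)
}

#' Repeatability grid: five behaviours by six analysis sets
#'
#' Computes the adjusted repeatability of every behaviour on every analysis
#' set (over time, each of the four contexts, and across contexts), plus
#' per-set observation counts and the mean / maximum number of days between
#' any two observation dates.
#'
#' @param analysis_sets named list of behaviour-table subsets (see
#'   [make_analysis_sets()]).
#' @param specs named list of [model_spec()]s (default
#'   [behaviour_model_specs()]).
#' @param n_boot,seed bootstrap settings passed through.
#' @return `data.frame` with one row per behaviour x set; combinations that
#'   cannot be fitted are listed in the `skipped` attribute.
#' @export
repeatability_matrix <- function(analysis_sets,
                                 specs = behaviour_model_specs(),
                                 n_boot = 0L, seed = 1L) {
  rows <- list(); skipped <- character()
  for (set in names(analysis_sets)) {
    d <- analysis_sets[[set]]
    if (nrow(d) < 2L * length(unique(d$hen_id))) {
      skipped <- c(skipped, sprintf(
        "%s: fewer than 2 observations per hen on average", set))
      next
    }
    dates <- unique(as.numeric(d$date))
    gaps <- if (length(dates) > 1L) as.numeric(stats::dist(dates)) else 0
    for (nm in names(specs)) {
      res <- tryCatch(
        fit_adjusted_repeatability(d, specs[[nm]], n_boot = n_boot,
                                   seed = derive_seed(seed, set, nm),
                                   analysis_set = set),
        error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped, sprintf("%s/%s: %s", set, nm, conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        behaviour = nm, analysis_set = set, R = res$R,
        ci_lo = res$ci95[1], ci_hi = res$ci95[2],
        v_among = res$v_among, v_within = res$v_within,
        family = res$family, n_obs = res$n_obs, n_hens = res$n_hens,
        mean_day_gap = mean(gaps), max_day_gap = max(gaps),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Assemble the six analysis sets from a behaviour table and contexts
#'
#' @param behaviours behaviour table with covariates.
#' @param contexts output of [select_context_days()].
#' @return named list: `over_time`, `early`, `late`, `cold`, `vaccination`
#'   (rows on each context's days) and `across_contexts` (one
#'   representative row per hen and context, from
#'   [across_context_observations()]).
#' @export
make_analysis_sets <- function(behaviours, contexts) {
  pickdays <- function(days)
    behaviours[behaviours$date %in% days, , drop = FALSE]
  list(over_time = pickdays(contexts$OVER_TIME),
       early = pickdays(contexts$EARLY),
       late = pickdays(contexts$LATE),
       cold = pickdays(contexts$COLD),
       vaccination = pickdays(contexts$VACCINATION),
       across_contexts = across_context_observations(behaviours, contexts))
}
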