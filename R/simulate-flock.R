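# Behaviour-level flock simulator: known variance components, hen profiles,
# covariate trajectories and the study calendar.
#
# Trait order used throughout: vtd, fdr, nest_timing, wg, sleep_top.

TRAITS <- c("vtd", "fdr", "nest_timing", "wg", "sleep_top")

#' Default among-individual covariance of the five latent behavioural types
#'
#' Latent-scale standard deviations and correlations chosen to mirror the
#' structure of a commercial flock: moderate-to-high repeatability of the
#' indoor movement and sleeping behaviours, a positively correlated
#' movement / outdoor / feeding cluster, a weak negative association of
#' those with the sleeping tier, and a nesting behaviour uncorrelated with
#' everything else.
#'
#' @return a 5x5 positive-definite covariance matrix (trait order
#'   `vtd, fdr, nest_timing, wg, sleep_top`).
#' @export
default_sigma_A <- function() {
  sds <- c(vtd = sqrt(0.5), fdr = sqrt(0.015), nest_timing = sqrt(0.037),
           wg = sqrt(2.19), sleep_top = sqrt(3.29))
  R <- diag(5)
  dimnames(R) <- list(TRAITS, TRAITS)
  R["vtd", "wg"] <- R["wg", "vtd"] <- 0.50
  R["vtd", "fdr"] <- R["fdr", "vtd"] <- 0.47
  R["vtd", "sleep_top"] <- R["sleep_top", "vtd"] <- -0.23
  R["fdr", "wg"] <- R["wg", "fdr"] <- 0.27
  R["fdr", "sleep_top"] <- R["sleep_top", "fdr"] <- -0.21
  diag(sds) %*% R %*% diag(sds)
}

#' Flock simulation configuration
#'
#' Defines a synthetic flock: its size and tracking span, the
#' among-individual covariance of the five latent behavioural types, the
#' residual structure per trait, trait intercepts, fixed-effect
#' coefficients on covariates, and the study calendar (vaccination days and
#' external temperature with embedded cold spells).
#'
#' Trait families follow the downstream models: `vtd` and `fdr` are
#' Gaussian, `nest_timing` is gamma with a log link (shape `nest_shape`),
#' `wg` and `sleep_top` are Bernoulli with a logit link. The defaults give
#' latent-scale repeatabilities of roughly 0.67, 0.38, 0.52, 0.40 and 0.50
#' respectively.
#'
#' @param n_hens,n_days flock size and tracking length in days.
#' @param start_date first tracked date.
#' @param sigma_A 5x5 among-individual covariance on the latent scale.
#' @param resid_var named residual variances for the Gaussian traits.
#' @param nest_shape gamma shape of the nestbox-timing response.
#' @param means named trait intercepts on the link scale (`nest_timing` on
#'   the log scale; binaries on the logit scale).
#' @param beta named list: per-trait named coefficient vectors on scaled
#'   covariates (`days_in_barn`, `kbf`, `mass`) and factor contrasts
#'   (`classLEXP`, `treatmentTRAN`, `feed_chainB`). Small nonzero defaults
#'   make the "adjusted" part of adjusted repeatability testable.
#' @param prob_missing per-hen-day probability that tracking failed.
#' @param type_ar1 day-to-day autocorrelation of the latent types. The
#'   default 1 keeps each hen's type fixed over the span; values below 1
#'   let types drift as a stationary AR(1) process (marginal covariance
#'   still `sigma_A`), which lowers the among-individual variance
#'   recoverable from widely spaced observations.
#' @param vaccination_offsets days (from start) of the three vaccinations.
#' @param cold_spell_offsets days (from start) on which 3-day cold spells
#'   begin.
#' @param seed integer.
#' @return list of class `flock_config`.
#' @export
flock_config <- function(n_hens = 194L, n_days = 242L,
                         start_date = as.Date("2020-11-01"),
                         sigma_A = default_sigma_A(),
                         resid_var = c(vtd = 0.25, fdr = 0.025),
                         nest_shape = 30,
                         means = c(vtd = 3.0, fdr = 0.15, nest_timing = 1.5,
                                   wg = 0.3, sleep_top = 0.8),
                         beta = default_beta(),
                         prob_missing = 0.05,
                         vaccination_offsets = NULL,
                         cold_spell_offsets = NULL,
                         type_ar1 = 1,
                         seed = 1L) {
  # calendar events scale with the span: cold spells sit between the early
  # and late context windows; vaccinations are spread over the middle
  if (is.null(cold_spell_offsets))
    cold_spell_offsets <- pmax(22L, 22L + as.integer(round(
      (n_days - 47L) * c(0.10, 0.45, 0.80))))
  if (is.null(vaccination_offsets))
    vaccination_offsets <- pmin(n_days, as.integer(round(
      n_days * c(0.19, 0.42, 0.65))))
  sigma_A <- as.matrix(sigma_A)
  dimnames(sigma_A) <- list(TRAITS, TRAITS)
  ev <- eigen(sigma_A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("sigma_A must be positive semi-definite")
  stopifnot(n_hens >= 1L, n_days >= 1L, nest_shape > 0)
  structure(list(n_hens = as.integer(n_hens), n_days = as.integer(n_days),
                 start_date = as.Date(start_date), sigma_A = sigma_A,
                 resid_var = resid_var, nest_shape = nest_shape,
                 means = means, beta = beta, prob_missing = prob_missing,
                 vaccination_offsets = vaccination_offsets,
                 cold_spell_offsets = cold_spell_offsets,
                 type_ar1 = type_ar1,
                 seed = as.integer(seed)),
            class = "flock_config")
}

#' @rdname flock_config
#' @export
default_beta <- function() {
  list(
    vtd = c(days_in_barn = -0.15, kbf = 0.10, mass = 0.10),
    fdr = c(days_in_barn = 0.03, feed_chainB = 0.02),
    nest_timing = c(days_in_barn = 0.04, mass = -0.04),
    wg = c(days_in_barn = 0.40),
    sleep_top = c(days_in_barn = -0.30, classLEXP = 0.20)
  )
}

#' Simulate hen profiles
#'
#' Static covariates (pen 1-8, feed chain A for pens 1-4 and B for pens
#' 5-8, exploration class, rearing treatment) plus five-assessment
#' keel-bone-fracture severity (0-100) and body-mass (g) trajectories, both
#' upward-trending. Assessment ages follow the study design (173, 215, 243,
#' 313, 417 days of age); hens enter the barn at 119 days of age and
#' tracking starts at 175.
#'
#' @param cfg a [flock_config()].
#' @return `data.frame` with one row per hen; the assessment pairs are kept
#'   in list-columns `kbf_assessments` / `mass_assessments`.
#' @export
simulate_hen_profiles <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "profiles"), {
    n <- cfg$n_hens
    pen <- rep_len(1:8, n)
    hen_id <- sprintf("hen%03d", seq_len(n))
    ages <- c(173, 215, 243, 313, 417)
    kbf <- lapply(seq_len(n), function(i) {
      v <- cumsum(c(stats::runif(1, 0, 20), stats::runif(4, 0, 15)))
      cbind(age = ages, score = pmin(v, 100))
    })
    mass <- lapply(seq_len(n), function(i) {
      v <- cumsum(c(stats::rnorm(1, 1600, 80), stats::runif(4, 20, 120)))
      cbind(age = ages, grams = v)
    })
    data.frame(hen_id = hen_id, pen = pen,
               feed_chain = ifelse(pen <= 4, "A", "B"),
               class = sample(c("MEXP", "LEXP"), n, replace = TRUE),
               treatment = ifelse(pen %in% c(1, 2, 5, 6), "OFH", "TRAN"),
               stringsAsFactors = FALSE) |>
      transform(kbf_assessments = I(kbf), mass_assessments = I(mass))
  })
}

#' Simulate the study calendar: temperature series and vaccination dates
#'
#' Hourly external temperatures over the tracking span with three embedded
#' cold spells (three consecutive days each on which every hourly mean
#' during winter-garden hours is negative, between -4 and -1 degC, as in a
#' mid-winter inversion); elsewhere daytime temperatures stay positive.
#' Vaccination days are placed mid-week so they do not collide with the
#' Saturday-based contexts.
#'
#' @param cfg a [flock_config()].
#' @return list with `dates`, `temperature` (`data.frame date, hour,
#'   temp_c`) and `vaccination_dates`.
#' @export
simulate_calendar <- function(cfg) {
  dates <- seq(cfg$start_date, by = "day", length.out = cfg$n_days)
  with_seed(derive_seed(cfg$seed, "calendar"), {
    grid <- expand.grid(hour = 0:23, date = dates)[, c("date", "hour")]
    doy <- as.integer(format(grid$date, "%j"))
    base <- 8 + 7 * cos(2 * pi * (doy - 200) / 365)     # seasonal mean
    diurnal <- 3 * sin(2 * pi * (grid$hour - 4) / 24)
    temp <- base + diurnal + stats::rnorm(nrow(grid), 0, 1)
    temp <- pmax(temp, 0.5)                              # no stray cold days
    cold_days <- as.Date(character())
    for (off in cfg$cold_spell_offsets) {
      spell <- dates[off + 0:2]
      spell <- spell[!is.na(spell)]
      cold_days <- c(cold_days, spell)
      sel <- grid$date %in% spell & grid$hour >= 8 & grid$hour <= 17
      temp[sel] <- stats::runif(sum(sel), -4, -1)
    }
    vacc <- dates[pmin(cfg$vaccination_offsets, cfg$n_days)]
    # nudge vaccinations off Saturdays and cold days
    for (i in seq_along(vacc)) {
      while (format(vacc[i], "%u") == "6" || vacc[i] %in% cold_days)
        vacc[i] <- vacc[i] + 1
    }
    list(dates = dates,
         temperature = data.frame(date = grid$date, hour = grid$hour,
                                  temp_c = temp),
         vaccination_dates = vacc)
  })
}

#' Simulate a daily-behaviour table with known variance components
#'
#' Draws each hen's latent behavioural type `u_i ~ MVN(0, sigma_A)`, builds
#' per-day linear predictors `eta = mean + X beta + u`, and draws the five
#' responses from their families: Gaussian with residual variance
#' `resid_var`, Bernoulli(logit^-1(eta)), and Gamma(shape, mean = exp(eta))
#' for the nest timing. Returns the table together with the exact ground
#' truth (types, covariances, and per-trait latent-scale repeatabilities:
#' `Va/(Va+Vr)` for Gaussian, `Va/(Va+pi^2/3)` for binary,
#' `Va/(Va+trigamma(shape))` for the gamma trait).
#'
#' @param cfg a [flock_config()].
#' @return list with `behaviours` (one row per tracked hen-day, including
#'   covariate columns), `profiles`, `calendar` and `truth`.
#' @export
simulate_behaviour_table <- function(cfg) {
  profiles <- simulate_hen_profiles(cfg)
  calendar <- simulate_calendar(cfg)
  dates <- calendar$dates
  n <- cfg$n_hens
  doa <- 175 + seq_len(cfg$n_days) - 1          # day of age per tracked day
  dib <- doa - 119                              # days in barn
  rho <- cfg$type_ar1 %||% 1
  u_arr <- with_seed(derive_seed(cfg$seed, "types"), {
    u0 <- MASS::mvrnorm(n, rep(0, 5), cfg$sigma_A)
    if (n == 1L) u0 <- matrix(u0, nrow = 1)
    arr <- array(NA_real_, c(n, cfg$n_days, 5))
    arr[, 1, ] <- u0
    if (rho < 1 && cfg$n_days > 1L) {
      for (j in 2:cfg$n_days) {
        eps <- MASS::mvrnorm(n, rep(0, 5), cfg$sigma_A)
        if (n == 1L) eps <- matrix(eps, nrow = 1)
        arr[, j, ] <- rho * arr[, j - 1, ] + sqrt(1 - rho^2) * eps
      }
    } else if (cfg$n_days > 1L) {
      for (j in 2:cfg$n_days) arr[, j, ] <- u0
    }
    arr
  })
  u <- matrix(u_arr[, 1, ], nrow = n, dimnames = list(NULL, TRAITS))
  # per-hen interpolated covariates, then z-scaled across the table
  interp_rows <- function(col) {
    m <- vapply(seq_len(n), function(i)
      interpolate_covariate(profiles[[col]][[i]][, 1],
                            profiles[[col]][[i]][, 2], doa),
      numeric(cfg$n_days))
    matrix(m, nrow = n, ncol = cfg$n_days, byrow = TRUE)
  }
  kbf <- interp_rows("kbf_assessments")
  mass <- interp_rows("mass_assessments")
  idx_hen <- rep(seq_len(n), each = cfg$n_days)
  idx_day <- rep(seq_len(cfg$n_days), times = n)
  zscale <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  X <- data.frame(
    days_in_barn = zscale(dib[idx_day]),
    kbf = zscale(kbf[cbind(idx_hen, idx_day)]),
    mass = zscale(mass[cbind(idx_hen, idx_day)]),
    classLEXP = as.numeric(profiles$class[idx_hen] == "LEXP"),
    treatmentTRAN = as.numeric(profiles$treatment[idx_hen] == "TRAN"),
    feed_chainB = as.numeric(profiles$feed_chain[idx_hen] == "B"))
  eta <- matrix(0, length(idx_hen), 5, dimnames = list(NULL, TRAITS))
  for (k in seq_along(TRAITS)) {
    b <- cfg$beta[[TRAITS[k]]]
    xb <- if (length(b)) as.matrix(X[, names(b), drop = FALSE]) %*% b else 0
    eta[, TRAITS[k]] <- cfg$means[[TRAITS[k]]] + xb +
      u_arr[cbind(idx_hen, idx_day, k)]
  }
  tab <- with_seed(derive_seed(cfg$seed, "responses"), {
    out <- data.frame(
      hen_id = profiles$hen_id[idx_hen],
      date = dates[idx_day],
      vtd = stats::rnorm(length(idx_hen), eta[, "vtd"],
                         sqrt(cfg$resid_var[["vtd"]])),
      fdr = stats::rnorm(length(idx_hen), eta[, "fdr"],
                         sqrt(cfg$resid_var[["fdr"]])),
      nest_timing = stats::rgamma(length(idx_hen), shape = cfg$nest_shape,
                                  rate = cfg$nest_shape / exp(eta[, "nest_timing"])),
      wg = stats::rbinom(length(idx_hen), 1, stats::plogis(eta[, "wg"])),
      sleep_top = stats::rbinom(length(idx_hen), 1,
                                stats::plogis(eta[, "sleep_top"])),
      stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(out)) >= cfg$prob_missing
    out[keep, , drop = FALSE]
  })
  covars <- data.frame(
    pen = profiles$pen[idx_hen], feed_chain = profiles$feed_chain[idx_hen],
    class = profiles$class[idx_hen], treatment = profiles$treatment[idx_hen],
    days_in_barn = dib[idx_day],
    kbf = kbf[cbind(idx_hen, idx_day)], mass = mass[cbind(idx_hen, idx_day)])
  tab <- cbind(tab, covars[rownames(tab), , drop = FALSE])
  rownames(tab) <- NULL
  va <- diag(cfg$sigma_A)
  vr <- c(vtd = unname(cfg$resid_var[["vtd"]]),
          fdr = unname(cfg$resid_var[["fdr"]]),
          nest_timing = trigamma(cfg$nest_shape),
          wg = pi^2 / 3, sleep_top = pi^2 / 3)
  corr_A <- if (all(diag(cfg$sigma_A) > 0)) stats::cov2cor(cfg$sigma_A) else
    matrix(NA_real_, 5, 5, dimnames = dimnames(cfg$sigma_A))
  truth <- list(u = u, sigma_A = cfg$sigma_A,
                corr_A = corr_A,
                v_within = vr, R = va / (va + vr[TRAITS]))
  list(behaviours = tab, profiles = profiles, calendar = calendar,
       truth = truth)
}
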