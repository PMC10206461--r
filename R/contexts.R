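# Analysis-day selection: four contexts, the over-time Saturday series,
# and monotone interpolation of time-varying health covariates.

#' Select analysis days for the four contexts and the over-time series
#'
#' Contexts follow the study design: `EARLY` / `LATE` are the Saturdays of
#' the first / last three weeks of the tracking span; `COLD` days are the
#' first day of each of the first three runs of consecutive days whose mean
#' hourly external temperature is negative throughout the winter-garden
#' hours; `VACCINATION` days are the three vaccination dates. Any day that
#' fits more than one context is excluded from all of them, and each fixed
#' context must end up with exactly three days. `OVER_TIME` contains the
#' Saturdays that fit no context (Saturdays are used to limit day-to-day
#' autocorrelation and non-staff disturbance).
#'
#' @param dates tracked dates (the tracking span).
#' @param temperature `data.frame` with `date`, `hour`, `temp_c` covering
#'   at least the winter-garden hours of every day.
#' @param vaccination_dates the three vaccination dates.
#' @param schedule a [day_schedule()] (supplies the winter-garden hours).
#' @return named list of date vectors (`EARLY`, `LATE`, `COLD`,
#'   `VACCINATION`, `OVER_TIME`) with attribute `excluded` (multi-context
#'   days).
#' @export
select_context_days <- function(dates, temperature, vaccination_dates,
                                schedule = day_schedule()) {
  dates <- sort(as.Date(dates))
  sat <- dates[format(dates, "%u") == "6"]
  h0 <- schedule$wg_open %/% 3600
  h1 <- (schedule$wg_close - 1) %/% 3600
  tt <- temperature[temperature$hour >= h0 & temperature$hour <= h1, ]
  if (!all(dates %in% tt$date))
    stop("temperature series must cover the winter-garden hours of all days")
  neg <- tapply(tt$temp_c, tt$date, function(x) all(x < 0))
  cold_q <- as.Date(names(neg))[neg]
  cold_q <- sort(cold_q[cold_q %in% dates])
  fits <- list(
    EARLY = sat[sat <= dates[1] + 20],
    LATE = sat[sat >= dates[length(dates)] - 20],
    COLD = cold_q,
    VACCINATION = as.Date(vaccination_dates))
  all_days <- sort(unique(as.Date(unlist(fits, use.names = FALSE),
                                  origin = "1970-01-01")))
  n_fit <- sapply(all_days, function(d)
    sum(vapply(fits, function(f) d %in% f, logical(1))))
  excluded <- all_days[n_fit > 1]
  fits <- lapply(fits, function(f) f[!f %in% excluded])
  # cold context: first day of each of the first three qualifying runs
  if (length(fits$COLD)) {
    run_start <- fits$COLD[c(TRUE, diff(fits$COLD) > 1)]
    fits$COLD <- run_start[seq_len(min(3L, length(run_start)))]
  }
  for (nm in names(fits)) {
    if (length(fits[[nm]]) < 3L)
      stop(sprintf("context %s has only %d qualifying day(s); need 3",
                   nm, length(fits[[nm]])))
    fits[[nm]] <- fits[[nm]][seq_len(3L)]
  }
  selected <- as.Date(unlist(fits, use.names = FALSE), origin = "1970-01-01")
  over <- sat[!sat %in% c(selected, excluded, cold_q,
                          as.Date(vaccination_dates))]
  out <- c(fits, list(OVER_TIME = over))
  attr(out, "excluded") <- excluded
  out
}

#' One representative observation per hen and context
#'
#' For the across-context repeatability each hen contributes a single
#' hen-day per context: by default the middle (second) of the three context
#' days, falling back to the nearest tracked context day when the hen was
#' not tracked on it (ties resolved toward the earlier day). Hens tracked
#' on no day of a context are omitted for that context and listed in the
#' `omitted` attribute.
#'
#' @param behaviours a behaviour table (one row per tracked hen-day).
#' @param contexts output of [select_context_days()].
#' @param pick `"middle"` (default) or `"first"`: the preferred day.
#' @return the behaviour rows used, with added columns `context` and
#'   `day_used`.
#' @export
across_context_observations <- function(behaviours, contexts,
                                        pick = c("middle", "first")) {
  pick <- match.arg(pick)
  fixed <- c("EARLY", "LATE", "COLD", "VACCINATION")
  omitted <- character()
  rows <- list()
  for (ctx in fixed) {
    days <- sort(contexts[[ctx]])
    pref <- if (pick == "middle") days[2] else days[1]
    sub <- behaviours[behaviours$date %in% days, , drop = FALSE]
    for (hen in unique(behaviours$hen_id)) {
      hs <- sub[sub$hen_id == hen, , drop = FALSE]
      if (!nrow(hs)) {
        omitted <- c(omitted, paste0(hen, ":", ctx))
        next
      }
      d <- hs$date[order(abs(as.numeric(hs$date - pref)), hs$date)][1]
      row <- hs[hs$date == d, , drop = FALSE]
      row$context <- ctx
      row$day_used <- d
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Monotone linear interpolation of assessment covariates
#'
#' Keel-bone-fracture severity and body mass trend upward over the
#' production period; repeated assessments are interpolated through a
#' monotone nondecreasing envelope (decreasing segments are flattened to
#' the running maximum) with linear interpolation between assessment ages
#' and constant extrapolation outside the assessed range.
#'
#' @param ages strictly increasing assessment ages.
#' @param values assessed values.
#' @param query_ages ages at which to evaluate.
#' @return interpolated values, nondecreasing in age.
#' @export
interpolate_covariate <- function(ages, values, query_ages) {
  stopifnot(length(ages) == length(values))
  if (length(ages) < 2L) {
    warning("single assessment: covariate treated as constant")
    return(rep(values[1], length(query_ages)))
  }
  if (any(diff(ages) <= 0)) stop("assessment ages must be strictly increasing")
  env <- cummax(values)
  stats::approx(ages, env, xout = query_ages, rule = 2)$y
}
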