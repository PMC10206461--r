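# The five daily spatial behaviours, extracted from occupancy intervals.
#
# All extractors take the occupancy intervals of a SINGLE hen (any rows for
# other hens must be filtered out beforehand; extract_all() does this) plus
# the schedule and a calendar date. The behavioural day runs 00:00-24:00
# local; the night used for the sleeping-tier behaviour is attributed to
# the day on which it starts.

#' Mean vertical travelled distance per hour
#'
#' Number of indoor zones crossed per eligible hour on a day. The eligible
#' window is the lights-on phase minus the dawn and dusk phases; time spent
#' in the winter garden is removed from the denominator, and transitions
#' into or out of the winter garden contribute no vertical distance (only
#' the four indoor zones are stacked). A transition's distance is the
#' absolute difference of the two vertical levels, so a direct
#' floor-to-top-tier move counts 3 crossed zones.
#'
#' @param intervals one hen's occupancy intervals.
#' @param schedule a [day_schedule()].
#' @param date calendar date.
#' @return zones crossed per hour, or `NA` if no eligible time remains.
#' @export
vertical_travelled_distance <- function(intervals, schedule, date) {
  d0 <- day_start(date)
  w0 <- d0 + schedule$lights_on + schedule$dawn_s
  w1 <- d0 + schedule$lights_off - schedule$dusk_s
  iv <- intervals[order(intervals$start), , drop = FALSE]
  lev <- zone_levels()
  n <- nrow(iv)
  crossed <- 0
  if (n >= 2L) {
    tt <- as.numeric(iv$end[-n])          # boundary times
    contiguous <- tt == as.numeric(iv$start[-1])
    inwin <- contiguous & tt >= as.numeric(w0) & tt < as.numeric(w1)
    from <- lev[iv$zone[-n]]
    to <- lev[iv$zone[-1]]
    d <- abs(to - from)
    d[is.na(d)] <- 0                      # WG-involving transitions
    crossed <- sum(d[inwin])
  }
  wg_secs <- time_in_zones(iv, w0, w1, "WG")
  elig_h <- (as.numeric(w1) - as.numeric(w0) - wg_secs) / 3600
  if (elig_h <= 0) return(NA_real_)
  crossed / elig_h
}

#' Winter garden presence
#'
#' 1 if the hen entered the winter garden at any point of the day, else 0.
#' @inheritParams vertical_travelled_distance
#' @return 0/1.
#' @export
wg_presence <- function(intervals, schedule, date) {
  d0 <- day_start(date)
  as.integer(time_in_zones(intervals, d0, d0 + 86400, "WG") > 0)
}

#' Nestbox tier timing
#'
#' The clock time (decimal hours) at which the hen first accumulated half
#' of its total nestbox-tier occupancy within the expected laying window
#' (02:00-08:00). Missing when the hen never used the nestbox tier in that
#' window. The value lies in (2, 8] and is treated as a positively skewed
#' gamma response downstream.
#'
#' @inheritParams vertical_travelled_distance
#' @return decimal clock hours in (2, 8], or `NA`.
#' @export
nestbox_tier_timing <- function(intervals, schedule, date) {
  d0 <- day_start(date)
  w0 <- as.numeric(d0) + schedule$nest_start
  w1 <- as.numeric(d0) + schedule$nest_end
  iv <- intervals[intervals$zone == "NESTBOX", , drop = FALSE]
  if (!nrow(iv)) return(NA_real_)
  s <- pmax(as.numeric(iv$start), w0)
  e <- pmin(as.numeric(iv$end), w1)
  keep <- e > s
  if (!any(keep)) return(NA_real_)
  o <- order(s[keep])
  e <- e[keep][o]
  s <- s[keep][o]
  len <- e - s
  total <- sum(len)
  half <- total / 2
  cum <- cumsum(len)
  i <- which(cum >= half)[1]
  t_half <- s[i] + (half - if (i > 1L) cum[i - 1L] else 0)
  (t_half - as.numeric(d0)) / 3600
}

#' Sleeping tier
#'
#' 1 if the hen spent strictly more than half of the night on the top tier.
#' The night of day *d* runs from lights-off on *d* to lights-on on *d*+1
#' (the dusk phase precedes lights-off and is therefore excluded), and is
#' attributed to day *d*.
#'
#' @inheritParams vertical_travelled_distance
#' @param min_coverage minimum fraction of the night that must be tracked;
#'   below it the behaviour is missing.
#' @return 0/1, or `NA` for an untracked night.
#' @export
sleeping_top <- function(intervals, schedule, date, min_coverage = 0.95) {
  d0 <- day_start(date)
  n0 <- d0 + schedule$lights_off
  n1 <- d0 + 86400 + schedule$lights_on
  night_len <- as.numeric(n1) - as.numeric(n0)
  tracked <- time_in_zones(intervals, n0, n1, zone_names())
  if (tracked < min_coverage * night_len) return(NA_integer_)
  top <- time_in_zones(intervals, n0, n1, "TOP")
  as.integer(top > 0.5 * night_len)
}

#' Feed-response configuration
#'
#' Settings of the comparison-window resampling behind the feed delivery
#' response: number of random comparison windows per delivery (50), the
#' surround within which they are drawn (1 h on each side of the delivery),
#' and the buffer around the delivery that they must avoid (15 min on each
#' side). `exhaustive = TRUE` replaces the random draws with every eligible
#' window start on a 1-second grid and is the statistic's oracle.
#'
#' @param n_comparison_windows integer, random windows per delivery.
#' @param surround_hours numeric hours.
#' @param buffer_minutes numeric minutes; must be smaller than the surround.
#' @param rng_seed integer seed of the per-hen-day draw streams.
#' @param exhaustive logical.
#' @return a list of class `feed_response_config`.
#' @export
feed_response_config <- function(n_comparison_windows = 50L,
                                 surround_hours = 1, buffer_minutes = 15,
                                 rng_seed = 1L, exhaustive = FALSE) {
  stopifnot(n_comparison_windows >= 1L,
            buffer_minutes * 60 < surround_hours * 3600)
  structure(list(n = as.integer(n_comparison_windows),
                 surround_s = surround_hours * 3600,
                 buffer_s = buffer_minutes * 60,
                 rng_seed = as.integer(rng_seed),
                 exhaustive = isTRUE(exhaustive)),
            class = "feed_response_config")
}

# Piecewise-linear cumulative feed-tier occupancy; returns a function C(t)
# with t in seconds (numeric POSIX time).
feed_tier_cumulator <- function(intervals) {
  iv <- intervals[intervals$zone %in% feed_tiers(), , drop = FALSE]
  if (!nrow(iv)) return(function(t) rep(0, length(t)))
  s <- as.numeric(iv$start); e <- as.numeric(iv$end)
  o <- order(s); s <- s[o]; e <- e[o]
  knots <- sort(unique(c(s, e)))
  # cumulative occupancy at each knot
  cum <- vapply(knots, function(t) sum(pmax(0, pmin(e, t) - s)), numeric(1))
  function(t) stats::approx(knots, cum, xout = t, rule = 2)$y
}

# Eligible comparison-window starts (1-s grid) for one delivery [p0, p1).
eligible_starts <- function(p0, p1, all_p0, all_p1, cfg) {
  dur <- p1 - p0
  s <- seq(p0 - cfg$surround_s, p1 + cfg$surround_s - dur)
  # must not intersect the delivery expanded by the buffer on each side
  s <- s[s + dur <= p0 - cfg$buffer_s | s >= p1 + cfg$buffer_s]
  # must not intersect any other delivery window
  for (k in seq_along(all_p0)) {
    if (all_p0[k] == p0) next
    s <- s[s + dur <= all_p0[k] | s >= all_p1[k]]
  }
  s
}

#' Feed delivery response
#'
#' A per-day statistic in \[-1, 1\] contrasting feed-tier occupancy during
#' the six 3-min feed deliveries against matched comparison windows of the
#' same duration drawn nearby (within 1 h of the delivery, outside a 15-min
#' buffer around it, and not overlapping any other delivery). For each
#' delivery *p* with feed-tier time `T_p` and each comparison window with
#' feed-tier time `T_pr`, the contrast is `(T_p - T_pr) / (T_p + T_pr)`
#' (defined as 0 when both are 0); contrasts are averaged over the 50
#' comparison windows and then over the deliveries. Positive values mean
#' the hen is in a feed tier more when fresh feed arrives.
#'
#' @inheritParams vertical_travelled_distance
#' @param cfg a [feed_response_config()].
#' @param hen_id optional identifier used (with the date) to derive the
#'   per-hen-day comparison-draw stream; defaults to the hen of the first
#'   interval row.
#' @return the response in \[-1, 1\], or `NA` if some delivery has no
#'   eligible comparison window.
#' @export
feed_delivery_response <- function(intervals, schedule, date,
                                   cfg = feed_response_config(),
                                   hen_id = NULL) {
  false_timing_response(intervals, schedule, date, shift_minutes = 0,
                        cfg = cfg, hen_id = hen_id)
}

#' Feed delivery response under shifted (false) delivery timing
#'
#' Identical to [feed_delivery_response()] but with every delivery start
#' shifted by `shift_minutes` (negative = earlier). Comparing the true
#' statistic with its values at +/-20 min verifies that the response is
#' driven by the actual delivery times rather than by general daily
#' occupancy rhythm.
#'
#' @inheritParams feed_delivery_response
#' @param shift_minutes signed shift applied to every delivery start.
#' @export
false_timing_response <- function(intervals, schedule, date, shift_minutes,
                                  cfg = feed_response_config(),
                                  hen_id = NULL) {
  d0 <- as.numeric(day_start(date))
  p0 <- d0 + schedule$feed_starts + shift_minutes * 60
  p1 <- p0 + schedule$feed_duration_s
  C <- feed_tier_cumulator(intervals)
  if (is.null(hen_id)) hen_id <- intervals$hen_id[1] %||% "hen"
  seed <- derive_seed(cfg$rng_seed, hen_id, as.Date(date), shift_minutes)
  dur <- schedule$feed_duration_s
  per_delivery <- with_seed(seed, {
    vapply(seq_along(p0), function(k) {
      elig <- eligible_starts(p0[k], p1[k], p0, p1, cfg)
      if (!length(elig)) return(NA_real_)
      starts <- if (cfg$exhaustive) elig else
        elig[sample.int(length(elig), cfg$n, replace = TRUE)]
      T_p <- C(p0[k] + dur) - C(p0[k])
      T_pr <- C(starts + dur) - C(starts)
      tot <- T_p + T_pr
      terms <- ifelse(tot == 0, 0, (T_p - T_pr) / tot)
      mean(terms)
    }, numeric(1))
  })
  if (anyNA(per_delivery)) return(NA_real_)
  mean(per_delivery)
}

#' Extract all five behaviours for every tracked hen-day
#'
#' A hen-day is considered tracked when its occupancy intervals cover at
#' least `min_coverage` of the 24-h day; untracked hen-days are omitted.
#' Within a tracked day individual behaviours can still be missing (no
#' nestbox use, untracked night) and are propagated as `NA`, never imputed.
#'
#' @param intervals occupancy intervals for any number of hens.
#' @param schedule a [day_schedule()].
#' @param dates vector of calendar dates.
#' @param cfg a [feed_response_config()].
#' @param min_coverage minimum tracked fraction of the day (default 0.95).
#' @return `data.frame` with one row per tracked hen-day: `hen_id`, `date`,
#'   `vtd`, `wg`, `nest_timing`, `sleep_top`, `fdr`.
#' @export
extract_all <- function(intervals, schedule, dates,
                        cfg = feed_response_config(), min_coverage = 0.95) {
  dates <- as.Date(dates)
  by_hen <- split(intervals, intervals$hen_id)
  rows <- list()
  for (hen in names(by_hen)) {
    iv <- by_hen[[hen]]
    for (d in seq_along(dates)) {
      date <- dates[d]
      if (day_coverage(iv, date) < min_coverage) next
      rows[[length(rows) + 1L]] <- data.frame(
        hen_id = hen, date = date,
        vtd = vertical_travelled_distance(iv, schedule, date),
        wg = wg_presence(iv, schedule, date),
        nest_timing = nestbox_tier_timing(iv, schedule, date),
        sleep_top = sleeping_top(iv, schedule, date),
        fdr = feed_delivery_response(iv, schedule, date, cfg, hen_id = hen),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hen_id = character(), date = as.Date(character()),
               vtd = numeric(), wg = integer(), nest_timing = numeric(),
               sleep_top = integer(), fdr = numeric())
  rownames(out) <- NULL
  out
}

#' Write / read a daily-behaviour table as CSV
#' @param behaviours a behaviour table from [extract_all()].
#' @param path file path.
#' @export
write_behaviours <- function(behaviours, path) {
  utils::write.csv(behaviours, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_behaviours
#' @export
read_behaviours <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$date <- as.Date(out$date)
  out$hen_id <- as.character(out$hen_id)
  out
}
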