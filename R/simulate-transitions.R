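# Trajectory-level simulator: builds per-hen-day itineraries on a 60-s grid
# that realize targeted behaviour values, and emits the resulting
# zone-transition stream. Used to validate the extraction stage end-to-end.

#' Simulate a zone-transition stream realizing behaviour targets
#'
#' For every hen-day in `targets`, builds a minute-resolution itinerary:
#' the night (lights-off to next lights-on) is spent on `TOP` when
#' `sleep_top = 1` and on `LOWER` otherwise; a nestbox residence is placed
#' so that its half-occupancy time equals `nest_timing` (within the 60-s
#' grid); a winter-garden excursion (11:00-11:30) occurs iff `wg = 1`;
#' short floor-to-lower-tier visits are scheduled so that crossings per
#' eligible hour match `vtd` (rounded to the nearest feasible crossing
#' count); and the hen occupies a feed tier throughout a delivery window
#' with probability `attraction` (its feed-attraction parameter), which
#' maps a positive feed-delivery-response tendency onto the stream.
#'
#' Moves between the day baseline and the night roost happen inside the
#' dawn/dusk phases so they do not enter the vertical-distance count.
#' Infeasible targets (e.g. a `vtd` too small to accommodate the mandatory
#' nestbox visit) are realized as closely as possible and reported in the
#' `adjustments` attribute.
#'
#' @param targets `data.frame` with columns `hen_id`, `date`, `sleep_top`
#'   (0/1), `wg` (0/1), `vtd` (zones/h), `nest_timing` (clock hours in
#'   (2,8\] or `NA`) and `attraction` (0-1).
#' @param schedule a [day_schedule()].
#' @param seed integer; drives the attraction draws and visit placement.
#' @return a transitions `data.frame` (as from [read_transitions()])
#'   covering `[00:00` of the first date, `02:00` after the last\], with
#'   attributes `itinerary` (the realized per-hen-day targets) and
#'   `adjustments` (character vector of per-hen-day warnings).
#' @export
simulate_transitions <- function(targets, schedule = day_schedule(),
                                 seed = 1L) {
  stopifnot(all(c("hen_id", "date", "sleep_top", "wg", "vtd",
                  "nest_timing", "attraction") %in% names(targets)))
  targets$date <- as.Date(targets$date)
  adjustments <- character()
  realized <- list()
  streams <- list()
  for (hen in unique(targets$hen_id)) {
    th <- targets[targets$hen_id == hen, , drop = FALSE]
    th <- th[order(th$date), , drop = FALSE]
    res <- simulate_hen_itinerary(hen, th, schedule, seed)
    streams[[hen]] <- res$transitions
    realized[[hen]] <- res$realized
    adjustments <- c(adjustments, res$adjustments)
  }
  out <- do.call(rbind, streams)
  rownames(out) <- NULL
  attr(out, "itinerary") <- do.call(rbind, realized)
  attr(out, "adjustments") <- adjustments
  out
}

# Minute-grid itinerary for one hen across consecutive target days.
simulate_hen_itinerary <- function(hen, th, schedule, seed) {
  dates <- th$date
  if (any(diff(as.integer(dates)) != 1L))
    stop("target dates must be consecutive for hen ", hen)
  n_days <- nrow(th)
  total_min <- n_days * 1440L + 120L       # through 02:00 after last day
  zones <- character(total_min)
  adjustments <- character()
  realized <- th
  realized$crossings <- NA_integer_
  feed_min <- as.integer(schedule$feed_starts %/% 60)
  feed_len <- as.integer(schedule$feed_duration_s %/% 60)
  dawn_end <- as.integer((schedule$lights_on + schedule$dawn_s) %/% 60)   # 135
  dusk_start <- as.integer((schedule$lights_off - schedule$dusk_s) %/% 60) # 1005
  night_zone_prev <- if (th$sleep_top[1] == 1) "TOP" else "LOWER"
  for (d in seq_len(n_days)) {
    off <- (d - 1L) * 1440L
    day <- rep("FLOOR", 1440L)
    sleep_zone <- if (th$sleep_top[d] == 1) "TOP" else "LOWER"
    # [00:00, 02:05): previous night's roost; move to floor during dawn
    day[1:125] <- night_zone_prev
    # [16:50, 24:00): tonight's roost (move happens inside dusk)
    day[1011:1440] <- sleep_zone
    blocked <- rep(FALSE, 1440L)           # minutes osc visits must avoid
    blocked[1:135] <- TRUE
    blocked[(dusk_start - 2):1440] <- TRUE
    # nestbox residence with half-time at the target; entries/exits inside
    # the dawn phase are not vertical-distance crossings, so count only the
    # boundaries that fall in the eligible window
    nest_crossings <- 0L
    if (!is.na(th$nest_timing[d])) {
      w <- min(0.25, 8 - th$nest_timing[d], th$nest_timing[d] - 2)
      w <- max(w, 1 / 60)
      lo <- max(120L, as.integer(round((th$nest_timing[d] - w) * 60)))
      hi <- min(480L, as.integer(round((th$nest_timing[d] + w) * 60)))
      if (hi <= lo) hi <- lo + 1L
      day[(lo + 1):hi] <- "NESTBOX"
      blocked[max(1, lo - 2):min(1440, hi + 2)] <- TRUE
      nest_crossings <- 2L * (lo >= dawn_end) + 2L * (hi >= dawn_end)
    }
    # winter-garden excursion 11:00-11:30
    if (th$wg[d] == 1) {
      day[661:690] <- "WG"
      blocked[658:692] <- TRUE
    }
    # feed attraction: full occupancy of qualifying delivery windows
    seed_d <- derive_seed(seed, hen, dates[d])
    visited <- with_seed(seed_d,
                         stats::runif(length(feed_min)) < th$attraction[d])
    for (k in seq_along(feed_min)) {
      fm <- feed_min[k]
      idx <- (fm + 1):(fm + feed_len)
      if (any(blocked[idx])) { visited[k] <- FALSE; next }
      if (visited[k]) {
        day[idx] <- "LOWER"
        blocked[max(1, fm - 1):min(1440, fm + feed_len + 1)] <- TRUE
      }
    }
    n_attract <- sum(visited)
    # crossing budget -> number of extra floor<->lower visits
    elig_h <- (dusk_start - dawn_end) / 60 - ifelse(th$wg[d] == 1, 0.5, 0)
    n_target <- as.integer(round(th$vtd[d] * elig_h))
    mandatory <- nest_crossings + 2L * n_attract
    rem <- n_target - mandatory
    if (rem < 0L) {
      adjustments <- c(adjustments, sprintf(
        "%s %s: vtd target %.2f below mandatory %d crossings",
        hen, format(dates[d]), th$vtd[d], mandatory))
      rem <- 0L
    }
    n_osc <- rem %/% 2L
    # odd remainders need one unpaired crossing: a late visit to the lower
    # tier that lasts until the dusk move (which itself is never counted)
    tail_start <- as.integer((max(schedule$feed_starts) +
                                schedule$feed_duration_s) %/% 60 + 4L)
    if (rem %% 2L == 1L) {
      day[(tail_start + 1):(dusk_start + 6)] <- "LOWER"
      blocked[tail_start:min(1440L, dusk_start + 7L)] <- TRUE
    }
    placed <- 0L
    if (n_osc > 0L) {
      cand <- which(!blocked)
      cand <- cand[cand >= dawn_end + 2 & cand <= dusk_start - 4]
      cand <- with_seed(seed_d + 1L, sample(cand))
      for (s in cand) {
        if (placed >= n_osc) break
        idx <- s:(s + 1)                   # 2-minute visit
        guard <- max(1, s - 1):min(1440, s + 2)
        if (any(blocked[guard])) next
        day[idx] <- "LOWER"
        blocked[guard] <- TRUE
        placed <- placed + 1L
      }
      if (placed < n_osc)
        adjustments <- c(adjustments, sprintf(
          "%s %s: placed %d of %d extra visits", hen, format(dates[d]),
          placed, n_osc))
    }
    realized$crossings[d] <- mandatory + 2L * placed + (rem %% 2L)
    zones[off + 1:1440] <- day
    night_zone_prev <- sleep_zone
  }
  zones[n_days * 1440L + 1:120] <- night_zone_prev
  # run-length encode into a transition stream
  r <- rle(zones)
  t_min <- c(0L, cumsum(r$lengths)[-length(r$lengths)])
  t0 <- day_start(dates[1])
  tr <- data.frame(hen_id = hen, timestamp = t0 + t_min * 60,
                   zone = r$values, stringsAsFactors = FALSE)
  list(transitions = tr, realized = realized, adjustments = adjustments)
}

#' Draw behaviour targets for the trajectory simulator
#'
#' Convenience wrapper: draws a behaviour table from the statistical
#' generator and maps it onto trajectory targets (`fdr` tendency mapped to
#' a feed-attraction probability `pmin(1, pmax(0, 2 * fdr))`; `vtd` clipped
#' to be nonnegative).
#'
#' @param cfg a [flock_config()].
#' @return a targets `data.frame` suitable for [simulate_transitions()].
#' @export
behaviour_targets <- function(cfg) {
  sim <- simulate_behaviour_table(cfg)
  b <- sim$behaviours
  data.frame(hen_id = b$hen_id, date = b$date,
             sleep_top = b$sleep_top, wg = b$wg,
             vtd = pmax(0, b$vtd),
             nest_timing = pmin(7.95, pmax(2.05, b$nest_timing)),
             attraction = pmin(1, pmax(0, 2 * b$fdr)),
             stringsAsFactors = FALSE)
}
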