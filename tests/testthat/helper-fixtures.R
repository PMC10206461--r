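# Fixtures built in code: constructed days, toy transition streams and
# small flock configurations shared across test files.

SCHED <- day_schedule()
DAY <- as.Date("2021-01-05")
D0 <- aviarytraits:::day_start(DAY)

# a transition stream for one hen on DAY from (time-offset-seconds, zone)
# pairs; the first pair should start at 0 so the day is fully covered
make_transitions <- function(times, zones, hen = "h1", day = DAY) {
  data.frame(hen_id = hen, timestamp = aviarytraits:::day_start(day) + times,
             zone = zones, stringsAsFactors = FALSE)
}

make_intervals <- function(times, zones, hen = "h1", day = DAY,
                           span_days = 1) {
  d0 <- aviarytraits:::day_start(day)
  to_intervals(make_transitions(times, zones, hen, day),
               d0, d0 + span_days * 86400)
}

# day in which the hen is in a feed tier exactly during every delivery
# (reverse = TRUE: outside feed tiers at deliveries, inside otherwise)
delivery_contrast_day <- function(reverse = FALSE) {
  t <- 0; z <- "FLOOR"
  for (fs in SCHED$feed_starts) {
    t <- c(t, fs, fs + SCHED$feed_duration_s)
    z <- c(z, "LOWER", "FLOOR")
  }
  if (reverse) z <- ifelse(z == "FLOOR", "LOWER", "FLOOR")
  make_intervals(t, z)
}

# stationary random occupancy alternating FLOOR/LOWER with exponential
# holding times: feed-tier occupancy independent of the delivery schedule
random_occupancy_day <- function(hen, day, mean_stay_s = 900) {
  t <- 0
  while (t[length(t)] < 86400) {
    t <- c(t, t[length(t)] + stats::rexp(1, 1 / mean_stay_s))
  }
  t <- floor(t[t < 86400])
  t <- t[!duplicated(t)]
  z <- rep(c("FLOOR", "LOWER"), length.out = length(t))
  make_intervals(t, z, hen = hen, day = day)
}

# tiny flock config used by several statistical tests
tiny_flock <- function(n_hens = 40, n_days = 12, seed = 7, ...) {
  flock_config(n_hens = n_hens, n_days = n_days, seed = seed,
               prob_missing = 0, ...)
}

# diagonal among-individual covariance with chosen variances
diag_sigma <- function(vtd = 0.5, fdr = 0.015, nest_timing = 0.037,
                       wg = 2.19, sleep_top = 3.29) {
  diag(c(vtd, fdr, nest_timing, wg, sleep_top))
}
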