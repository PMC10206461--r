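# Extraction of the five daily behaviours from constructed days.

test_that("vertical travelled distance counts level differences per eligible hour", {
  # no transitions all day
  expect_equal(vertical_travelled_distance(make_intervals(0, "FLOOR"),
                                           SCHED, DAY), 0)
  # a single floor-to-top move: 3 levels over 14.5 eligible hours
  iv <- make_intervals(c(0, 36000), c("FLOOR", "TOP"))
  expect_equal(vertical_travelled_distance(iv, SCHED, DAY), 3 / 14.5)
  # dawn/dusk moves are excluded; WG time shrinks the denominator and
  # WG-involving transitions count zero
  iv <- make_intervals(c(0, 7500, 36000, 37800, 50400, 60000),
                       c("TOP", "FLOOR", "WG", "FLOOR", "LOWER", "TOP"))
  # counted: WG moves 0 + FLOOR->LOWER (1) at 14:00; TOP->FLOOR at 02:05 is
  # in dawn and 16:40 LOWER->TOP is inside the window (1 + 2)
  # eligible hours: 14.5 - 0.5 h in WG
  expect_equal(vertical_travelled_distance(iv, SCHED, DAY), 3 / 14)
  # oracle recount on a scripted itinerary
  set.seed(42)
  times <- sort(sample(seq(9000, 59000, by = 60), 20))
  zones <- character(20)
  pool <- c("FLOOR", "LOWER", "NESTBOX", "TOP")
  zones[1] <- "FLOOR"
  for (i in 2:20) zones[i] <- sample(setdiff(pool, zones[i - 1]), 1)
  iv <- make_intervals(c(0, times), c("TOP", zones))
  lev <- zone_levels()
  w0 <- 2.25 * 3600; w1 <- 16.75 * 3600
  hand <- sum(abs(diff(lev[c("TOP", zones)]))[times >= w0 & times < w1])
  expect_equal(vertical_travelled_distance(iv, SCHED, DAY), hand / 14.5)
})

test_that("vtd depends only on transition counts inside the eligible window", {
  # relabelling the times of the same transitions within the window leaves
  # the value unchanged
  iv1 <- make_intervals(c(0, 30000, 40000), c("FLOOR", "TOP", "FLOOR"))
  iv2 <- make_intervals(c(0, 20000, 55000), c("FLOOR", "TOP", "FLOOR"))
  expect_equal(vertical_travelled_distance(iv1, SCHED, DAY),
               vertical_travelled_distance(iv2, SCHED, DAY))
})

test_that("winter-garden presence flags any WG entry", {
  expect_equal(wg_presence(make_intervals(c(0, 40000, 40005),
                                          c("FLOOR", "WG", "FLOOR")),
                           SCHED, DAY), 1L)
  expect_equal(wg_presence(make_intervals(0, "TOP"), SCHED, DAY), 0L)
})

test_that("nestbox tier timing inverts the cumulative occupancy step function", {
  # whole window in the nestbox: half of 6 h reached at 05:00
  expect_equal(nestbox_tier_timing(make_intervals(0, "NESTBOX"), SCHED, DAY), 5)
  # single residence 03:00-04:00: midpoint 03:30
  iv <- make_intervals(c(0, 10800, 14400), c("FLOOR", "NESTBOX", "FLOOR"))
  expect_equal(nestbox_tier_timing(iv, SCHED, DAY), 3.5)
  # two residences 02:30-03:00 and 06:00-06:30: cumulative reaches 30 min
  # (half of 60) exactly at 03:00
  iv <- make_intervals(c(0, 9000, 10800, 21600, 23400),
                       c("FLOOR", "NESTBOX", "FLOOR", "NESTBOX", "FLOOR"))
  expect_equal(nestbox_tier_timing(iv, SCHED, DAY), 3)
  # invariant to occupancy outside 02:00-08:00
  iv2 <- make_intervals(c(0, 9000, 10800, 21600, 23400, 36000, 39600),
                        c("FLOOR", "NESTBOX", "FLOOR", "NESTBOX", "FLOOR",
                          "NESTBOX", "FLOOR"))
  expect_equal(nestbox_tier_timing(iv2, SCHED, DAY), 3)
  # no nestbox use: missing
  expect_true(is.na(nestbox_tier_timing(make_intervals(0, "TOP"), SCHED, DAY)))
})

test_that("sleeping tier uses a strict night-time majority on the top tier", {
  expect_equal(sleeping_top(make_intervals(0, "TOP", span_days = 2),
                            SCHED, DAY), 1L)
  expect_equal(sleeping_top(make_intervals(0, "LOWER", span_days = 2),
                            SCHED, DAY), 0L)
  # 4.6 h of a 9 h night on top: 4.6/9 > 0.5
  iv <- make_intervals(c(0, 61200, 61200 + 4.6 * 3600),
                       c("FLOOR", "TOP", "LOWER"), span_days = 2)
  expect_equal(sleeping_top(iv, SCHED, DAY), 1L)
  # exactly half is not a majority
  iv <- make_intervals(c(0, 61200, 61200 + 4.5 * 3600),
                       c("FLOOR", "TOP", "LOWER"), span_days = 2)
  expect_equal(sleeping_top(iv, SCHED, DAY), 0L)
  # untracked night is missing
  expect_true(is.na(sleeping_top(make_intervals(0, "TOP", span_days = 1),
                                 SCHED, DAY)))
})

test_that("feed delivery response attains its bounds and is 0 without contrast", {
  cfg <- feed_response_config(exhaustive = TRUE)
  expect_equal(feed_delivery_response(delivery_contrast_day(), SCHED, DAY, cfg), 1)
  expect_equal(feed_delivery_response(delivery_contrast_day(reverse = TRUE),
                                      SCHED, DAY, cfg), -1)
  # continuously in a feed tier: no contrast, response 0
  expect_equal(feed_delivery_response(make_intervals(0, "LOWER"), SCHED, DAY,
                                      cfg), 0, tolerance = 1e-12)
  # the sampled estimator respects the bounds too
  cfg50 <- feed_response_config(rng_seed = 3)
  expect_equal(feed_delivery_response(delivery_contrast_day(), SCHED, DAY,
                                      cfg50), 1)
})

test_that("false-timing response at shift 0 is the true response", {
  iv <- delivery_contrast_day()
  cfg <- feed_response_config(rng_seed = 11)
  expect_identical(false_timing_response(iv, SCHED, DAY, 0, cfg),
                   feed_delivery_response(iv, SCHED, DAY, cfg))
})

test_that("occupancy independent of the schedule gives a near-zero mean response", {
  set.seed(99)
  cfg <- feed_response_config(rng_seed = 5)
  vals <- vapply(1:40, function(i) {
    iv <- random_occupancy_day(sprintf("h%02d", i), DAY)
    c(feed_delivery_response(iv, SCHED, DAY, cfg, hen_id = sprintf("h%02d", i)),
      false_timing_response(iv, SCHED, DAY, 20, cfg, hen_id = sprintf("h%02d", i)))
  }, numeric(2))
  expect_lt(abs(mean(vals[1, ])), 0.1)
  expect_lt(abs(mean(vals[2, ])), 0.1)
})

test_that("extract_all yields one row per tracked hen-day and propagates NAs", {
  tg <- data.frame(hen_id = rep(c("a", "b"), each = 2),
                   date = rep(DAY + 0:1, 2),
                   sleep_top = c(1, 0, 0, 1), wg = c(1, 0, 0, 1),
                   vtd = c(2, 1, 0.5, 3),
                   nest_timing = c(4, NA, 5, 6), attraction = 0.5)
  tr <- simulate_transitions(tg, SCHED, seed = 2)
  iv <- to_intervals(tr, D0, D0 + 2 * 86400)
  beh <- extract_all(iv, SCHED, DAY + 0:1, feed_response_config(rng_seed = 1))
  expect_equal(nrow(beh), 4L)
  expect_true(is.na(beh$nest_timing[beh$hen_id == "a" & beh$date == DAY + 1]))
  expect_true(all(!is.na(beh$vtd)))
  # a hen with only 1 h of coverage on a day is not a tracked hen-day
  stub <- rbind(iv, data.frame(hen_id = "c", zone = "FLOOR",
                               start = D0, end = D0 + 3600))
  beh2 <- extract_all(stub, SCHED, DAY + 0:1, feed_response_config())
  expect_false("c" %in% beh2$hen_id)
})
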