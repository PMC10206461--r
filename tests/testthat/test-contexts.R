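# Context-day selection, across-context observations and covariate
# interpolation.

# a 13-week calendar with three clean cold spells and mid-week vaccinations
toy_calendar <- function(start = as.Date("2021-01-01"), n_days = 91,
                         spells = list(0:2 + 30, 0:2 + 45, 0:2 + 60),
                         extra_cold = integer()) {
  dates <- seq(start, by = "day", length.out = n_days)
  grid <- expand.grid(hour = 0:23, date = dates)[, c("date", "hour")]
  temp <- rep(5, nrow(grid))
  cold <- dates[unique(c(unlist(spells), extra_cold))]
  temp[grid$date %in% cold & grid$hour >= 8 & grid$hour <= 17] <- -2
  vacc <- dates[c(25, 50, 75)]
  for (i in seq_along(vacc))
    while (format(vacc[i], "%u") == "6" || vacc[i] %in% cold)
      vacc[i] <- vacc[i] + 1
  list(dates = dates,
       temperature = data.frame(date = grid$date, hour = grid$hour,
                                temp_c = temp),
       vaccination_dates = vacc)
}

test_that("context days are selected, disjoint and exactly three each", {
  cal <- toy_calendar()
  ctx <- select_context_days(cal$dates, cal$temperature,
                             cal$vaccination_dates)
  expect_equal(ctx$COLD, cal$dates[c(30, 45, 60)])
  expect_equal(length(ctx$EARLY), 3L)
  expect_true(all(ctx$EARLY <= cal$dates[1] + 20))
  expect_equal(length(ctx$LATE), 3L)
  sel <- c(ctx$EARLY, ctx$LATE, ctx$COLD, ctx$VACCINATION)
  expect_equal(anyDuplicated(sel), 0L)
  expect_true(all(format(ctx$OVER_TIME, "%u") == "6"))
  expect_false(any(ctx$OVER_TIME %in% sel))
})

test_that("cold-qualifying Saturdays never enter the over-time series", {
  cal <- toy_calendar()
  # which mid-period days are Saturdays?
  sat_off <- which(format(cal$dates, "%u") == "6")
  sat_mid <- sat_off[sat_off > 63 & sat_off < 70][1]
  cal2 <- toy_calendar(extra_cold = sat_mid + 0:1)
  ctx <- select_context_days(cal2$dates, cal2$temperature,
                             cal2$vaccination_dates)
  # the spell starting on that Saturday is the fourth run, so the day is
  # cold-qualifying but not a selected context day; it still leaves the
  # over-time series
  expect_false(cal2$dates[sat_mid] %in% ctx$COLD)
  expect_false(cal2$dates[sat_mid] %in% ctx$OVER_TIME)
})

test_that("multi-context days are excluded and shortfalls are hard errors", {
  cal <- toy_calendar()
  # force a vaccination onto an early-stage Saturday: the day leaves both
  # contexts, so the vaccination context cannot reach three days
  sat1 <- cal$dates[format(cal$dates, "%u") == "6"][1]
  cal$vaccination_dates[1] <- sat1
  expect_error(select_context_days(cal$dates, cal$temperature,
                                   cal$vaccination_dates),
               "VACCINATION|EARLY")
  # no negative-temperature days at all
  cal3 <- toy_calendar(spells = list())
  expect_error(select_context_days(cal3$dates, cal3$temperature,
                                   cal3$vaccination_dates), "COLD")
})

test_that("across-context observations use the middle day with fallback", {
  cal <- toy_calendar()
  ctx <- select_context_days(cal$dates, cal$temperature,
                             cal$vaccination_dates)
  all_days <- sort(c(ctx$EARLY, ctx$LATE, ctx$COLD, ctx$VACCINATION))
  full <- expand.grid(hen_id = c("a", "b", "c"), date = all_days,
                      stringsAsFactors = FALSE)
  full$vtd <- 1
  # hen b misses the middle EARLY day; hen c is never tracked early
  drop <- (full$hen_id == "b" & full$date == ctx$EARLY[2]) |
    (full$hen_id == "c" & full$date %in% ctx$EARLY)
  tab <- full[!drop, ]
  obs <- across_context_observations(tab, ctx)
  expect_equal(nrow(obs), 4 + 4 + 3)   # a: 4, b: 4, c: 3
  a_early <- obs[obs$hen_id == "a" & obs$context == "EARLY", ]
  expect_equal(a_early$day_used, ctx$EARLY[2])
  b_early <- obs[obs$hen_id == "b" & obs$context == "EARLY", ]
  expect_true(b_early$day_used %in% ctx$EARLY[c(1, 3)])
  expect_match(attr(obs, "omitted"), "c:EARLY", all = FALSE)
})

test_that("covariate interpolation is monotone with constant extrapolation", {
  expect_equal(interpolate_covariate(c(100, 200), c(10, 20), 150), 15)
  # decreasing segment flattened to the running maximum
  expect_equal(interpolate_covariate(c(100, 200), c(20, 10), c(150, 200)),
               c(20, 20))
  expect_equal(interpolate_covariate(c(100, 200, 300), c(10, 20, 15),
                                     c(100, 200, 250, 300, 400)),
               c(10, 20, 20, 20, 20))
  expect_warning(one <- interpolate_covariate(100, 5, c(50, 150)), "single")
  expect_equal(one, c(5, 5))
  q <- sort(runif(20, 0, 500))
  v <- interpolate_covariate(c(100, 200, 300), c(3, 9, 7), q)
  expect_true(all(diff(v) >= 0))
})
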