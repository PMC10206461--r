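# Zones and the daily husbandry schedule.

#' Zone labels and vertical levels
#'
#' The aviary pen is tracked across five zones: the littered floor
#' (`FLOOR`), the lower tier (`LOWER`), the nestbox tier (`NESTBOX`), the
#' top tier (`TOP`) and the outside winter garden (`WG`). The four indoor
#' zones are stacked and carry vertical levels 0-3; the winter garden has
#' no vertical level and transitions involving it contribute no vertical
#' distance.
#'
#' @return `zone_names()` returns the five labels; `zone_levels()` a named
#'   numeric vector of vertical levels (`NA` for `WG`).
#' @export
zone_names <- function() c("FLOOR", "LOWER", "NESTBOX", "TOP", "WG")

#' @rdname zone_names
#' @export
zone_levels <- function() {
  c(FLOOR = 0, LOWER = 1, NESTBOX = 2, TOP = 3, WG = NA_real_)
}

#' Feed tiers: the two tiers where the feed chain runs.
#' @rdname zone_names
#' @export
feed_tiers <- function() c("LOWER", "TOP")

#' Daily husbandry schedule
#'
#' Clock-based schedule of the laying barn: lights on 02:00-17:00 with a
#' 15-min dusk before lights-off and a (configurable) 15-min dawn after
#' lights-on; six 3-min feed deliveries; winter-garden access 10:00-16:00;
#' expected laying window 02:00-08:00. All times are local clock times,
#' stored as seconds from midnight.
#'
#' @param lights_on,lights_off clock times.
#' @param dusk_minutes,dawn_minutes phase lengths in minutes.
#' @param feed_starts character vector of delivery start times.
#' @param feed_duration_min delivery length in minutes.
#' @param wg_open,wg_close winter-garden access window.
#' @param nest_window length-2 clock interval in which laying is expected.
#' @return an object of class `day_schedule`.
#' @examples
#' sched <- day_schedule()
#' sched$feed_starts / 3600  # delivery starts in decimal hours
#' @export
day_schedule <- function(lights_on = "02:00", lights_off = "17:00",
                         dusk_minutes = 15, dawn_minutes = 15,
                         feed_starts = c("02:30", "06:00", "09:00",
                                         "12:00", "14:15", "16:15"),
                         feed_duration_min = 3,
                         wg_open = "10:00", wg_close = "16:00",
                         nest_window = c("02:00", "08:00")) {
  s <- structure(list(
    lights_on = clock_seconds(lights_on),
    lights_off = clock_seconds(lights_off),
    dusk_s = dusk_minutes * 60,
    dawn_s = dawn_minutes * 60,
    feed_starts = sort(clock_seconds(feed_starts)),
    feed_duration_s = feed_duration_min * 60,
    wg_open = clock_seconds(wg_open),
    wg_close = clock_seconds(wg_close),
    nest_start = clock_seconds(nest_window[1]),
    nest_end = clock_seconds(nest_window[2])
  ), class = "day_schedule")
  validate_schedule(s)
  s
}

#' @keywords internal
validate_schedule <- function(s) {
  fe <- s$feed_starts + s$feed_duration_s
  if (any(s$feed_starts[-1] < fe[-length(fe)]))
    stop("feed delivery windows overlap")
  if (s$nest_start < s$lights_on || s$nest_end > s$lights_off)
    stop("nest window must lie within the lights-on phase")
  if (s$wg_open < s$lights_on || s$wg_close > s$lights_off)
    stop("winter-garden window must lie within the lights-on phase")
  if (s$lights_off <= s$lights_on)
    stop("lights-off must come after lights-on")
  invisible(s)
}

#' Read / write a schedule as YAML
#'
#' @param path file path.
#' @return `read_schedule()` returns a `day_schedule`.
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  sec_to_clock <- function(x) x  # yaml stores clock strings already
  day_schedule(
    lights_on = y$lights_on, lights_off = y$lights_off,
    dusk_minutes = y$dusk_minutes %||% 15,
    dawn_minutes = y$dawn_minutes %||% 15,
    feed_starts = unlist(y$feed_starts),
    feed_duration_min = y$feed_duration_min %||% 3,
    wg_open = y$wg_open, wg_close = y$wg_close,
    nest_window = unlist(y$nest_window)
  )
}

#' @rdname read_schedule
#' @param schedule a `day_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  fmt <- function(sec) sprintf("%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60)
  yaml::write_yaml(list(
    lights_on = fmt(schedule$lights_on),
    lights_off = fmt(schedule$lights_off),
    dusk_minutes = schedule$dusk_s / 60,
    dawn_minutes = schedule$dawn_s / 60,
    feed_starts = vapply(schedule$feed_starts, fmt, character(1)),
    feed_duration_min = schedule$feed_duration_s / 60,
    wg_open = fmt(schedule$wg_open),
    wg_close = fmt(schedule$wg_close),
    nest_window = vapply(c(schedule$nest_start, schedule$nest_end),
                         fmt, character(1))
  ), path)
  invisible(path)
}

#' @exportS3Method base::print
print.day_schedule <- function(x, ...) {
  fmt <- function(sec) sprintf("%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60)
  cat("Day schedule:\n")
  cat("  lights:", fmt(x$lights_on), "-", fmt(x$lights_off),
      sprintf("(dawn %d min, dusk %d min)\n", x$dawn_s / 60, x$dusk_s / 60))
  cat("  feed deliveries:", paste(vapply(x$feed_starts, fmt, character(1)),
                                  collapse = ", "),
      sprintf("(%d min each)\n", x$feed_duration_s / 60))
  cat("  winter garden:", fmt(x$wg_open), "-", fmt(x$wg_close), "\n")
  cat("  nest window:", fmt(x$nest_start), "-", fmt(x$nest_end), "\n")
  invisible(x)
}
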