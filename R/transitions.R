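# Zone-transition records: I/O, interval construction, window arithmetic.

#' Read zone-transition records
#'
#' Reads a delimited file with columns `hen_id`, `timestamp` (ISO-8601,
#' seconds resolution) and `zone`. Records are sorted per hen by time;
#' consecutive records of the same zone are collapsed to the first (a
#' transition stream should only contain zone *changes*). A report of
#' collapsed rows is attached as attribute `"report"`.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with columns `hen_id` (character), `timestamp`
#'   (`POSIXct`, UTC-stored local clock time) and `zone` (character), with
#'   attribute `report = list(n_read, n_collapsed)`.
#' @details Unknown zone labels and non-monotone timestamps within a hen are
#'   hard errors naming the offending row/hen: both indicate corrupted
#'   tracking output rather than recoverable noise.
#' @export
read_transitions <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("hen_id", "timestamp", "zone")
  if (!all(need %in% names(raw)))
    stop("transitions file must have columns: ", paste(need, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("empty transitions file: ", path)
    out <- data.frame(hen_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      zone = character(), stringsAsFactors = FALSE)
    attr(out, "report") <- list(n_read = 0L, n_collapsed = 0L)
    return(out)
  }
  bad <- which(!raw$zone %in% zone_names())
  if (length(bad))
    stop("unknown zone label '", raw$zone[bad[1]], "' at row ", bad[1])
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts))
    stop("unparseable timestamp at row ", which(is.na(ts))[1])
  out <- data.frame(hen_id = as.character(raw$hen_id), timestamp = ts,
                    zone = raw$zone, stringsAsFactors = FALSE)
  out <- out[order(out$hen_id, out$timestamp), , drop = FALSE]
  # strictly increasing timestamps within hen
  same_hen <- out$hen_id[-1] == out$hen_id[-nrow(out)]
  nonmono <- same_hen & diff(as.numeric(out$timestamp)) <= 0
  if (any(nonmono)) {
    i <- which(nonmono)[1]
    stop("non-monotone timestamps for hen '", out$hen_id[i + 1], "' near ",
         format(out$timestamp[i + 1]))
  }
  # collapse consecutive same-zone records per hen
  dup <- c(FALSE, same_hen & out$zone[-1] == out$zone[-nrow(out)])
  n_collapsed <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(n_read = nrow(raw), n_collapsed = n_collapsed)
  out
}

#' @rdname read_transitions
#' @param transitions a transitions `data.frame`.
#' @export
write_transitions <- function(transitions, path) {
  out <- data.frame(
    hen_id = transitions$hen_id,
    timestamp = format(transitions$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    zone = transitions$zone, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build occupancy intervals from a transition stream
#'
#' Converts per-hen transition records into half-open occupancy intervals
#' `[start, end)` that tile each hen's covered span: a transition timestamp
#' belongs to the *new* zone. Coverage starts at `span_start` when a record
#' exists at or before it (the most recent such record supplies the initial
#' zone), otherwise at the hen's first record; the last interval is closed
#' at `span_end`.
#'
#' @param transitions transitions `data.frame` (see [read_transitions()]).
#' @param span_start,span_end `POSIXct` bounds of the tracked span.
#' @return `data.frame` with columns `hen_id`, `zone`, `start`, `end`.
#' @export
to_intervals <- function(transitions, span_start, span_end) {
  stopifnot(span_end > span_start)
  pieces <- lapply(split(transitions, transitions$hen_id), function(tr) {
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    pre <- tr$timestamp <= span_start
    if (any(pre)) {
      i0 <- max(which(pre))
      starts <- c(span_start, tr$timestamp[tr$timestamp > span_start &
                                           tr$timestamp < span_end])
      zones <- c(tr$zone[i0], tr$zone[tr$timestamp > span_start &
                                      tr$timestamp < span_end])
    } else {
      keep <- tr$timestamp < span_end
      if (!any(keep)) return(NULL)
      starts <- tr$timestamp[keep]
      zones <- tr$zone[keep]
    }
    ends <- c(starts[-1], span_end)
    data.frame(hen_id = tr$hen_id[1], zone = zones,
               start = starts, end = ends, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Time spent in a set of zones within a time window
#'
#' Sums the intersection of a hen's occupancy intervals (restricted to the
#' given zones) with the half-open window `[window_start, window_end)`.
#' Windows are absolute times, so clock windows that cross midnight are
#' simply expressed with an end on the following day.
#'
#' @param intervals occupancy intervals (one hen's or many; all rows used).
#' @param window_start,window_end `POSIXct` window bounds.
#' @param zones character vector of zone names.
#' @return duration in seconds (0 when there is no overlap).
#' @export
time_in_zones <- function(intervals, window_start, window_end, zones) {
  iv <- intervals[intervals$zone %in% zones, , drop = FALSE]
  if (!nrow(iv)) return(0)
  s <- pmax(as.numeric(iv$start), as.numeric(window_start))
  e <- pmin(as.numeric(iv$end), as.numeric(window_end))
  sum(pmax(0, e - s))
}

#' Fraction of a calendar day covered by occupancy intervals
#' @keywords internal
day_coverage <- function(intervals, date) {
  d0 <- day_start(date)
  time_in_zones(intervals, d0, d0 + 86400, zone_names()) / 86400
}
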