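# Internal helpers: clock arithmetic and reproducible seed streams.

#' Parse a clock time into seconds from midnight
#'
#' Accepts `"HH:MM"` or `"HH:MM:SS"`; numeric input is returned unchanged
#' (already seconds).
#' @param x character or numeric.
#' @return numeric seconds from midnight.
#' @keywords internal
clock_seconds <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) == 2L) p <- c(p, 0)
    if (length(p) != 3L || anyNA(p)) stop("malformed clock time", call. = FALSE)
    p[1L] * 3600 + p[2L] * 60 + p[3L]
  }, numeric(1))
}

#' @keywords internal
day_start <- function(date) {
  as.POSIXct(paste0(format(as.Date(date)), " 00:00:00"), tz = "UTC")
}

#' Derive a reproducible integer seed from a base seed and arbitrary keys
#'
#' Mixes each key (character or integer) into a 31-bit state with a
#' Lehmer-style multiplicative step, so that every hen-day (or bootstrap
#' replicate, or chain) gets its own deterministic RNG stream.
#' @param base integer base seed.
#' @param ... keys (strings, dates, integers).
#' @return a positive integer below 2^31 - 1.
#' @keywords internal
derive_seed <- function(base, ...) {
  m <- 2147483647
  x <- (abs(as.numeric(base)) + 1) %% m
  for (k in list(...)) {
    if (inherits(k, "Date")) k <- as.integer(k)
    if (is.character(k)) k <- sum(utf8ToInt(paste(k, collapse = ""))) %% m
    x <- (x * 69069 + (abs(as.numeric(k)) %% m) + 1) %% m
  }
  as.integer(max(1, x))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so package internals do
#' not perturb user-level random streams.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
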