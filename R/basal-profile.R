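#' Parse a clock time string to minutes after midnight
#'
#' @param x Character vector of `"HH:MM"` clock times (24-h), or a numeric
#'   vector already in minutes (returned unchanged).
#' @return Numeric vector of minutes after midnight in `[0, 1440)`.
#' @export
#' @examples
#' parse_clock("07:30")  # 450
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  stopifnot(is.character(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("invalid clock time(s): ", paste(x[bad], collapse = ", "))
  hh <- as.numeric(vapply(m, `[`, "", 2L))
  mm <- as.numeric(vapply(m, `[`, "", 3L))
  if (any(hh > 23) || any(mm > 59)) stop("clock time out of range")
  hh * 60 + mm
}

#' Piecewise-constant basal insulin profile
#'
#' A 24-h basal profile as programmed in an insulin pump: a set of segments,
#' each starting at a clock time and holding a constant rate in U/h until the
#' next segment. The profile wraps around midnight.
#'
#' @param start_time Clock times (`"HH:MM"` or minutes after midnight) at which
#'   each segment starts. The first segment must start at midnight (00:00).
#' @param rate_U_per_h Basal rate for each segment, in U/h. Non-negative.
#' @return An object of class `basal_profile`: a data frame with columns
#'   `start_min` and `rate_U_per_h`, sorted by start time.
#' @export
#' @examples
#' basal_profile("00:00", 1)                      # flat 1 U/h
#' basal_profile(c("00:00", "07:00"), c(0.8, 1.2))
basal_profile <- function(start_time, rate_U_per_h) {
  start_min <- parse_clock(start_time)
  rate <- as.numeric(rate_U_per_h)
  if (length(start_min) != length(rate) || length(rate) < 1L)
    stop("start_time and rate_U_per_h must be non-empty and equal length")
  if (any(!is.finite(rate)) || any(rate < 0)) stop("basal rates must be finite and >= 0")
  if (anyDuplicated(start_min)) stop("duplicated segment start times")
  o <- order(start_min)
  start_min <- start_min[o]; rate <- rate[o]
  if (start_min[1L] != 0) stop("profile must start at 00:00 to cover 24 h")
  if (any(start_min >= 1440)) stop("segment start times must be < 24:00")
  structure(data.frame(start_min = start_min, rate_U_per_h = rate),
            class = c("basal_profile", "data.frame"))
}

#' Basal rate at given times
#'
#' @param profile A [basal_profile()].
#' @param t_min Times in minutes (absolute simulation time or minutes after
#'   midnight); reduced modulo 24 h.
#' @return Basal rate(s) in U/h.
#' @export
basal_rate_at <- function(profile, t_min) {
  stopifnot(inherits(profile, "basal_profile"))
  tod <- t_min %% 1440
  idx <- findInterval(tod, profile$start_min)
  profile$rate_U_per_h[idx]
}

#' Basal insulin scheduled over a time window
#'
#' Integrates the profile over `[t_min, t_min + duration_min)`, wrapping
#' across midnight, and returns the insulin in U that open-loop therapy would
#' deliver in that window.
#'
#' @inheritParams basal_rate_at
#' @param duration_min Window length in minutes (>= 0); may exceed 24 h.
#' @return Insulin amount in U.
#' @export
basal_insulin_between <- function(profile, t_min, duration_min) {
  stopifnot(inherits(profile, "basal_profile"),
            length(t_min) == 1L, length(duration_min) == 1L,
            is.finite(duration_min), duration_min >= 0)
  if (duration_min == 0) return(0)
  # integrate piecewise over breakpoints; work in time-of-day coordinates
  brks <- profile$start_min
  t0 <- t_min %% 1440
  total <- 0
  remaining <- duration_min
  t <- t0
  while (remaining > 1e-12) {
    idx <- findInterval(t, brks)
    seg_end <- if (idx < length(brks)) brks[idx + 1L] else 1440
    step <- min(seg_end - t, remaining)
    total <- total + profile$rate_U_per_h[idx] * step / 60
    remaining <- remaining - step
    t <- (t + step) %% 1440
  }
  total
}

#' Read or write a basal profile as JSON
#'
#' The on-disk form is a JSON array of `{"start_time": "HH:MM",
#' "rate_U_per_h": <number>}` segments covering 24 h.
#'
#' @param path File path.
#' @return `read_basal_profile` returns a [basal_profile()];
#'   `write_basal_profile` returns `path` invisibly.
#' @export
read_basal_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  basal_profile(x$start_time, x$rate_U_per_h)
}

#' @rdname read_basal_profile
#' @param profile A [basal_profile()].
#' @export
write_basal_profile <- function(profile, path) {
  stopifnot(inherits(profile, "basal_profile"))
  mins <- profile$start_min
  out <- data.frame(
    start_time = sprintf("%02d:%02d", mins %/% 60, mins %% 60),
    rate_U_per_h = profile$rate_U_per_h
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
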