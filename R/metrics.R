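#' Percent of time in a closed glucose range
#'
#' @param g Glucose samples, mg/dl (uniformly sampled).
#' @param lo,hi Range bounds, mg/dl (`lo < hi`); the interval is closed.
#' @return Percent of samples with `lo <= g <= hi`.
#' @export
time_in_range <- function(g, lo, hi) {
  if (length(g) == 0L) stop("empty trace")
  stopifnot(lo < hi)
  100 * mean(g >= lo & g <= hi)
}

#' Percent of time strictly below / above a threshold
#'
#' @param g Glucose samples, mg/dl.
#' @param threshold Threshold, mg/dl (strict inequality).
#' @return Percent of samples.
#' @export
time_below <- function(g, threshold) {
  if (length(g) == 0L) stop("empty trace")
  100 * mean(g < threshold)
}

#' @rdname time_below
#' @export
time_above <- function(g, threshold) {
  if (length(g) == 0L) stop("empty trace")
  100 * mean(g > threshold)
}

#' Count hypoglycemic events
#'
#' An event is a maximal run of consecutive samples strictly below the
#' threshold lasting at least `min_duration` minutes (run length times the
#' sampling period); a sample at or above the threshold ends the run.
#'
#' @param g Glucose samples, mg/dl, uniformly sampled.
#' @param period Sampling period, min.
#' @param threshold Event threshold, mg/dl. Default 70.
#' @param min_duration Minimum event duration, min. Default 15.
#' @param starts If `TRUE`, return the start indices of the events instead of
#'   the count.
#' @return Event count (or start indices).
#' @export
hypo_events <- function(g, period, threshold = 70, min_duration = 15,
                        starts = FALSE) {
  stopifnot(period > 0)
  if (length(g) == 0L) return(if (starts) integer(0) else 0L)
  r <- rle(g < threshold)
  ok <- r$values & (r$lengths * period >= min_duration)
  if (!starts) return(sum(ok))
  ends <- cumsum(r$lengths)
  (ends - r$lengths + 1L)[ok]
}

#' Postprandial glycemic excursion
#'
#' Difference between the maximum glucose in the postprandial window and the
#' premeal glucose.
#'
#' @param trace A trace data frame with `time_min` and `G`.
#' @param meal_time Meal time, min (must be a sample time).
#' @param horizon Postprandial window length, min. Default 240.
#' @return Excursion in mg/dl (>= 0: the maximum includes the meal-time
#'   sample).
#' @export
glycemic_excursion <- function(trace, meal_time, horizon = 240) {
  sel <- trace$time_min >= meal_time & trace$time_min <= meal_time + horizon
  if (!any(trace$time_min == meal_time) ||
      max(trace$time_min) < meal_time + horizon)
    stop("trace does not cover the postprandial window")
  g <- trace$G[sel]
  max(g) - trace$G[trace$time_min == meal_time][1L]
}

#' Glucose management indicator
#'
#' `GMI (%) = 3.31 + 0.02392 * mean glucose (mg/dl)`: the published linear
#' map from mean CGM glucose to estimated A1C.
#'
#' @param mean_glucose Mean glucose, mg/dl (> 0 for a meaningful value).
#' @return GMI in percent.
#' @export
gmi <- function(mean_glucose) 3.31 + 0.02392 * mean_glucose

#' Control-variability grid analysis zone
#'
#' Classifies a (24-h minimum, 24-h maximum) glucose pair into the standard
#' CVGA zone. The minimum axis spans 110 down to 50 mg/dl with grid lines at
#' 90 and 70; the maximum axis spans 110 up to 400 with grid lines at 180 and
#' 300; values beyond the axis ends are clamped. Zone A is the
#' best-in-both-axes cell; B the three adjacent cells; C, D and E the
#' progressively worse off-diagonal and corner cells.
#'
#' @param min_g,max_g 24-h minimum and maximum glucose, mg/dl (vectorised;
#'   `min_g <= max_g`).
#' @return Character vector of zones `"A"` to `"E"`.
#' @export
cvga_zone <- function(min_g, max_g) {
  stopifnot(all(min_g <= max_g))
  m <- pmin(pmax(min_g, 50), 110)
  M <- pmin(pmax(max_g, 110), 400)
  xc <- ifelse(m >= 90, 0L, ifelse(m >= 70, 1L, 2L))
  yc <- ifelse(M <= 180, 0L, ifelse(M <= 300, 1L, 2L))
  grid <- matrix(c("A", "B", "C",
                   "B", "B", "D",
                   "C", "D", "E"), nrow = 3, byrow = TRUE)
  grid[cbind(xc + 1L, yc + 1L)]
}

# day window: 06:00-23:00 local; night is the complement
is_daytime <- function(time_min) {
  tod <- time_min %% 1440
  tod >= 360 & tod < 1380
}

metrics_one <- function(g) {
  data.frame(
    mean_g = mean(g),
    pct_70_140 = time_in_range(g, 70, 140),
    pct_70_180 = time_in_range(g, 70, 180),
    pct_above_180 = time_above(g, 180),
    pct_below_70 = time_below(g, 70),
    pct_below_54 = time_below(g, 54),
    gmi = gmi(mean(g))
  )
}

#' Glycemic outcome report for simulation traces
#'
#' Computes per-patient-per-arm metrics — mean glucose, percent time in
#' 70–140 and 70–180 mg/dl, above 180, below 70 and 54, hypoglycemic events
#' (at least 15 consecutive minutes below 70 mg/dl), total
#' controller-delivered insulin and GMI — overall and split into daytime
#' (06:00–23:00) and night (23:00–06:00) windows (events are attributed to
#' the window containing their onset), aggregates them as cohort median and
#' 25th–75th percentiles, and classifies per-patient-per-day CVGA zones.
#' If `meals` are supplied, postprandial metrics (4-h glycemic excursion and
#' controller-delivered insulin after the bolus) are added per meal.
#'
#' @param traces A trace data frame (possibly several patients and arms
#'   row-bound together) with the [simulate_patient()] schema.
#' @param meals Optional named list (by patient id) of meal data frames, or a
#'   single meal data frame applying to all patients.
#' @param period Sampling period in min; inferred from the trace when `NULL`.
#' @param pp_horizon Postprandial analysis window, min. Default 240.
#' @return A list with data frames `per_patient`, `cohort`, `cvga` and (when
#'   meals are given) `postprandial`.
#' @export
metrics_report <- function(traces, meals = NULL, period = NULL,
                           pp_horizon = 240) {
  if (is.null(period)) period <- trace_period(traces)
  combos <- unique(traces[c("arm", "patient_id")])
  per <- list(); cvga <- list(); pp <- list()
  for (i in seq_len(nrow(combos))) {
    a <- combos$arm[i]; pid <- combos$patient_id[i]
    tr <- traces[traces$arm == a & traces$patient_id == pid, ]
    tr <- tr[order(tr$time_min), ]
    day <- is_daytime(tr$time_min)
    ev_start <- hypo_events(tr$G, period, starts = TRUE)
    ev_day <- sum(is_daytime(tr$time_min[ev_start]))
    # "total basal": controller-delivered insulin, meal boluses excluded
    rows <- rbind(
      cbind(window = "all", metrics_one(tr$G),
            hypo_events = length(ev_start),
            total_basal_U = sum(tr$u_d) * period),
      cbind(window = "day", metrics_one(tr$G[day]),
            hypo_events = ev_day,
            total_basal_U = sum(tr$u_d[day]) * period),
      cbind(window = "night", metrics_one(tr$G[!day]),
            hypo_events = length(ev_start) - ev_day,
            total_basal_U = sum(tr$u_d[!day]) * period)
    )
    rows <- cbind(arm = a, patient_id = pid, rows)
    per[[i]] <- rows
    # per-day CVGA
    dayidx <- tr$time_min %/% 1440
    mins <- tapply(tr$G, dayidx, min)
    maxs <- tapply(tr$G, dayidx, max)
    cvga[[i]] <- data.frame(arm = a, patient_id = pid,
                            day = as.integer(names(mins)),
                            zone = cvga_zone(as.numeric(mins),
                                             as.numeric(maxs)))
    if (!is.null(meals)) {
      m <- if (is.data.frame(meals)) meals else meals[[as.character(pid)]]
      if (!is.null(m) && nrow(m) > 0) {
        exc <- ins <- numeric(nrow(m))
        for (j in seq_len(nrow(m))) {
          mt <- m$t_min[j]
          if (max(tr$time_min) < mt + pp_horizon) { exc[j] <- NA; ins[j] <- NA; next }
          exc[j] <- glycemic_excursion(tr, mt, pp_horizon)
          sel <- tr$time_min >= mt & tr$time_min <= mt + pp_horizon
          ins[j] <- sum(tr$u_d[sel]) * period
        }
        pp[[length(pp) + 1L]] <- data.frame(arm = a, patient_id = pid,
                                            t_min = m$t_min,
                                            excursion = exc,
                                            controller_insulin_U = ins)
      }
    }
  }
  per <- do.call(rbind, per)
  num_cols <- setdiff(names(per), c("arm", "patient_id", "window"))
  coh <- list()
  for (a in unique(per$arm)) for (w in unique(per$window)) {
    sub <- per[per$arm == a & per$window == w, num_cols, drop = FALSE]
    qs <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
                names = FALSE)
    coh[[length(coh) + 1L]] <- data.frame(
      arm = a, window = w, metric = num_cols,
      q25 = qs[1L, ], median = qs[2L, ], q75 = qs[3L, ], row.names = NULL)
  }
  out <- list(per_patient = per, cohort = do.call(rbind, coh),
              cvga = do.call(rbind, cvga))
  if (length(pp)) out$postprandial <- do.call(rbind, pp)
  out
}
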