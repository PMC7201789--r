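#' Day/night gain schedule for the fasting IOB-limit baseline
#'
#' The fasting baseline scales the steady-state IOB of the programmed basal
#' rate by a gain `K_IOB`: above 1 the controller may hold more IOB than
#' open-loop therapy would, below 1 less. A lower night gain protects against
#' nocturnal hypoglycemia.
#'
#' @param day_gain Gain during the daytime window. Default 1.3.
#' @param night_gain Gain during the night window. Default 1.1.
#' @param day_start Clock time the daytime window opens. Default "06:00".
#' @param night_start Clock time the night window opens. Default "23:00".
#' @return An object of class `kiob_schedule`.
#' @export
kiob_schedule <- function(day_gain = 1.3, night_gain = 1.1,
                          day_start = "06:00", night_start = "23:00") {
  ds <- parse_clock(day_start); ns <- parse_clock(night_start)
  stopifnot(day_gain > 0, night_gain > 0, ds < ns)
  structure(list(day_gain = day_gain, night_gain = night_gain,
                 day_start = ds, night_start = ns),
            class = "kiob_schedule")
}

#' Gain in force at a clock time
#'
#' @param schedule A [kiob_schedule()].
#' @param t_min Time in minutes (reduced modulo 24 h); vectorised.
#' @return `K_IOB` value(s).
#' @export
kiob_at <- function(schedule, t_min) {
  tod <- t_min %% 1440
  ifelse(tod >= schedule$day_start & tod < schedule$night_start,
         schedule$day_gain, schedule$night_gain)
}

#' Fasting baseline IOB limit
#'
#' \deqn{\bar{IOB}_{bl}(t) = K_{IOB}(t) \cdot \frac{2\, u_{basal}(t)}{60\, K_{DIA}}}
#' with the basal rate in U/h — i.e. `K_IOB` times the IOB the estimator would
#' settle at under the programmed basal rate, so `K_IOB = 1` reproduces
#' open-loop IOB exposure exactly.
#'
#' @param t Time in minutes (clock or absolute; reduced mod 24 h); vectorised.
#' @param profile A [basal_profile()].
#' @param schedule A [kiob_schedule()].
#' @param params An [iob_params()].
#' @return Baseline IOB limit(s), U.
#' @export
baseline_limit <- function(t, profile, schedule = kiob_schedule(),
                           params = iob_params()) {
  rate <- basal_rate_at(profile, t)           # U/h
  kiob_at(schedule, t) * 2 * rate / (60 * params$k_dia)
}

#' Dynamic rule-based tuner parameters
#'
#' @param g_trigger BG threshold (mg/dl) above which, once the evaluation
#'   delay has elapsed, the postprandial IOB limit is raised. Default 150.
#' @param g_release BG threshold (mg/dl) at or below which the raised limit is
#'   released back to the fasting baseline. Default 140.
#' @param t_iob_slope Evaluation-delay slope, min per gram of announced CHO.
#'   Default 1.5.
#' @param schedule A [kiob_schedule()].
#' @return An object of class `drb_params`.
#' @export
drb_params <- function(g_trigger = 150, g_release = 140, t_iob_slope = 1.5,
                       schedule = kiob_schedule()) {
  stopifnot(g_trigger >= g_release, g_release > 0, t_iob_slope > 0,
            inherits(schedule, "kiob_schedule"))
  structure(list(g_trigger = g_trigger, g_release = g_release,
                 t_iob_slope = t_iob_slope, schedule = schedule),
            class = "drb_params")
}

#' Postprandial evaluation delay
#'
#' `T_IOB = slope * M_CHO`: minutes after a meal announcement before BG
#' readings are evaluated to decide whether the IOB limit should be raised.
#' With the default slope of 1.5 min/g a 45-g meal gives 67.5 min.
#'
#' @param m_cho Announced meal carbohydrate, g (>= 0).
#' @param slope Min per gram (> 0). Default 1.5.
#' @return Delay in minutes.
#' @export
t_iob <- function(m_cho, slope = 1.5) {
  stopifnot(is.finite(m_cho), m_cho >= 0, slope > 0)
  slope * m_cho
}

#' Initial DRB constraint-machine state
#'
#' `pp_state` flags an active postprandial window; `flag_pp` that the raised
#' limit has already been computed for the current meal (at most once per
#' meal). Both start at zero.
#'
#' @return An object of class `constraint_state`.
#' @export
constraint_state <- function() {
  structure(list(pp_state = 0L, flag_pp = 0L, meal_time = NA_real_,
                 t_iob = NA_real_, iob_bar_pp = NA_real_),
            class = "constraint_state")
}

#' Register an announced meal with the DRB tuner
#'
#' Opens (or, for a meal announced during an active window, resets to the new
#' meal) the postprandial window: records the meal time, computes the
#' evaluation delay from the announced grams, and clears the single-raise flag.
#'
#' @param state A [constraint_state()].
#' @param t Announcement time, minutes (absolute simulation time).
#' @param m_cho_announced Announced carbohydrate, g (> 0).
#' @param params A [drb_params()].
#' @return Updated [constraint_state()].
#' @export
on_meal_announced <- function(state, t, m_cho_announced, params = drb_params()) {
  if (!is.finite(m_cho_announced) || m_cho_announced <= 0)
    stop("announced meal must have positive grams")
  state$pp_state <- 1L
  state$flag_pp <- 0L
  state$meal_time <- t
  state$t_iob <- t_iob(m_cho_announced, params$t_iob_slope)
  state$iob_bar_pp <- NA_real_
  state
}

#' Current IOB limit under the DRB rules
#'
#' One tuner evaluation per controller sample. Outside a postprandial window
#' the limit is the fasting baseline. Inside a window, before the evaluation
#' delay elapses the limit stays at baseline (the meal bolus itself violates
#' it, engaging the SAFE layer). From `meal_time + T_IOB` on, the first sample
#' with BG above the trigger threshold freezes
#' `max(previous-sample IOB estimate, baseline)` as the raised limit — once
#' per meal — which is held while BG stays above the release threshold; when
#' BG falls to or below it, the window closes and the limit returns to the
#' baseline.
#'
#' @param state A [constraint_state()].
#' @param t Current time, minutes.
#' @param g CGM glucose, mg/dl.
#' @param iob_hat_prev Previous-sample IOB estimate, U.
#' @param baseline Fasting baseline limit at `t`, U.
#' @param params A [drb_params()].
#' @return A list with elements `limit` (U) and `state` (updated
#'   [constraint_state()]).
#' @export
current_limit <- function(state, t, g, iob_hat_prev, baseline,
                          params = drb_params()) {
  if (state$pp_state == 0L)
    return(list(limit = baseline, state = state))
  if (t < state$meal_time + state$t_iob)
    return(list(limit = baseline, state = state))
  # evaluation phase
  if (state$flag_pp == 0L) {
    if (g > params$g_trigger) {
      state$iob_bar_pp <- max(iob_hat_prev, baseline)
      state$flag_pp <- 1L
      return(list(limit = state$iob_bar_pp, state = state))
    }
    if (g <= params$g_release) {
      # meal absorbed without ever triggering: close the window
      state$pp_state <- 0L
      state$meal_time <- NA_real_
      state$t_iob <- NA_real_
    }
    return(list(limit = baseline, state = state))
  }
  # raised limit active
  if (g > params$g_release)
    return(list(limit = state$iob_bar_pp, state = state))
  state$pp_state <- 0L
  state$flag_pp <- 0L
  state$meal_time <- NA_real_
  state$t_iob <- NA_real_
  state$iob_bar_pp <- NA_real_
  list(limit = baseline, state = state)
}
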