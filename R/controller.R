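#' Inner-loop controller parameters
#'
#' Proportional-derivative (PD) glucose controller with insulin feedback
#' (IFB), plus the patient's open-loop therapy settings used by the
#' feed-forward terms. Defaults follow the published tuning: `Kp = TDI/2250`
#' U/min per mg/dl, `Td = 90` min, reference 100 mg/dl, IFB gain 0.42.
#'
#' @param tdi Total daily insulin, U (> 0).
#' @param i2c Insulin-to-carbohydrate ratio, g/U (> 0).
#' @param cf Correction factor, mg/dl per U (> 0).
#' @param kp Proportional gain, U/min per mg/dl. Default `tdi/2250`.
#' @param td Derivative time, min (>= 0).
#' @param g_r Glucose reference, mg/dl (> 0).
#' @param gamma Insulin-feedback gain (>= 0; dimensionless scaling on the
#'   estimated plasma-insulin deviation rate).
#' @param k_ifb Rate constant of the IFB deviation estimator, min^-1.
#'   Default 0.05 (a ~20-min plasma-insulin time scale, faster than the
#'   subcutaneous absorption chain it mirrors structurally).
#' @return An object of class `controller_params`.
#' @export
controller_params <- function(tdi, i2c, cf, kp = tdi / 2250, td = 90,
                              g_r = 100, gamma = 0.42, k_ifb = 0.05) {
  stopifnot(tdi > 0, i2c > 0, cf > 0, kp > 0, td >= 0, g_r > 0,
            gamma >= 0, k_ifb > 0)
  structure(list(tdi = tdi, i2c = i2c, cf = cf, kp = kp, td = td,
                 g_r = g_r, gamma = gamma, k_ifb = k_ifb),
            class = "controller_params")
}

#' PD control action
#'
#' `u_pd = Kp * ((G - G_rf) + Td * dG/dt)`: glucose above the (conditioned)
#' reference, or rising, calls for insulin. Raising the conditioned reference
#' `G_rf` therefore reduces the commanded insulin — the mechanism by which the
#' SAFE layer winds the controller down.
#'
#' @param g_rf Conditioned glucose reference, mg/dl.
#' @param g CGM glucose, mg/dl.
#' @param dgdt Glucose rate of change, mg/dl/min.
#' @param params A [controller_params()].
#' @return PD action in U/min (may be negative; clamping happens in
#'   [final_action()]).
#' @export
pd_action <- function(g_rf, g, dgdt, params) {
  params$kp * ((g - g_rf) + params$td * dgdt)
}

#' Meal bolus
#'
#' Augmented feed-forward bolus for an announced meal: the carbohydrate dose
#' `M/I2C`, a correction term `(G - G_r)/CF`, plus the basal insulin that
#' open-loop therapy would deliver over the next `M` minutes (the augmentation
#' that the fixed IOB constraint was designed around; for a 60-g meal it is
#' the next hour of basal). The correction term may be negative; the total is
#' clamped at zero.
#'
#' @param m_cho Announced meal carbohydrate, g (>= 0).
#' @param g CGM glucose at announcement, mg/dl.
#' @param params A [controller_params()].
#' @param profile A [basal_profile()].
#' @param t Clock time of the announcement (`"HH:MM"` or minutes).
#' @return Bolus in U (>= 0).
#' @export
meal_bolus <- function(m_cho, g, params, profile, t) {
  if (!is.finite(m_cho) || m_cho < 0) stop("m_cho must be >= 0")
  if (m_cho == 0 && g == params$g_r) return(0)
  t0 <- parse_clock(t)
  b <- m_cho / params$i2c +
    (g - params$g_r) / params$cf +
    basal_insulin_between(profile, t0, m_cho)
  max(b, 0)
}

#' Insulin-feedback (IFB) deviation estimator state
#'
#' A two-compartment linear chain, structurally identical to the IOB
#' absorption model but driven by the delivery *deviation* from the scheduled
#' basal rate, `u_d - u_basal`. Its compartments hold the deviation of
#' subcutaneous/plasma-proximal insulin from basal steady state and may be
#' negative (delivery suspended below basal).
#'
#' @param d1,d2 Compartment deviations, U.
#' @return An object of class `ifb_state`.
#' @export
ifb_state <- function(d1 = 0, d2 = 0) {
  stopifnot(is.finite(d1), is.finite(d2))
  structure(list(d1 = d1, d2 = d2), class = "ifb_state")
}

#' Advance the IFB estimator
#'
#' @param state An [ifb_state()].
#' @param u_d Delivered rate over the step, U/min.
#' @param u_basal Scheduled basal rate over the step, U/min.
#' @param dt Step, min (> 0).
#' @param k Chain rate constant, min^-1.
#' @return Updated [ifb_state()].
#' @export
ifb_update <- function(state, u_d, u_basal, dt, k = 0.05) {
  stopifnot(dt > 0, k > 0)
  v <- iob_exact_update(state$d1, state$d2, u_d - u_basal, dt, k)
  ifb_state(v[1L], v[2L])
}

#' Inject a bolus into the IFB estimator
#'
#' @param state An [ifb_state()].
#' @param bolus Bolus in U (>= 0), an impulse above basal.
#' @return Updated [ifb_state()].
#' @export
ifb_bolus <- function(state, bolus) {
  stopifnot(bolus >= 0)
  ifb_state(state$d1 + bolus, state$d2)
}

#' Estimated plasma-insulin deviation
#'
#' The IFB signal fed back to the controller: the estimated plasma-proximal
#' insulin in excess of basal steady state, the deviation chain's second
#' compartment (U). Zero at basal steady state; multiplied by `gamma` in
#' [final_action()], mimicking beta-cell suppression of secretion as plasma
#' insulin rises.
#'
#' @param state An [ifb_state()].
#' @return Deviation estimate in U.
#' @export
plasma_insulin_deviation <- function(state) state$d2

#' Final control action
#'
#' `u_d = max(0, u_pd + u_basal - gamma * Ip_hat)`. The pump cannot remove
#' insulin, so delivery is clamped at zero. Meal boluses are impulses routed
#' separately (to the plant, the IOB estimator and the IFB estimator), not
#' part of the rate.
#'
#' @param u_pd PD action, U/min.
#' @param u_basal Scheduled basal rate, U/min.
#' @param gamma IFB gain, min^-1 scale (multiplies a deviation in U to give a
#'   rate in U/min).
#' @param ip_hat Estimated plasma-insulin deviation, U.
#' @return Commanded delivery rate, U/min (>= 0).
#' @export
final_action <- function(u_pd, u_basal, gamma, ip_hat) {
  max(0, u_pd + u_basal - gamma * ip_hat)
}
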