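#' Surrogate virtual-patient parameters
#'
#' A minimal-model glucoregulatory plant: Bergman-type glucose/remote-insulin
#' dynamics, a two-compartment gut (stomach emptying into an absorbing gut
#' compartment, so meal glucose appearance ramps up and peaks tens of minutes
#' after ingestion), and a two-compartment subcutaneous insulin depot feeding
#' a plasma pool. It is a public, well-characterised
#' surrogate chosen to exercise every controller pathway (meal rise, insulin
#' lowering, suspend-induced rebound, circadian sensitivity); it does not
#' reproduce any licensed simulator's numerics.
#'
#' @param gb Basal (fasting, insulin-replete) glucose, mg/dl.
#' @param p1 Glucose effectiveness, min^-1: insulin-independent relaxation of
#'   glucose toward `gb`.
#' @param p2 Remote insulin action rate, min^-1.
#' @param si0 Nominal insulin sensitivity: remote-action gain per U of
#'   plasma-pool insulin deviation, min^-1 per U.
#' @param k_e Plasma insulin elimination rate, min^-1.
#' @param k_sc Subcutaneous insulin absorption rate, min^-1.
#' @param k_emp Gastric emptying rate, min^-1.
#' @param k_abs Gut carbohydrate absorption rate, min^-1.
#' @param f Carbohydrate bioavailability, fraction of ingested CHO appearing
#'   in plasma.
#' @param v Glucose distribution volume, dl.
#' @param k_cr Counterregulatory gain, mg/dl/min of extra glucose production
#'   per mg/dl below the counterregulation threshold.
#' @param g_cr Counterregulation threshold, mg/dl: below it, endogenous
#'   glucose production ramps up linearly, emulating the hormonal defence
#'   against hypoglycemia.
#' @param tdi,i2c,cf Therapy block: total daily insulin (U), insulin-to-carb
#'   ratio (g/U), correction factor (mg/dl per U).
#' @param profile A [basal_profile()], the open-loop basal schedule.
#' @param id Optional patient identifier.
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(gb, p1, p2, si0, k_e, k_sc, k_emp, k_abs, f, v,
                           tdi, i2c, cf, profile, k_cr = 0.04, g_cr = 75,
                           id = NA_integer_) {
  rates <- c(p1 = p1, p2 = p2, si0 = si0, k_e = k_e, k_sc = k_sc,
             k_emp = k_emp, k_abs = k_abs)
  stopifnot(all(is.finite(rates)), all(rates > 0), gb > 0, f > 0, f <= 1,
            v > 0, tdi > 0, i2c > 0, cf > 0, k_cr >= 0, g_cr > 0,
            inherits(profile, "basal_profile"))
  structure(list(gb = gb, p1 = p1, p2 = p2, si0 = si0, k_e = k_e,
                 k_sc = k_sc, k_emp = k_emp, k_abs = k_abs, f = f, v = v,
                 tdi = tdi, i2c = i2c, cf = cf, profile = profile,
                 k_cr = k_cr, g_cr = g_cr, id = id),
            class = "patient_params")
}

#' Circadian modulation of a parameter
#'
#' A 24-h sinusoid with amplitude 30% of the nominal value and a random phase:
#' `q(t) = q0 + 0.3 q0 sin(2 pi t / 1440 + 2 pi phase)`, `phase` drawn
#' uniformly in `[0, 1)` once per patient per simulation. Applied to the
#' insulin-sensitivity parameter to emulate intraday variability in insulin
#' requirements.
#'
#' @param t Time in minutes (vectorised).
#' @param q0 Nominal parameter value (> 0).
#' @param phase Phase in `[0, 1)`.
#' @return Modulated value(s), in `[0.7 q0, 1.3 q0]`.
#' @export
circadian_param <- function(t, q0, phase) {
  stopifnot(q0 > 0, phase >= 0, phase < 1)
  q0 + 0.3 * q0 * sin(2 * pi * t / 1440 + 2 * pi * phase)
}

#' Perturb absorption parameters for a meal
#'
#' Meal-to-meal variability: the gut absorption rate and the subcutaneous
#' insulin absorption rate are scaled by independent uniform draws in
#' `[0.7, 1.3]` at each meal ingestion and held until the next meal.
#'
#' @param params A [patient_params()].
#' @param factors Two multipliers in `[0.7, 1.3]` (for `k_abs` and `k_sc`);
#'   defaults to fresh uniform draws from the current RNG stream.
#' @return A [patient_params()] with perturbed absorption rates.
#' @export
perturb_meal_params <- function(params, factors = stats::runif(2, 0.7, 1.3)) {
  stopifnot(inherits(params, "patient_params"), length(factors) == 2L,
            all(factors >= 0.7 - 1e-12), all(factors <= 1.3 + 1e-12))
  params$k_abs <- params$k_abs * factors[1L]
  params$k_sc <- params$k_sc * factors[2L]
  params
}

#' Initial plant state at basal steady state
#'
#' @param params A [patient_params()].
#' @param t0 Clock time of initialisation, minutes. Default 0 (midnight).
#' @return A list state: `g` (mg/dl), `x` (remote action, min^-1), `ip`
#'   (plasma insulin pool, U), `isc1`, `isc2` (subcutaneous depots, U), `q1`
#'   (stomach glucose, mg), `q2` (gut glucose, mg).
#' @export
patient_init_state <- function(params, t0 = 0) {
  u_b <- basal_rate_at(params$profile, t0) / 60
  list(g = params$gb, x = 0, ip = u_b / params$k_e,
       isc1 = u_b / params$k_sc, isc2 = u_b / params$k_sc, q1 = 0, q2 = 0)
}

#' Advance the virtual patient one step
#'
#' Integrates the plant for `dt` minutes under a constant delivery rate.
#' Carbohydrate and bolus impulses are applied at the start of the step.
#' Glucose uses an exponential (unconditionally positive) update; the linear
#' insulin/gut states use explicit Euler at the 1-min plant step.
#'
#' @param state Plant state from [patient_init_state()] or a previous step.
#' @param params A [patient_params()] (absorption rates possibly perturbed).
#' @param u_d Delivered insulin rate, U/min (>= 0).
#' @param carb_g Carbohydrate impulse ingested at the start of the step, g.
#' @param dt Step, min (> 0).
#' @param si_t Insulin sensitivity in force over the step (circadian value).
#' @param u_basal_t Scheduled open-loop basal rate over the step, U/min; sets
#'   the plasma-insulin deviation the remote action responds to.
#' @param bolus_u Insulin bolus impulse at the start of the step, U.
#' @return Updated state list.
#' @export
patient_step <- function(state, params, u_d, carb_g, dt, si_t,
                         u_basal_t, bolus_u = 0) {
  if (!all(is.finite(unlist(state)))) stop("non-finite plant state")
  stopifnot(dt > 0, u_d >= 0, carb_g >= 0, bolus_u >= 0)
  g <- state$g; x <- state$x; ip <- state$ip
  isc1 <- state$isc1 + bolus_u; isc2 <- state$isc2
  q1 <- state$q1 + carb_g * 1000; q2 <- state$q2
  ra <- params$f * params$k_abs * q2 / params$v        # mg/dl/min
  ip_b <- u_basal_t / params$k_e
  # glucose: dg = -(p1 + x) g + p1 gb + ra + counterregulation, exponential
  # update; below g_cr the counterregulatory term adds k_cr (g_cr - g)
  a <- params$p1 + x
  inp <- params$p1 * params$gb + ra
  if (g < params$g_cr) {
    a <- a + params$k_cr
    inp <- inp + params$k_cr * params$g_cr
  }
  if (a > 1e-8) {
    geq <- inp / a
    g <- geq + (g - geq) * exp(-a * dt)
  } else {
    g <- g + dt * (-a * g + inp)
  }
  x <- x + dt * (-params$p2 * (x - si_t * (ip - ip_b)))
  ip <- ip + dt * (params$k_sc * isc2 - params$k_e * ip)
  isc2 <- isc2 + dt * params$k_sc * (isc1 - isc2)
  isc1 <- isc1 + dt * (u_d - params$k_sc * isc1)
  q2 <- q2 + dt * (params$k_emp * q1 - params$k_abs * q2)
  q1 <- q1 * exp(-params$k_emp * dt)
  list(g = max(g, 1), x = x, ip = max(ip, 0), isc1 = max(isc1, 0),
       isc2 = max(isc2, 0), q1 = q1, q2 = max(q2, 0))
}

#' CGM reading
#'
#' @param g Plasma glucose, mg/dl (or a plant state list).
#' @param noise_sd Additive Gaussian noise SD, mg/dl. Default 0 (noiseless).
#' @return Sensor reading, mg/dl (floored at 1).
#' @export
cgm_read <- function(g, noise_sd = 0) {
  if (is.list(g)) g <- g$g
  if (noise_sd > 0) g <- g + stats::rnorm(length(g), 0, noise_sd)
  pmax(g, 1)
}

# deterministic sub-seed derivation; keeps values in [1, 2^31 - 2]
derive_seed <- function(master, ...) {
  keys <- c(master, ...)
  h <- 0
  for (k in keys) h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

# one sampled patient; NULL if the basal steady-state check fails
sample_patient <- function(id) {
  gb <- stats::runif(1, 110, 140)
  base <- stats::runif(1, 0.6, 1.4)
  prof <- basal_profile(c("00:00", "06:00", "12:00", "22:00"),
                        base * c(0.90, 1.10, 1.00, 0.95))
  daily_basal <- basal_insulin_between(prof, 0, 1440)
  tdi <- daily_basal / 0.5                 # basal ~50% of total daily insulin
  i2c <- 450 / tdi
  cf <- 1700 / tdi
  k_e <- 0.1
  k_sc <- stats::runif(1, 0.02, 0.03)
  k_emp <- stats::runif(1, 0.025, 0.045)
  k_abs <- stats::runif(1, 0.008, 0.015)
  v <- stats::runif(1, 120, 180)
  si0 <- cf * k_e / gb
  ipb_max <- max(prof$rate_U_per_h) / 60 / k_e
  p1 <- stats::runif(1, 1.2, 1.8) * 1.3 * si0 * ipb_max
  p2 <- stats::runif(1, 0.025, 0.04)
  patient_params(gb = gb, p1 = p1, p2 = p2, si0 = si0, k_e = k_e,
                 k_sc = k_sc, k_emp = k_emp, k_abs = k_abs, f = 0.8, v = v,
                 tdi = tdi, i2c = i2c, cf = cf, profile = prof, id = id)
}

# 24-h basal-only run; TRUE if glucose stays within tol of basal glucose
basal_steady_check <- function(params, tol = 10) {
  st <- patient_init_state(params)
  for (t in 0:1439) {
    u_b <- basal_rate_at(params$profile, t) / 60
    st <- patient_step(st, params, u_d = u_b, carb_g = 0, dt = 1,
                       si_t = params$si0, u_basal_t = u_b)
    if (abs(st$g - params$gb) > tol) return(FALSE)
  }
  TRUE
}

#' Generate a surrogate virtual-patient cohort
#'
#' Samples heterogeneous patients (basal glucose, basal profile, absorption
#' and sensitivity rates, distribution volume) within physiological ranges
#' and derives each patient's therapy block from the sampled physiology: TDI
#' from the basal schedule (basal as half of TDI), the insulin-to-carb ratio
#' by the 450 rule and the correction factor by the 1700 rule. Patients whose
#' plant does not hold basal glucose within 10 mg/dl over 24 h under their
#' own basal schedule are rejected and resampled. Deterministic given `seed`.
#'
#' @param n Number of patients (>= 1).
#' @param seed Master seed (non-negative integer).
#' @return A list of `n` [patient_params()] objects, ids `1:n`.
#' @export
generate_cohort <- function(n, seed = 1) {
  stopifnot(n >= 1)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in 1:100) {
      set.seed(derive_seed(seed, 101L, i, attempt))
      p <- sample_patient(i)
      if (basal_steady_check(p)) break
      p <- NULL
    }
    if (is.null(p)) stop("could not sample a feasible patient (id ", i, ")")
    cohort[[i]] <- p
  }
  cohort
}

#' Write or read a cohort as JSON
#'
#' @param cohort A list of [patient_params()].
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the cohort.
#' @export
write_cohort <- function(cohort, path) {
  out <- lapply(cohort, function(p) {
    prof <- p$profile
    p$profile <- list(start_min = prof$start_min,
                      rate_U_per_h = prof$rate_U_per_h)
    unclass(p)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(p) {
    prof <- basal_profile(unlist(p$profile$start_min),
                          unlist(p$profile$rate_U_per_h))
    patient_params(gb = p$gb, p1 = p$p1, p2 = p$p2, si0 = p$si0, k_e = p$k_e,
                   k_sc = p$k_sc, k_emp = p$k_emp, k_abs = p$k_abs, f = p$f,
                   v = p$v,
                   tdi = p$tdi, i2c = p$i2c, cf = p$cf, profile = prof,
                   k_cr = p$k_cr, g_cr = p$g_cr, id = p$id)
  })
}
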