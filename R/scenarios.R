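#' Simulation scenarios
#'
#' Three stress scenarios for the closed loop, each defined by a daily meal
#' pattern and the treatment arms compared:
#'
#' * `scenario_a()`: 7 days, one 60-g meal per day at a random time between
#'   10:00 and 16:00, announced exactly; DRB versus the fixed 60-g constraint
#'   (the meal size the fixed constraint was designed for).
#' * `scenario_b()`: 45 days, one meal per day of 40–120 g (uniform) between
#'   08:00 and 19:00; DRB versus fixed.
#' * `scenario_c()`: 14 days, three meals per day at 07:30 (45 g), 13:00
#'   (90 g) and 18:30 (50 g), each announced with a uniform ±15% carb-counting
#'   error; all four arms.
#'
#' @param days Scenario duration in days (defaults follow the scenario
#'   definitions above; shorter runs are useful for quick checks).
#' @return A `scenario` object: name, days, per-day meal specification and
#'   default arms.
#' @export
scenario_a <- function(days = 7) {
  new_scenario("A", days,
               data.frame(window_start = parse_clock("10:00"),
                          window_end = parse_clock("16:00"),
                          grams_lo = 60, grams_hi = 60),
               ann_error = 0, arms = c("drb", "fixed"))
}

#' @rdname scenario_a
#' @export
scenario_b <- function(days = 45) {
  new_scenario("B", days,
               data.frame(window_start = parse_clock("08:00"),
                          window_end = parse_clock("19:00"),
                          grams_lo = 40, grams_hi = 120),
               ann_error = 0, arms = c("drb", "fixed"))
}

#' @rdname scenario_a
#' @export
scenario_c <- function(days = 14) {
  tt <- parse_clock(c("07:30", "13:00", "18:30"))
  new_scenario("C", days,
               data.frame(window_start = tt, window_end = tt,
                          grams_lo = c(45, 90, 50), grams_hi = c(45, 90, 50)),
               ann_error = 0.15,
               arms = c("drb", "fixed", "baseline_only", "unconstrained"))
}

new_scenario <- function(name, days, meal_spec, ann_error, arms) {
  stopifnot(days >= 1, all(meal_spec$grams_lo > 0),
            all(meal_spec$grams_lo <= meal_spec$grams_hi),
            all(meal_spec$window_start <= meal_spec$window_end),
            all(meal_spec$window_end < 1440), ann_error >= 0, ann_error < 1)
  structure(list(name = name, days = days, meal_spec = meal_spec,
                 ann_error = ann_error, arms = arms),
            class = "scenario")
}

#' Draw the meal realisation for one patient
#'
#' Samples, per day and per scheduled meal: the meal time (uniform on the
#' window, snapped to the controller grid), the true grams (uniform on the
#' gram range), the announced grams (true grams times one plus a uniform
#' error on `[-ann_error, +ann_error]`), and the per-meal absorption
#' perturbation factors (uniform on `[0.7, 1.3]` for the gut and insulin
#' absorption rates). The draw depends on the seed and patient id only, so
#' all treatment arms face identical meals.
#'
#' @param scenario A scenario object.
#' @param patient_id Patient identifier (enters the seed derivation).
#' @param seed Master seed.
#' @param days Number of days (default: the scenario's duration).
#' @param sample_period Controller period for time snapping, min.
#' @return A data frame with columns `t_min`, `grams_true`, `grams_announced`,
#'   `kabs_mult`, `ksc_mult`, sorted by time.
#' @export
build_meals <- function(scenario, patient_id, seed, days = scenario$days,
                        sample_period = 5) {
  stopifnot(inherits(scenario, "scenario"))
  set.seed(derive_seed(seed, 13L, patient_id))
  spec <- scenario$meal_spec
  out <- vector("list", days * nrow(spec))
  n <- 0L
  for (d in seq_len(days) - 1L) {
    for (r in seq_len(nrow(spec))) {
      tod <- stats::runif(1, spec$window_start[r], spec$window_end[r])
      tod <- round(tod / sample_period) * sample_period
      grams <- stats::runif(1, spec$grams_lo[r], spec$grams_hi[r])
      err <- if (scenario$ann_error > 0)
        stats::runif(1, -scenario$ann_error, scenario$ann_error) else 0
      n <- n + 1L
      out[[n]] <- data.frame(t_min = d * 1440 + tod,
                             grams_true = grams,
                             grams_announced = grams * (1 + err),
                             kabs_mult = stats::runif(1, 0.7, 1.3),
                             ksc_mult = stats::runif(1, 0.7, 1.3))
    }
  }
  m <- do.call(rbind, out)
  m[order(m$t_min), , drop = FALSE]
}

#' Run a scenario over a cohort
#'
#' Simulates every (patient, arm) pair through the closed loop. Meals,
#' circadian phases and CGM noise are drawn from seeds derived from `seed`
#' and the patient id — never the arm — so arms are compared pairwise under
#' identical disturbances. Per-run failures are recorded and reported, not
#' silently dropped.
#'
#' @param scenario A scenario object from [scenario_a()], [scenario_b()] or
#'   [scenario_c()].
#' @param cohort A list of [patient_params()] (see [generate_cohort()]).
#' @param seed Master seed for all scenario randomness.
#' @param arms Arms to run; defaults to the scenario's arms.
#' @param days Override the scenario duration.
#' @param cgm_sd CGM additive noise SD, mg/dl. Default 0 (noiseless).
#' @param sparams,dparams,iparams Layer parameter objects.
#' @param sample_period Controller period, min.
#' @return A list: `traces` (all runs row-bound), `metrics` (see
#'   [metrics_report()]), `meals` (per-patient meal draws), `failures`
#'   (data frame of failed runs, zero rows when all succeed).
#' @export
run_scenario <- function(scenario, cohort, seed = 1, arms = scenario$arms,
                         days = scenario$days, cgm_sd = 0,
                         sparams = safe_params(), dparams = drb_params(),
                         iparams = iob_params(), sample_period = 5) {
  stopifnot(inherits(scenario, "scenario"), length(cohort) >= 1)
  traces <- list(); meals_by_pid <- list()
  failures <- data.frame(patient_id = integer(0), arm = character(0),
                         error = character(0))
  K <- days * 1440L %/% sample_period
  for (p in cohort) {
    pid <- p$id
    meals <- build_meals(scenario, pid, seed, days, sample_period)
    meals_by_pid[[as.character(pid)]] <- meals
    set.seed(derive_seed(seed, 7L, pid))
    phase <- stats::runif(1)
    noise <- if (cgm_sd > 0) {
      set.seed(derive_seed(seed, 11L, pid))
      stats::rnorm(K, 0, cgm_sd)
    } else NULL
    for (a in arms) {
      tr <- tryCatch(
        simulate_patient(p, days, meals, arm = a, sparams = sparams,
                         dparams = dparams, iparams = iparams,
                         phase = phase, cgm_noise = noise,
                         sample_period = sample_period),
        error = function(e) e)
      if (inherits(tr, "error")) {
        failures <- rbind(failures,
                          data.frame(patient_id = pid, arm = a,
                                     error = conditionMessage(tr)))
      } else {
        traces[[length(traces) + 1L]] <- tr
      }
    }
  }
  if (!length(traces)) stop("all runs failed")
  all_tr <- do.call(rbind, traces)
  attr(all_tr, "sample_period") <- sample_period
  list(traces = all_tr,
       metrics = metrics_report(all_tr, meals = meals_by_pid,
                                period = sample_period),
       meals = meals_by_pid,
       failures = failures)
}
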