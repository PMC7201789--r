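#' Simulate one patient under one treatment arm
#'
#' Runs the full closed loop — virtual patient, IOB estimator, insulin
#' feedback, PD controller, SAFE reference-conditioning layer, and the IOB
#' limit policy of the chosen arm — for `n_days` simulated days. The plant and
#' estimators advance on a 1-min internal step; the CGM, controller, SAFE
#' switching and DRB rules run at the (5-min) controller period. The plant
#' dynamics are the same equations as [patient_step()], inlined here for
#' speed. The CGM glucose and its derivative are sampled at the controller
#' period; the SAFE switching law, reference filter, PD arithmetic, insulin
#' feedback and commanded delivery are evaluated every internal minute —
#' the discrete counterpart of the continuous-time sliding-mode layer — while
#' the DRB rules, which act on BG readings, run once per CGM sample.
#'
#' Arms: `"drb"` (dynamic rule-based IOB limit), `"fixed"` (the clinically
#' validated single 60-g constraint), `"baseline_only"` (the fasting baseline
#' with no postprandial rules), `"unconstrained"` (no IOB limit).
#'
#' @param patient A [patient_params()].
#' @param n_days Simulated days (>= 1).
#' @param meals Data frame with columns `t_min` (absolute announcement time,
#'   a multiple of the controller period), `grams_true`, `grams_announced`,
#'   `kabs_mult`, `ksc_mult` (per-meal absorption perturbation factors).
#'   May have zero rows.
#' @param arm One of `"drb"`, `"fixed"`, `"baseline_only"`, `"unconstrained"`.
#' @param cparams A [controller_params()]; defaults to the patient's therapy
#'   block with published gains.
#' @param sparams A [safe_params()].
#' @param dparams A [drb_params()].
#' @param iparams An [iob_params()].
#' @param phase Circadian phase for insulin sensitivity, in `[0, 1)`.
#' @param cgm_noise Optional vector of additive CGM noise (mg/dl), one value
#'   per controller sample; `NULL` for a noiseless sensor.
#' @param sample_period Controller/CGM period, min. Default 5.
#' @return A `sim_trace` data frame with one row per controller sample:
#'   `time_min`, `G`, `G_rf`, `u_d` (mean delivered rate over the sample
#'   interval, U/min, boluses excluded), `bolus`, `IOB_hat`, `IOB_bar`,
#'   `arm`, `patient_id`.
#' @export
simulate_patient <- function(patient, n_days, meals,
                             arm = c("drb", "fixed", "baseline_only",
                                     "unconstrained"),
                             cparams = NULL, sparams = safe_params(),
                             dparams = drb_params(), iparams = iob_params(),
                             phase = 0, cgm_noise = NULL, sample_period = 5) {
  arm <- match.arg(arm)
  stopifnot(inherits(patient, "patient_params"), n_days >= 1)
  if (is.null(cparams))
    cparams <- controller_params(tdi = patient$tdi, i2c = patient$i2c,
                                 cf = patient$cf)
  Ts <- sample_period
  N <- as.integer(n_days * 1440)
  K <- N %/% Ts
  prof <- patient$profile

  # per-minute schedules
  tmin <- 0:(N - 1L)
  u_bas <- basal_rate_at(prof, tmin) / 60                 # U/min
  si <- circadian_param(tmin, patient$si0, phase)
  ts <- Ts * (0:(K - 1L))                                 # sample times
  base_lim <- baseline_limit(ts, prof, dparams$schedule, iparams)
  fixed_lim <- if (arm == "fixed")
    fixed_iob_constraint(prof, patient$i2c, "12:00", iparams) else NA_real_
  if (is.null(cgm_noise)) cgm_noise <- numeric(K)
  stopifnot(length(cgm_noise) == K)

  # meal lookup by sample index
  meal_at <- integer(K)
  if (nrow(meals) > 0) {
    stopifnot(all(meals$t_min %% Ts == 0), all(meals$t_min < N),
              !is.unsorted(meals$t_min))
    meal_at[meals$t_min %/% Ts + 1L] <- seq_len(nrow(meals))
  }

  # parameter shorthands
  p1 <- patient$p1; p2 <- patient$p2; k_e <- patient$k_e
  k_sc0 <- patient$k_sc; k_abs0 <- patient$k_abs; k_emp <- patient$k_emp
  fv <- patient$f / patient$v; gb <- patient$gb
  k_cr <- patient$k_cr; g_cr <- patient$g_cr
  k <- iparams$k_dia
  tau <- sparams$tau; W <- sparams$W; lam <- sparams$lambda
  kp <- cparams$kp; td <- cparams$td; g_r <- cparams$g_r
  gamma <- cparams$gamma; k_ifb <- cparams$k_ifb
  e_lam <- exp(-lam); e_ifb <- exp(-k_ifb)

  # initial conditions: basal steady state everywhere
  u_b0 <- u_bas[1L]
  g <- gb; x <- 0; ip <- u_b0 / k_e
  isc1 <- u_b0 / k_sc0; isc2 <- u_b0 / k_sc0; q1 <- 0; q2 <- 0
  c1 <- u_b0 / k; c2 <- u_b0 / k
  d1 <- 0; d2 <- 0
  g_rf <- g_r
  drb_st <- constraint_state()
  kabs_mult <- 1; ksc_mult <- 1
  prev_iob_hat <- c1 + c2
  prev_hat_min <- prev_iob_hat
  prev_g <- NA_real_

  o_g <- numeric(K); o_grf <- numeric(K); o_ud <- numeric(K)
  o_bol <- numeric(K); o_hat <- numeric(K); o_bar <- numeric(K)

  for (kk in seq_len(K)) {
    t <- ts[kk]
    g_cgm <- max(g + cgm_noise[kk], 1)
    dgdt <- if (is.na(prev_g)) 0 else (g_cgm - prev_g) / Ts
    iob_hat <- c1 + c2

    lim <- switch(arm,
      drb = {
        res <- current_limit(drb_st, t, g_cgm, prev_iob_hat, base_lim[kk],
                             dparams)
        drb_st <- res$state
        res$limit
      },
      baseline_only = base_lim[kk],
      fixed = fixed_lim,
      unconstrained = Inf)

    bolus <- 0; carb <- 0
    mi <- meal_at[kk]
    if (mi > 0L) {
      bolus <- meal_bolus(meals$grams_announced[mi], g_cgm, cparams, prof,
                          t %% 1440)
      carb <- meals$grams_true[mi]
      kabs_mult <- meals$kabs_mult[mi]
      ksc_mult <- meals$ksc_mult[mi]
      if (arm == "drb")
        drb_st <- on_meal_announced(drb_st, t, meals$grams_announced[mi],
                                    dparams)
    }

    o_g[kk] <- g_cgm; o_grf[kk] <- g_rf
    o_bol[kk] <- bolus; o_hat[kk] <- iob_hat; o_bar[kk] <- lim

    # impulses routed to estimators and plant
    c1 <- c1 + bolus; d1 <- d1 + bolus
    isc1 <- isc1 + bolus; q1 <- q1 + carb * 1000

    k_abs <- k_abs0 * kabs_mult; k_sc <- k_sc0 * ksc_mult
    e_q1 <- exp(-k_emp)
    delivered <- 0
    for (j in 1:Ts) {
      i <- t + j                                  # minute index [i-1, i)
      ub <- u_bas[i]
      # SAFE switching at the internal step; the limit is piecewise
      # constant, so its derivative term is 0
      hat_min <- c1 + c2
      sigma <- (hat_min - lim) + tau * (hat_min - prev_hat_min)
      omega <- if (is.finite(lim) && sigma > 0) W else 0
      prev_hat_min <- hat_min
      # conditioned-reference filter (exact over the minute)
      target <- g_r + omega / lam
      g_rf <- target + (g_rf - target) * e_lam
      # PD + feed-forward basal + insulin feedback, held CGM sample
      u_pd <- kp * ((g_cgm - g_rf) + td * dgdt)
      u_d <- max(0, u_pd + ub - gamma * d2)
      delivered <- delivered + u_d
      # IOB estimator, 1-min Heun step (same scheme as step_iob "fixed")
      f1 <- u_d - k * c1
      f2 <- k * (c1 - c2)
      c1e <- c1 + f1
      c2e <- c2 + f2
      c1 <- c1 + 0.5 * (f1 + (u_d - k * c1e))
      c2 <- c2 + 0.5 * (f2 + k * (c1e - c2e))
      # IFB deviation chain (exact over 1 min)
      uss <- (u_d - ub) / k_ifb
      nd1 <- uss + (d1 - uss) * e_ifb
      d2 <- uss + ((d2 - uss) + k_ifb * (d1 - uss)) * e_ifb
      d1 <- nd1
      # plant (same equations as patient_step)
      ra <- fv * k_abs * q2
      a <- p1 + x
      inp <- p1 * gb + ra
      if (g < g_cr) {
        a <- a + k_cr
        inp <- inp + k_cr * g_cr
      }
      if (a > 1e-8) {
        geq <- inp / a
        g <- geq + (g - geq) * exp(-a)
      } else {
        g <- g + (-a * g + inp)
      }
      x <- x + (-p2 * (x - si[i] * (ip - ub / k_e)))
      ip <- max(ip + (k_sc * isc2 - k_e * ip), 0)
      isc2 <- isc2 + k_sc * (isc1 - isc2)
      isc1 <- max(isc1 + (u_d - k_sc * isc1), 0)
      q2 <- max(q2 + (k_emp * q1 - k_abs * q2), 0)
      q1 <- q1 * e_q1
      g <- max(g, 1)
    }
    o_ud[kk] <- delivered / Ts
    if (!is.finite(g) || !is.finite(c1) || !is.finite(g_rf))
      stop("closed-loop divergence at t = ", t, " min (arm ", arm, ")")
    prev_iob_hat <- iob_hat
    prev_g <- g_cgm
  }

  structure(data.frame(time_min = ts, G = o_g, G_rf = o_grf, u_d = o_ud,
                       bolus = o_bol, IOB_hat = o_hat, IOB_bar = o_bar,
                       arm = arm, patient_id = patient$id,
                       stringsAsFactors = FALSE),
            class = c("sim_trace", "data.frame"),
            sample_period = Ts)
}

#' Controller sample period of a trace
#'
#' @param trace A `sim_trace` (or any trace data frame with uniform sampling).
#' @return Sampling period in minutes.
#' @export
trace_period <- function(trace) {
  p <- attr(trace, "sample_period")
  if (!is.null(p)) return(p)
  tt <- sort(unique(trace$time_min))
  if (length(tt) < 2L) stop("cannot infer sampling period from a single sample")
  d <- unique(diff(tt))
  if (length(d) != 1L) stop("trace has mixed sampling periods")
  d
}
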