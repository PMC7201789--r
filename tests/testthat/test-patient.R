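test_that("circadian modulation is a 30% 24-h sinusoid", {
  expect_equal(circadian_param(0, 10, 0), 10)
  expect_equal(circadian_param(360, 10, 0), 13)   # quarter period
  tt <- seq(0, 2880, by = 7)
  q <- circadian_param(tt, 5, 0.37)
  expect_true(all(q >= 0.7 * 5 & q <= 1.3 * 5))
  expect_equal(max(q), 1.3 * 5, tolerance = 1e-3)
})

test_that("meal perturbations scale absorption rates within +/-30%", {
  p <- test_cohort(1)[[1]]
  same <- perturb_meal_params(p, factors = c(1, 1))
  expect_equal(same$k_abs, p$k_abs)
  low <- perturb_meal_params(p, factors = c(0.7, 0.7))
  expect_equal(low$k_abs, 0.7 * p$k_abs)
  expect_equal(low$k_sc, 0.7 * p$k_sc)
  set.seed(123)
  draws <- t(replicate(1000, {
    q <- perturb_meal_params(p)
    c(q$k_abs / p$k_abs, q$k_sc / p$k_sc)
  }))
  expect_true(all(draws >= 0.7 & draws <= 1.3))
  expect_equal(colMeans(draws), c(1, 1), tolerance = 0.02)
})

test_that("the plant holds basal glucose under its own basal schedule", {
  for (p in test_cohort(2)) {
    st <- patient_init_state(p)
    for (t in 0:1439) {
      ub <- basal_rate_at(p$profile, t) / 60
      st <- patient_step(st, p, ub, 0, 1, p$si0, ub)
    }
    expect_lt(abs(st$g - p$gb), 10)
  }
})

test_that("an uncovered meal raises glucose to a peak above baseline", {
  p <- test_cohort(1)[[1]]
  st <- patient_init_state(p)
  g <- numeric(600)
  for (t in 0:599) {
    ub <- basal_rate_at(p$profile, t) / 60
    st <- patient_step(st, p, ub, carb_g = if (t == 0) 60 else 0, 1,
                       p$si0, ub)
    g[t + 1] <- st$g
  }
  pk <- which.max(g)
  expect_gt(max(g), p$gb + 40)
  expect_true(all(diff(g[10:pk]) > 0))          # rise to the peak
  expect_lt(g[600], max(g))                     # and back down
})

test_that("insulin deprivation drives glucose up toward a bounded ceiling", {
  p <- test_cohort(1)[[1]]
  st <- patient_init_state(p)
  ub <- basal_rate_at(p$profile, 0) / 60        # autonomous case: flat basal
  g <- numeric(2880)
  for (t in seq_len(2880)) {
    st <- patient_step(st, p, 0, 0, 1, p$si0, ub)
    g[t] <- st$g
  }
  expect_true(all(diff(g[60:2880]) >= -1e-9))   # monotone approach
  expect_lt(max(g), 500)                         # bounded equilibrium
  expect_gt(g[2880], p$gb + 50)
})

test_that("a larger bolus yields a lower postprandial minimum", {
  p <- test_cohort(1)[[1]]
  run_min <- function(bolus) {
    st <- patient_init_state(p)
    lo <- Inf
    for (t in 0:899) {
      ub <- basal_rate_at(p$profile, t) / 60
      st <- patient_step(st, p, ub, carb_g = if (t == 0) 60 else 0, 1,
                         p$si0, ub, bolus_u = if (t == 0) bolus else 0)
      if (t > 60) lo <- min(lo, st$g)          # postprandial window minimum
    }
    lo
  }
  mins <- vapply(c(6, 9, 12, 15), run_min, 0)
  expect_true(all(diff(mins) < 0))
})

test_that("cohort generation is deterministic, heterogeneous and feasible", {
  c1 <- generate_cohort(5, seed = 9)
  c2 <- generate_cohort(5, seed = 9)
  expect_identical(c1, c2)
  tdis <- vapply(c1, `[[`, 0, "tdi")
  expect_equal(length(unique(round(tdis, 6))), 5)
  expect_gt(stats::sd(tdis) / mean(tdis), 0)
  for (p in c1) {
    expect_s3_class(p$profile, "basal_profile")
    expect_true(all(c(p$p1, p$p2, p$si0, p$k_e, p$k_sc, p$k_emp,
                      p$k_abs) > 0))
    # therapy consistent with the published heuristics
    expect_equal(p$i2c, 450 / p$tdi)
    expect_equal(p$cf, 1700 / p$tdi)
  }
})

test_that("cohort JSON round trip preserves every patient", {
  co <- test_cohort(3)
  path <- withr::local_tempfile(fileext = ".json")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  for (i in seq_along(co))
    expect_equal(co2[[i]], co[[i]], tolerance = 1e-12)
})

test_that("CGM reading is the plasma glucose unless noise is requested", {
  expect_equal(cgm_read(123.4), 123.4)
  expect_equal(cgm_read(123.4, noise_sd = 0), 123.4)
  set.seed(5)
  reads <- cgm_read(rep(120, 1e4), noise_sd = 5)
  # folded-normal mean absolute deviation: sd * sqrt(2/pi)
  expect_equal(mean(abs(reads - 120)), 5 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("glucose stays bounded over 14 basal-only days in closed loop", {
  p <- test_cohort(1)[[1]]
  tr <- simulate_patient(p, 14, meals = data.frame(), arm = "baseline_only",
                         phase = 0.5)
  expect_true(all(is.finite(tr$G)))
  expect_true(all(tr$G > 40 & tr$G < 300))
})
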