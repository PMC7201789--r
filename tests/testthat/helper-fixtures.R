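# shared fixtures: built in code, deterministic

flat_profile <- function(rate = 1) basal_profile("00:00", rate)

# a small fixed cohort for closed-loop tests
test_cohort <- function(n = 2, seed = 42) generate_cohort(n, seed)

# independent brute-force run-length scan for hypoglycemic events
brute_hypo_events <- function(g, period, threshold = 70, min_duration = 15) {
  count <- 0L
  run <- 0L
  for (v in g) {
    if (v < threshold) {
      run <- run + 1L
    } else {
      if (run * period >= min_duration) count <- count + 1L
      run <- 0L
    }
  }
  if (run * period >= min_duration) count <- count + 1L
  count
}

# matrix-exponential solution of the two-compartment absorption chain,
# independent of the package's own updates
expm_iob <- function(c1, c2, u, dt, k) {
  A <- matrix(c(-k, 0, k, -k), 2, 2, byrow = TRUE)
  x0 <- c(c1, c2)
  eAt <- as.matrix(Matrix::expm(A * dt))
  xp <- c(u / k, u / k)                      # particular (steady) solution
  eAt %*% (x0 - xp) + xp
}

# one-meal closed-loop run used by SAFE-layer tests
one_meal_run <- function(patient, grams = 60, meal_clock = "12:00",
                         days = 1, ...) {
  meals <- data.frame(t_min = parse_clock(meal_clock), grams_true = grams,
                      grams_announced = grams, kabs_mult = 1, ksc_mult = 1)
  simulate_patient(patient, days, meals, ...)
}
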