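test_that("fasting baseline scales the basal steady-state IOB by K_IOB", {
  prof <- flat_profile(1)
  sch <- kiob_schedule()
  # 1 U/h at K_DIA = 0.013: steady IOB 2.5641 U; day gain 1.3, night 1.1
  expect_equal(baseline_limit(parse_clock("12:00"), prof, sch),
               1.3 * 2 / (60 * 0.013), tolerance = 1e-6)
  expect_equal(baseline_limit(parse_clock("02:00"), prof, sch),
               1.1 * 2 / (60 * 0.013), tolerance = 1e-6)
  expect_equal(baseline_limit(0, flat_profile(0), sch), 0)
  # gain 1 reproduces the estimator's own steady state exactly
  sch1 <- kiob_schedule(day_gain = 1, night_gain = 1)
  expect_equal(baseline_limit(600, prof, sch1), steady_state_iob(1 / 60))
  # night limit below day limit for the same basal rate
  expect_lt(baseline_limit(parse_clock("03:00"), prof, sch),
            baseline_limit(parse_clock("15:00"), prof, sch))
  # boundaries: day window is [06:00, 23:00)
  expect_equal(kiob_at(sch, parse_clock("06:00")), 1.3)
  expect_equal(kiob_at(sch, parse_clock("23:00")), 1.1)
  expect_equal(kiob_at(sch, parse_clock("05:59")), 1.1)
})

test_that("evaluation delay is 1.5 min per announced gram", {
  expect_equal(t_iob(45), 67.5)
  expect_equal(t_iob(60), 90)
  expect_equal(t_iob(0), 0)
  expect_equal(t_iob(45, slope = 2), 90)
})

test_that("meal announcement opens and resets the postprandial window", {
  st <- constraint_state()
  expect_equal(st$pp_state, 0L)
  expect_equal(st$flag_pp, 0L)
  st <- on_meal_announced(st, t = 450, m_cho_announced = 45)
  expect_equal(st$pp_state, 1L)
  expect_equal(st$meal_time, 450)
  expect_equal(st$t_iob, 67.5)                 # evaluation starts 67.5 min in
  # a second meal mid-window replaces the window
  st$flag_pp <- 1L; st$iob_bar_pp <- 9
  st <- on_meal_announced(st, t = 600, m_cho_announced = 90)
  expect_equal(st$meal_time, 600)
  expect_equal(st$t_iob, 135)
  expect_equal(st$flag_pp, 0L)
  expect_true(is.na(st$iob_bar_pp))
  expect_error(on_meal_announced(constraint_state(), 0, 0), "positive")
})

test_that("the limit follows every branch of the postprandial rule set", {
  dp <- drb_params()
  bl <- 3.333
  st <- constraint_state()
  # fasting: pass-through
  r <- current_limit(st, 0, 120, 3, bl, dp)
  expect_equal(r$limit, bl)
  # meal at t=0 (45 g): before T_IOB the limit stays at baseline
  st <- on_meal_announced(st, 0, 45, dp)
  r <- current_limit(st, 65, 180, 6.0, bl, dp); st <- r$state
  expect_equal(r$limit, bl)
  expect_equal(st$flag_pp, 0L)
  # at/after T_IOB with G > 150: single raise to max(prev IOB estimate, bl)
  r <- current_limit(st, 70, 160, 6.0, bl, dp); st <- r$state
  expect_equal(r$limit, 6.0)
  expect_equal(st$flag_pp, 1L)
  # held while G > release threshold, even if G drops below the trigger
  r <- current_limit(st, 75, 145, 5.5, bl, dp); st <- r$state
  expect_equal(r$limit, 6.0)
  # release at G <= 140: back to baseline, window closed
  r <- current_limit(st, 80, 139, 5.0, bl, dp); st <- r$state
  expect_equal(r$limit, bl)
  expect_equal(st$pp_state, 0L)
  expect_equal(st$flag_pp, 0L)
  # no re-raise without a new meal
  r <- current_limit(st, 85, 200, 8.0, bl, dp)
  expect_equal(r$limit, bl)
})

test_that("the raise uses the baseline when the IOB estimate is lower", {
  dp <- drb_params()
  st <- on_meal_announced(constraint_state(), 0, 45, dp)
  r <- current_limit(st, 70, 160, iob_hat_prev = 2.0, baseline = 3.333, dp)
  expect_equal(r$limit, 3.333)                  # max(2.0, 3.333)
  expect_gte(r$state$iob_bar_pp, 3.333)
})

test_that("a window that never triggers closes once G falls to the release", {
  dp <- drb_params()
  st <- on_meal_announced(constraint_state(), 0, 45, dp)
  # after T_IOB, G between release and trigger: window open, limit baseline
  r <- current_limit(st, 70, 145, 6.0, 3.3, dp); st <- r$state
  expect_equal(r$limit, 3.3)
  expect_equal(st$pp_state, 1L)
  # G falls to the release threshold: closes without ever raising
  r <- current_limit(st, 75, 138, 6.0, 3.3, dp); st <- r$state
  expect_equal(st$pp_state, 0L)
  r <- current_limit(st, 80, 170, 6.0, 3.3, dp)
  expect_equal(r$limit, 3.3)                    # trigger after close: nothing
})

test_that("at most one raise happens per announced meal", {
  dp <- drb_params()
  st <- on_meal_announced(constraint_state(), 0, 60, dp)
  g_seq <- c(200, 190, 185, 180, 175, 170, 165, 160, 155, 150, 145, 139)
  lims <- numeric(length(g_seq))
  for (i in seq_along(g_seq)) {
    r <- current_limit(st, 90 + 5 * i, g_seq[i], 7 - 0.1 * i, 3.3, dp)
    st <- r$state
    lims[i] <- r$limit
  }
  raised <- lims > 3.3
  # one contiguous raised stretch, one frozen raised value
  expect_equal(sum(diff(c(FALSE, raised)) == 1), 1)
  expect_equal(length(unique(lims[raised])), 1)
  expect_equal(st$pp_state, 0L)                 # released at 139
})
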