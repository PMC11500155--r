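test_that("elapsed time is the set delay plus the loop latency", {
  run <- run_rtc_trial(preset4,
                       config = rtc_config("positive", set_delay = 1e-3,
                                           timeout = 0.5),
                       seed = 1)
  expect_false(run$timed_out)
  expect_equal(run$elapsed, 1.44e-3)  # 1 ms set delay + 0.44 ms latency
  expect_true(is.finite(run$intensity))
})

test_that("an unsatisfiable condition times out and is flagged", {
  cone_jet <- make_preset(6)  # cone always present => negative never fires
  run <- run_rtc_trial(cone_jet,
                       config = rtc_config("negative", timeout = 0.05),
                       seed = 1)
  expect_true(run$timed_out)
  expect_true(is.na(run$intensity))
})

test_that("gate causality: no signal from flux before the gate opens", {
  # noise-free chain with no transit or mixing: every event that ends
  # before the gate opens must be exactly zero
  ch <- chain_params(transit_delay = 0, mixing_tau = 0,
                     detector_noise_sd = 0)
  run <- run_rtc_trial(preset4, chain = ch,
                       config = rtc_config("positive", set_delay = 20e-3,
                                           timeout = 0.5),
                       seed = 2)
  t_open <- run$trigger_frame_time + run$elapsed
  train <- generate_emission_train(preset4, 0.6, seed = 2)
  gate <- gate_waveform(matrix(c(t_open, t_open + 1e-3), ncol = 2))
  ms <- sample_sim_events(transit_mixing(apply_gate(train, gate), ch),
                          ch, 0.6, seed = 3)
  before <- ms$event_times + ms$event <= t_open
  expect_true(all(ms$intensity[before] == 0))
  expect_gt(run$intensity, 0)
})

test_that("delay calibration recovers slope 1 and the loop latency", {
  cal <- calibrate_delay(delay_ladder(0, reps = 2))
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_equal(cal$intercept, 0.44e-3, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  cal_j <- calibrate_delay(delay_ladder(0.02e-3, reps = 5))
  expect_lt(abs(cal_j$intercept - 0.44e-3), 0.05e-3)
  expect_equal(cal_j$slope, 1, tolerance = 0.05)
  expect_gt(cal_j$r_squared, 0.98)
})

test_that("latency recovery holds across jitter levels", {
  for (jit in c(0.01e-3, 0.03e-3, 0.06e-3)) {
    cal <- calibrate_delay(delay_ladder(jit, reps = 4,
                                        seed0 = round(jit * 1e7)))
    expect_lt(abs(cal$intercept - 0.44e-3), 3 * jit)
  }
})

test_that("degenerate delay ladders are rejected", {
  trials <- delay_ladder(0, reps = 1)
  one_delay <- trials[vapply(trials, function(x) x$set_delay == 0.2e-3,
                             logical(1))]
  expect_error(calibrate_delay(one_delay), "distinct set delays")
})

test_that("condition summaries handle identical and single-run cells", {
  mk <- function(cond, delay, intensity) {
    structure(list(condition = cond, set_delay = delay, elapsed = delay,
                   intensity = intensity, trigger_frame_time = 0,
                   timed_out = FALSE), class = "rtc_run")
  }
  same <- c(lapply(c(10, 20, 30), mk, cond = "positive", delay = 1e-3),
            lapply(c(10, 20, 30), mk, cond = "negative", delay = 1e-3))
  cmp <- compare_conditions(same, n_boot = 200, seed = 1)
  expect_equal(cmp$difference$diff, c(0, 0))

  single <- list(mk("positive", 1e-3, 10), mk("negative", 1e-3, 12))
  cmp1 <- compare_conditions(single, n_boot = 50, seed = 1)
  expect_true(all(is.na(cmp1$table$sd)))
  # missing cells are reported, not dropped
  pos_only <- list(mk("positive", 1e-3, 10), mk("positive", 1e-3, 11))
  cmp2 <- compare_conditions(pos_only, n_boot = 50, seed = 1)
  neg_row <- cmp2$table[cmp2$table$condition == "negative", ]
  expect_equal(neg_row$n, 0)
  expect_true(is.na(neg_row$mean))
})
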