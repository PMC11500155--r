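test_that("gate transmission multiplies flux and leaves the cone alone", {
  train <- generate_emission_train(preset4, 0.5, seed = 6)
  closed <- apply_gate(train, gate_waveform(matrix(numeric(0), ncol = 2)))
  expect_true(all(closed$flux == 0))
  expect_identical(closed$cone_state, train$cone_state)

  open <- apply_gate(train, gate_waveform())
  expect_identical(open$flux, train$flux)

  gated <- apply_gate(train, gate_waveform(rbind(c(0, 0.1), c(0.3, 0.4))))
  inside <- (train$times < 0.1) | (train$times >= 0.3 & train$times < 0.4)
  expect_true(all(gated$flux[!inside] == 0))
  expect_identical(gated$flux[inside], train$flux[inside])
  # the analytic model respects the gate too
  expect_equal(emission_flux_at(gated, train$times), gated$flux)
})

test_that("invalid gate schedules are rejected", {
  expect_error(gate_waveform(rbind(c(0, 1), c(0.5, 2))), "disjoint")
  expect_error(gate_waveform(rbind(c(1, 1))), "end > start")
})

test_that("transit mixing is a delayed, flux-conserving exponential kernel", {
  train <- generate_emission_train(preset4, 0.2, seed = 6)
  dt <- train$dt
  # tau = 0: pure delay
  pure <- chain_params(transit_delay = 1e-3, mixing_tau = 0)
  ar <- transit_mixing(train, pure)
  lag <- round(1e-3 / dt)
  expect_equal(ar$flux[(lag + 1):length(ar$flux)],
               train$flux[1:(length(ar$flux) - lag)])
  expect_true(all(ar$flux[1:lag] == 0))

  # unit impulse -> sampled exponential decay, unit mass
  imp <- train
  imp$flux <- rep(0, length(train$flux)); imp$flux[100] <- 1
  imp$model <- list(type = "no_spray")
  tau <- 5e-3
  mix <- transit_mixing(imp, chain_params(transit_delay = 0,
                                          mixing_tau = tau))
  a <- exp(-dt / tau)
  expect_equal(mix$flux[100:150], (1 - a) * a^(0:50))
  expect_equal(sum(mix$flux), 1, tolerance = 1e-3)

  # sinusoidal modulation attenuated by |1 / (1 + i 2 pi f tau)|
  f <- 1920
  sine <- train
  sine$flux <- 1 + sin(2 * pi * f * train$times)
  sine$model <- list(type = "no_spray")
  out <- transit_mixing(sine, chain_params(transit_delay = 0,
                                           mixing_tau = tau))
  settled <- out$flux[5000:length(out$flux)]
  gain <- sd(settled) * sqrt(2) / 1
  expect_equal(gain, 1 / sqrt(1 + (2 * pi * f * tau)^2), tolerance = 0.02)

  # conservation on a long window: mixing never creates flux
  arr <- transit_mixing(train, chain_params())
  expect_lte(sum(arr$flux), sum(train$flux))
  # edge loss is bounded by (delay + tau) / window = ~3% on 0.2 s
  expect_equal(sum(arr$flux) * dt, sum(train$flux) * dt, tolerance = 0.05)
})

test_that("SIM sampling integrates only the dwell window", {
  train <- generate_emission_train(preset4, 0.5, seed = 6)
  const <- train
  const$flux <- rep(3, length(train$flux))
  const$model <- list(type = "cone_jet", amp = 3)
  ch <- chain_params(transit_delay = 0, mixing_tau = 0,
                     detector_noise_sd = 0)
  ar <- transit_mixing(const, ch)
  ms <- sample_sim_events(ar, ch, 0.5, seed = 1)
  expect_length(ms$intensity, floor(0.5 / ch$event))
  expect_equal(ms$intensity,
               rep(ch$gain * 3 * ch$dwell, length(ms$intensity)))
  # linearity: doubling gain doubles noiseless intensities
  ch2 <- chain_params(transit_delay = 0, mixing_tau = 0,
                      detector_noise_sd = 0, gain = 2 * ch$gain)
  expect_equal(sample_sim_events(ar, ch2, 0.5, seed = 1)$intensity,
               2 * ms$intensity)
})

test_that("pulses falling outside every dwell window are invisible", {
  # pulses at 3 ms into each 4 ms event; dwell covers only the first 0.8 ms
  train <- generate_emission_train(preset4, 0.1, seed = 6)
  miss <- train
  miss$flux <- rep(0, length(train$flux))
  pulse_idx <- round((seq(3e-3, 0.099, by = 4e-3)) / train$dt) + 1
  miss$flux[pulse_idx] <- 100
  miss$model <- list(type = "no_spray")
  ch <- chain_params(transit_delay = 0, mixing_tau = 0,
                     detector_noise_sd = 0)
  ms <- sample_sim_events(transit_mixing(miss, ch), ch, 0.1, seed = 1)
  expect_true(all(ms$intensity == 0))
})

test_that("the gated end-to-end experiment matches the voltage regimes", {
  # below threshold: intensities at the (clipped) noise floor
  quiet <- run_gated_experiment(make_preset(1.0), duration = 2, seed = 4)
  expect_lt(mean(quiet$ms$intensity), 25)
  r <- spearman_rho(quiet$occupancy$percent, quiet$ms$intensity)
  expect_true(is.na(r))  # constant zero occupancy

  # burst mode: sparse isolated high events above the noise background
  sporadic <- run_gated_experiment(make_preset(2.5), duration = 4, seed = 4)
  noise_q <- quantile(quiet$ms$intensity, 0.999)
  expect_lt(mean(sporadic$ms$intensity > noise_q), 0.2)
  expect_gt(max(sporadic$ms$intensity), 2 * noise_q)

  # gate schedule confines flux to its windows
  g <- gate_waveform(rbind(c(0, 1), c(2, 3)))
  gexp <- run_gated_experiment(preset4, gate = g, duration = 4, seed = 4)
  blocked <- gexp$train$times >= 1 & gexp$train$times < 2
  expect_true(all(gexp$train$flux[blocked] == 0))
  expect_gt(sum(gexp$train$flux[!blocked]), 0)
})

test_that("event/dwell ratio and mixing tau erase the correlation", {
  exp <- run_gated_experiment(preset4, duration = 10, seed = 5)
  max_rho <- function(chain, continuous = FALSE) {
    ar <- transit_mixing(exp$train, chain)
    ms <- if (continuous) {
      sample_arrival_continuous(ar, chain, 10)
    } else {
      sample_sim_events(ar, chain, 10, seed = 99)
    }
    max(abs(shift_scan(exp$occupancy, ms)$rho), na.rm = TRUE)
  }
  ladder <- c(
    max_rho(chain_params(transit_delay = 0, mixing_tau = 0,
                         detector_noise_sd = 0), continuous = TRUE),
    max_rho(chain_params(transit_delay = 0, mixing_tau = 5e-3,
                         detector_noise_sd = 0)),
    max_rho(chain_params(transit_delay = 0, mixing_tau = 20e-3,
                         detector_noise_sd = 0)))
  expect_true(all(diff(ladder) < 0))
  expect_gt(ladder[1], 0.5)
})
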