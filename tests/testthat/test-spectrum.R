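test_that("spectra locate pure and mixed sinusoids at their bins", {
  rate <- 50000
  t <- (0:49999) / rate
  sp <- compute_spectrum(sin(2 * pi * 1000 * t), rate)
  expect_equal(peak_frequency(sp), 1000)

  # two tones: each a local maximum at its own bin
  two <- sin(2 * pi * 500 * t) + 0.8 * sin(2 * pi * 1900 * t)
  sp2 <- compute_spectrum(two, rate)
  expect_equal(peak_frequency(sp2, band = c(100, 1200)), 500)
  expect_equal(peak_frequency(sp2, band = c(1200, 25000)), 1900)

  # constant trace: mean subtraction leaves ~0 magnitude
  spc <- compute_spectrum(rep(3.7, 1024), rate)
  expect_lt(max(spc$magnitude), 1e-8)
})

test_that("spectrum preconditions are enforced", {
  expect_error(compute_spectrum(rnorm(32), 1000), ">= 64 samples")
  tj <- cumsum(runif(200, 0.5, 1.5))
  expect_error(compute_spectrum(rnorm(200), 1000, times = tj),
               "not uniform")
  sp <- compute_spectrum(rnorm(256), 1000)
  expect_error(peak_frequency(sp, band = c(600, 400)), "invalid band")
  expect_error(peak_frequency(sp, band = c(900, 2000)), "invalid band")
})

test_that("band restriction never returns out-of-band peaks", {
  ds <- generate_offline_dataset(preset4, duration = 0.2, seed = 3)
  sp <- compute_spectrum(ds$cone_trace$black_count, 50000)
  f_low <- peak_frequency(sp, band = c(100, 1000))
  expect_lte(f_low, 1000)
  expect_gte(f_low, 100)
  expect_gt(peak_frequency(sp), 1800)  # true peak lives near 1.92 kHz
})

test_that("peak recovery across pulsation frequencies and seeds", {
  for (f_khz in c(1.0, 1.5, 1.92, 2.0)) {
    for (s in 1:5) {
      p <- make_preset(4.0)
      p$pulsation_frequency <- f_khz
      train <- generate_emission_train(p, 0.5, seed = s)
      cur <- generate_current_trace(train, sample_step = 1 / 50000,
                                    noise_sd = 0.05, seed = s + 50)
      sp <- compute_spectrum(cur$current, 50000)
      expect_lte(abs(peak_frequency(sp) - f_khz * 1000), sp$bin_width)
    }
  }
})

test_that("peak location is window-invariant for isolated peaks", {
  train <- generate_emission_train(preset4, 0.5, seed = 12)
  cur <- generate_current_trace(train, seed = 13)
  rate <- 1 / cur$sample_step
  f_hann <- peak_frequency(compute_spectrum(cur$current, rate, "hann"))
  f_rect <- peak_frequency(compute_spectrum(cur$current, rate,
                                            "rectangular"))
  expect_equal(f_hann, f_rect)
})

test_that("undersampled traces trigger the aliasing warning", {
  # a peak landing at the Nyquist edge cannot be trusted
  t <- (0:2999) / 3000
  sp <- compute_spectrum(sin(2 * pi * 1499 * t), 3000)
  expect_warning(peak_frequency(sp), "undersampled")
  expect_warning(
    compare_channels(sin(2 * pi * 1000 * t), rnorm(3000),
                     pixel_rate = 3000, current_rate = 50000,
                     preset = preset4),
    "below twice")
})

test_that("coupled channels agree; independent tones do not", {
  ds <- generate_offline_dataset(preset4, duration = 0.5, seed = 8)
  cmp <- compare_channels(ds$cone_trace, ds$current, preset = preset4)
  expect_true(cmp$agree)
  expect_lte(cmp$delta_f, max(cmp$bin_widths))

  rate <- 50000
  t <- (0:24999) / rate
  ind <- compare_channels(sin(2 * pi * 1000 * t), sin(2 * pi * 2000 * t),
                          pixel_rate = rate, current_rate = rate)
  expect_false(ind$agree)
  expect_equal(ind$delta_f, 1000)
})

test_that("voltage sweep tabulates matched frequency pairs", {
  sweep <- lapply(c(3.0, 4.0, 5.0), function(v) {
    p <- make_preset(v)
    ds <- generate_offline_dataset(p, duration = 0.25, seed = 4)
    cmp <- compare_channels(ds$cone_trace, ds$current, preset = p)
    data.frame(voltage = v, f_pixel = cmp$f_pixel,
               f_current = cmp$f_current, agree = cmp$agree)
  })
  tab <- do.call(rbind, sweep)
  expect_true(all(tab$agree))
  expect_equal(tab$f_pixel / 1000,
               vapply(c(3.0, 4.0, 5.0),
                      function(v) make_preset(v)$pulsation_frequency,
                      numeric(1)),
               tolerance = 0.02)
})
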