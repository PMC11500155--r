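make_cone_trace <- function(present, frame_rate = 5000) {
  structure(list(timestamps = (seq_along(present) - 1) / frame_rate,
                 black_count = as.integer(present) * 20L,
                 present = as.logical(present),
                 geometry = default_geom()),
            class = "cone_trace")
}

make_ms <- function(intensity, event = 4e-3) {
  structure(list(event_times = (seq_along(intensity) - 1) * event,
                 intensity = intensity, mz_label = 152,
                 dwell = 0.8e-3, event = event),
            class = "ms_trace")
}

test_that("occupancy binning computes exact percentages", {
  present <- c(rep(TRUE, 20),                  # 100%
               rep(c(TRUE, FALSE, FALSE, FALSE), 5),  # 25%
               rep(FALSE, 15))                 # partial bin, discarded
  occ <- bin_occupancy(make_cone_trace(present), 20)
  expect_equal(occ$percent, c(100, 25))
  expect_equal(occ$bin_times, c(0, 20 / 5000))
})

test_that("binning conserves presence counts over complete bins", {
  set.seed(10)
  present <- runif(1037) < 0.4
  occ <- bin_occupancy(make_cone_trace(present), 20)
  n_bins <- length(occ$percent)
  expect_equal(sum(occ$percent) * 20 / 100,
               sum(present[seq_len(n_bins * 20)]))
  expect_equal(n_bins, 1037 %/% 20)
  # empty trace -> empty occupancy
  expect_length(bin_occupancy(make_cone_trace(logical(0)), 20)$percent, 0)
})

test_that("spearman_rho matches the hand-computed average-rank oracle", {
  # x = (1,2,2,4): ranks (1, 2.5, 2.5, 4); y = (3,1,2,4): ranks (3,1,2,4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(3, 1, 2, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(3, 1, 2, 4)), oracle)

  x <- 1:10
  expect_equal(spearman_rho(x, x^2), 1)          # monotone increasing
  expect_equal(spearman_rho(x, rev(x)), -1)      # reversed ranks

  # cross-check against the reference implementation on tied data
  set.seed(42)
  x <- sample(1:20, 50, replace = TRUE)
  y <- sample(1:20, 50, replace = TRUE)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(40)
  r <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), r)
  expect_equal(spearman_rho(x, y^3), r)
  # decreasing transform of x and negation of y flip the sign twice
  expect_equal(spearman_rho(-1 / (1 + exp(-x)), -y), r)
})

test_that("constant inputs give flagged missing rho, never zero", {
  r <- spearman_rho(rep(0, 10), rnorm(10))
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "constant input")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_true(is.na(spearman_rho(c(1, 2), c(3, 4))))
})

test_that("zero shift on identical grids equals the direct correlation", {
  set.seed(8)
  occ <- bin_occupancy(make_cone_trace(runif(2000) < 0.5), 20)
  ms <- make_ms(rnorm(100, 50, 10))
  sc <- shift_scan(occ, ms, shifts = 0)
  expect_equal(sc$rho, spearman_rho(occ$percent, ms$intensity))
  expect_equal(sc$n_pairs, 100L)
})

test_that("shift scan recovers a whole-event offset between the series", {
  set.seed(9)
  base <- rnorm(300)
  # occupancy tracks the process two events ahead of the MS trace, so
  # the scan should peak at +2 events = +8 ms
  occ <- structure(list(bin_times = (0:249) * 4e-3,
                        percent = 100 * pnorm(base[(1:250) + 2]),
                        bin_size = 20L),
                   class = "occupancy_trace")
  ms <- make_ms(base[1:250] + rnorm(250, 0, 0.05))
  sc <- shift_scan(occ, ms)
  # nearest-event alignment resolves the offset to within half an event
  expect_lte(abs(sc$shifts[which.max(sc$rho)] - 8e-3), 2e-3 + 1e-9)
  expect_gt(max(sc$rho, na.rm = TRUE), 0.9)
  # pairs shrink as the shift walks events off the end of the trace
  expect_true(all(diff(sc$n_pairs[sc$shifts >= 0]) <= 0))
})

test_that("shifts with fewer than 3 overlapping pairs are flagged missing", {
  occ <- structure(list(bin_times = c(0, 4e-3), percent = c(10, 90),
                        bin_size = 20L), class = "occupancy_trace")
  ms <- make_ms(rnorm(5))
  sc <- shift_scan(occ, ms, shifts = 0)
  expect_true(is.na(sc$rho))
  expect_equal(sc$n_pairs, 2L)
})
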