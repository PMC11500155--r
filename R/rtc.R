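#' Configuration of a real-time-control (RTC) trial
#'
#' In an RTC trial, frames are classified in stream order; the first
#' frame satisfying the condition ("positive": cone present,
#' "negative": cone absent) triggers the plume gate to open after the
#' loop latency plus a configurable set delay, for a fixed duration,
#' after which the run ends with a single MS intensity.
#'
#' @param condition `"positive"` (open on cone present) or `"negative"`
#'   (open on cone absent).
#' @param set_delay additional delay from image-analysis completion to
#'   gate opening, s.
#' @param gate_open_duration gate opening duration, s (default 1 ms).
#' @param loop_latency image acquisition -> analysis -> trigger latency,
#'   s (default 0.44 ms).
#' @param latency_jitter_sd Gaussian jitter sd of the latency, s
#'   (truncated so total latency stays >= 0).
#' @param frame_rate camera frame rate, fps.
#' @param timeout give up if the condition is never satisfied within
#'   this many seconds of frames (default 5 s).
#' @return object of class `rtc_config`.
#' @export
rtc_config <- function(condition = c("positive", "negative"),
                       set_delay = 1e-3,
                       gate_open_duration = 1e-3,
                       loop_latency = 0.44e-3,
                       latency_jitter_sd = 0,
                       frame_rate = 5000,
                       timeout = 5) {
  condition <- match.arg(condition)
  stopifnot(set_delay >= 0, gate_open_duration > 0, loop_latency >= 0,
            latency_jitter_sd >= 0, frame_rate > 0, timeout > 0)
  structure(list(condition = condition, set_delay = set_delay,
                 gate_open_duration = gate_open_duration,
                 loop_latency = loop_latency,
                 latency_jitter_sd = latency_jitter_sd,
                 frame_rate = frame_rate, timeout = timeout),
            class = "rtc_config")
}

#' Run one simulated RTC trial
#'
#' Streams frames from a synthetic acquisition, classifies each with the
#' reference-line classifier, and on the first frame satisfying the
#' condition opens the plume gate at `frame_time + elapsed` (with
#' `elapsed = set_delay + loop_latency (+ jitter)`) for
#' `gate_open_duration`. The run's single MS intensity is the maximum
#' SIM-event intensity among events overlapping the arrival window of
#' the gated packet. If the condition is never satisfied within the
#' timeout, a flagged timeout result is returned.
#'
#' @param preset a [make_preset()].
#' @param chain a [chain_params()].
#' @param config an [rtc_config()].
#' @param seed integer seed (emission, pixel noise, jitter and detector
#'   noise sub-seeds are derived from it).
#' @param geometry optional [detection_geometry()].
#' @param pixel_noise_sd shadowgraph pixel noise sd, 8-bit levels.
#' @return object of class `rtc_run`: list with `condition`,
#'   `set_delay`, `elapsed` (s), `intensity` (NA on timeout),
#'   `trigger_frame_time` (s), `timed_out`.
#' @export
run_rtc_trial <- function(preset, chain = chain_params(),
                          config = rtc_config(), seed = 1,
                          geometry = NULL, pixel_noise_sd = 5) {
  stopifnot(inherits(preset, "spray_preset"), inherits(chain, "chain_params"),
            inherits(config, "rtc_config"))
  seed <- as.integer(seed)
  if (is.null(geometry)) {
    geometry <- detection_geometry(tip_x = 100, tip_y = 128,
                                   horizontal_offset =
                                     preset$horizontal_offset)
  }
  tail_window <- config$set_delay + config$loop_latency +
    5 * config$latency_jitter_sd + config$gate_open_duration +
    chain$transit_delay + 5 * chain$mixing_tau + 2 * chain$event
  duration <- config$timeout + tail_window + 0.01
  train <- generate_emission_train(preset, duration, seed = seed)
  settings <- acquisition_settings(frame_rate = config$frame_rate,
                                   duration = config$timeout)
  stack <- render_shadowgraph_stack(train, settings, preset,
                                    seed = seed + 1L,
                                    noise_sd = pixel_noise_sd,
                                    max_pixels_in_memory = 0)

  want_present <- config$condition == "positive"
  x <- geometry$tip_x + geometry$horizontal_offset
  rows <- line_rows(geometry)
  check_geometry_fits(geometry, stack$width, stack$height)
  trigger <- NA_integer_
  chunk <- 512L
  s <- 1L
  while (s <= stack$n_frames) {
    idx <- s:min(stack$n_frames, s + chunk - 1L)
    region <- stack$render_region(idx, rows, x)
    counts <- colSums(matrix(region, length(rows), length(idx)) <
                        geometry$intensity_threshold)
    hit <- which(classify_presence(counts, geometry$count_threshold) ==
                   want_present)
    if (length(hit)) {
      trigger <- idx[hit[1]]
      break
    }
    s <- s + chunk
  }
  if (is.na(trigger)) {
    return(structure(list(condition = config$condition,
                          set_delay = config$set_delay,
                          elapsed = NA_real_, intensity = NA_real_,
                          trigger_frame_time = NA_real_, timed_out = TRUE),
                     class = "rtc_run"))
  }
  trigger_time <- stack$timestamps[trigger]

  set.seed(seed + 2L)
  latency <- max(0, config$loop_latency +
                   stats::rnorm(1, 0, config$latency_jitter_sd))
  elapsed <- config$set_delay + latency
  t_open <- trigger_time + elapsed
  gate <- gate_waveform(matrix(c(t_open, t_open + config$gate_open_duration),
                               ncol = 2))

  arrival <- transit_mixing(apply_gate(train, gate), chain)
  ms <- sample_sim_events(arrival, chain, duration, seed = seed + 3L)
  win_lo <- t_open + chain$transit_delay
  win_hi <- t_open + config$gate_open_duration + chain$transit_delay +
    5 * chain$mixing_tau
  in_win <- ms$event_times + chain$event > win_lo & ms$event_times < win_hi
  intensity <- if (any(in_win)) max(ms$intensity[in_win]) else 0

  structure(list(condition = config$condition, set_delay = config$set_delay,
                 elapsed = elapsed, intensity = intensity,
                 trigger_frame_time = trigger_time, timed_out = FALSE),
            class = "rtc_run")
}

#' @export
print.rtc_run <- function(x, ...) {
  if (x$timed_out) {
    cat("<rtc_run> ", x$condition, ": TIMED OUT\n", sep = "")
  } else {
    cat("<rtc_run> ", x$condition, ", set delay ",
        format(x$set_delay * 1e3), " ms, elapsed ",
        format(signif(x$elapsed * 1e3, 4)), " ms, intensity ",
        format(signif(x$intensity, 4)), "\n", sep = "")
  }
  invisible(x)
}

rtc_runs_frame <- function(trials) {
  stopifnot(length(trials) > 0,
            all(vapply(trials, inherits, logical(1), "rtc_run")))
  data.frame(
    condition = vapply(trials, `[[`, character(1), "condition"),
    set_delay = vapply(trials, `[[`, numeric(1), "set_delay"),
    elapsed = vapply(trials, `[[`, numeric(1), "elapsed"),
    intensity = vapply(trials, `[[`, numeric(1), "intensity"),
    timed_out = vapply(trials, `[[`, logical(1), "timed_out")
  )
}

#' Calibrate the RTC loop latency from a delay ladder
#'
#' Ordinary least squares of elapsed time (image acquisition -> gate
#' opening) on the configured set delay. The slope should be ~1 and the
#' intercept estimates the loop latency.
#'
#' @param trials list of `rtc_run` results spanning >= 3 distinct set
#'   delays (timed-out runs are dropped).
#' @return object of class `rtc_calibration`: list with `slope`,
#'   `intercept` (s), `r_squared`, `n`, and the underlying `fit`.
#' @export
calibrate_delay <- function(trials) {
  df <- rtc_runs_frame(trials)
  df <- df[!df$timed_out, ]
  if (length(unique(df$set_delay)) < 3) {
    stop("calibration needs >= 3 distinct set delays (degenerate fit)",
         call. = FALSE)
  }
  fit <- stats::lm(elapsed ~ set_delay, data = df)
  # a zero-jitter ladder gives an exact fit; summary.lm warns about it
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = nrow(df), fit = fit),
            class = "rtc_calibration")
}

#' @export
print.rtc_calibration <- function(x, ...) {
  cat("<rtc_calibration> elapsed = ",
      format(signif(x$intercept * 1e3, 4)), " ms + ",
      format(signif(x$slope, 4)), " x set_delay  (R^2 = ",
      format(signif(x$r_squared, 4)), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Compare positive and negative RTC conditions
#'
#' Summarises per-(condition, set delay) mean and sd intensities and
#' computes a two-sided percentile bootstrap interval for the
#' positive - negative mean intensity difference, per delay and pooled.
#' Empty cells are reported as missing, never dropped silently.
#'
#' @param trials list of `rtc_run` results.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return object of class `rtc_comparison`: list with `table` (one row
#'   per condition x delay: n, mean, sd), `difference` (per-delay and
#'   pooled positive - negative mean difference with bootstrap CI).
#' @export
compare_conditions <- function(trials, n_boot = 2000, conf = 0.95,
                               seed = 1) {
  df <- rtc_runs_frame(trials)
  df <- df[!df$timed_out, ]
  if (nrow(df) == 0) stop("no completed trials", call. = FALSE)
  delays <- sort(unique(df$set_delay))
  grid <- expand.grid(condition = c("positive", "negative"),
                      set_delay = delays, stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    v <- df$intensity[df$condition == grid$condition[i] &
                        df$set_delay == grid$set_delay[i]]
    data.frame(condition = grid$condition[i], set_delay = grid$set_delay[i],
               n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  tab <- do.call(rbind, cells)

  set.seed(as.integer(seed))
  boot_diff <- function(pos, neg) {
    if (!length(pos) || !length(neg)) {
      return(c(diff = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    d <- replicate(n_boot, mean(sample(pos, replace = TRUE)) -
                            mean(sample(neg, replace = TRUE)))
    q <- stats::quantile(d, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                         names = FALSE)
    c(diff = mean(pos) - mean(neg), lo = q[1], hi = q[2])
  }
  per_delay <- lapply(delays, function(dl) {
    b <- boot_diff(df$intensity[df$condition == "positive" &
                                  df$set_delay == dl],
                   df$intensity[df$condition == "negative" &
                                  df$set_delay == dl])
    data.frame(set_delay = dl, diff = b["diff"], lo = b["lo"], hi = b["hi"],
               row.names = NULL)
  })
  pooled <- boot_diff(df$intensity[df$condition == "positive"],
                      df$intensity[df$condition == "negative"])
  difference <- rbind(do.call(rbind, per_delay),
                      data.frame(set_delay = NA_real_, diff = pooled["diff"],
                                 lo = pooled["lo"], hi = pooled["hi"],
                                 row.names = NULL))
  structure(list(table = tab, difference = difference, conf = conf),
            class = "rtc_comparison")
}

#' @export
print.rtc_comparison <- function(x, ...) {
  cat("<rtc_comparison> intensities by condition and set delay:\n")
  print(x$table, row.names = FALSE)
  cat("positive - negative mean difference (",
      format(100 * x$conf), "% bootstrap CI; last row pooled):\n", sep = "")
  print(x$difference, row.names = FALSE)
  invisible(x)
}
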