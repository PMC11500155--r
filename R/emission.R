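#' Generate a continuous-time emission train
#'
#' Simulates the instantaneous charged-droplet/ion emission flux of an
#' electrospray emitter together with the Boolean Taylor-cone state,
#' sampled on a fine uniform grid. The underlying model is an analytic
#' phase function, so the same train can later be re-sampled exactly at
#' arbitrary times (camera frame timestamps, oscilloscope grid) via
#' [emission_flux_at()] and [emission_cone_at()].
#'
#' Modes:
#' \describe{
#'   \item{pulsating}{one flux burst per pulsation cycle. Cycle `i` has
#'     the cone present for a fraction `duty_i` of the period (duty and
#'     burst amplitude jittered cycle-to-cycle per the preset), with
#'     flux `2 * A_i * sin(pi * u)^2` over the cone-present part
#'     (`u` in \[0, 1\]), so the cycle-averaged flux equals
#'     `duty_i * A_i` in emission-amplitude units.}
#'   \item{burst}{sporadic isolated bursts at Poisson-random times
#'     (default mean rate 20 per second, 50% amplitude jitter, 1 ms
#'     burst width).}
#'   \item{cone_jet}{persistent cone, constant flux.}
#'   \item{no_spray}{zero flux, cone never present.}
#' }
#'
#' @param preset a [make_preset()] object.
#' @param duration length of the train in seconds (>= 0).
#' @param seed integer seed; identical seeds and parameters give
#'   bit-identical trains.
#' @param dt grid step in seconds (default 10 us; must be <= 10 us).
#' @param burst_rate mean burst rate (per second) in burst mode.
#' @param burst_width burst width in seconds in burst mode.
#' @param burst_amp_scale peak-flux multiplier of burst-mode discharges
#'   relative to the emission amplitude (default 20): an isolated burst
#'   releases the charge accumulated between events, so single bursts
#'   register as clear spikes rather than blending into the baseline.
#' @return An object of class `emission_train`: list with `times` (s),
#'   `flux` (arbitrary flux units, >= 0, positive only while the cone is
#'   present), `cone_state` (logical), `preset`, `dt`, `duration`, and
#'   the analytic `model` used for re-sampling.
#' @export
generate_emission_train <- function(preset, duration, seed,
                                    dt = 1e-5,
                                    burst_rate = 20,
                                    burst_width = 1e-3,
                                    burst_amp_scale = 20) {
  stopifnot(inherits(preset, "spray_preset"))
  if (!is.numeric(duration) || duration < 0) {
    stop("`duration` must be >= 0", call. = FALSE)
  }
  if (dt > 1e-5 + 1e-12) stop("grid step `dt` must be <= 10 us", call. = FALSE)

  set.seed(as.integer(seed))
  model <- switch(preset$mode,
    no_spray = list(type = "no_spray"),
    cone_jet = list(type = "cone_jet", amp = preset$emission_amplitude),
    pulsating = {
      f <- preset$pulsation_frequency * 1000
      stopifnot(f > 0)
      n_cyc <- floor(duration * f) + 2L
      duty <- pmin(0.95, pmax(0.05, stats::rnorm(n_cyc, preset$cone_duty,
                                                 preset$duty_jitter_sd)))
      amp <- pmax(0, preset$emission_amplitude *
                       (1 + stats::rnorm(n_cyc, 0, preset$amp_jitter_sd)))
      list(type = "pulsating", f_hz = f, duty = duty, amp = amp)
    },
    burst = {
      n_b <- stats::rpois(1, burst_rate * duration)
      starts <- sort(stats::runif(n_b, 0, max(0, duration - burst_width)))
      amp <- pmax(0.05, burst_amp_scale * preset$emission_amplitude *
                          (1 + 0.5 * stats::rnorm(n_b)))
      list(type = "burst", starts = starts, amp = amp, width = burst_width)
    }
  )
  model$gate <- NULL  # set by apply_gate()

  n <- floor(duration / dt + 1e-9)
  times <- if (n > 0) (seq_len(n) - 1) * dt else numeric(0)

  train <- structure(
    list(times = times, flux = NULL, cone_state = NULL,
         preset = preset, model = model, dt = dt, duration = duration),
    class = "emission_train"
  )
  train$flux <- emission_flux_at(train, times)
  train$cone_state <- emission_cone_at(train, times)
  train
}

#' Evaluate the analytic cone state of a train at arbitrary times
#'
#' @param train an `emission_train`.
#' @param t numeric vector of times in seconds.
#' @return logical vector: is the Taylor cone present at each time.
#' @export
emission_cone_at <- function(train, t) {
  m <- train$model
  switch(m$type,
    no_spray = rep(FALSE, length(t)),
    cone_jet = rep(TRUE, length(t)),
    pulsating = {
      p <- m$f_hz * t
      i <- pmin(length(m$duty), floor(p) + 1L)
      (p - floor(p)) < m$duty[i]
    },
    burst = {
      state <- rep(FALSE, length(t))
      for (j in seq_along(m$starts)) {
        state <- state | (t >= m$starts[j] & t < m$starts[j] + m$width)
      }
      state
    }
  )
}

#' Evaluate the analytic emission flux of a train at arbitrary times
#'
#' Respects any plume gate applied with [apply_gate()].
#' @inheritParams emission_cone_at
#' @return numeric vector of flux values (>= 0).
#' @export
emission_flux_at <- function(train, t) {
  m <- train$model
  flux <- switch(m$type,
    no_spray = rep(0, length(t)),
    cone_jet = rep(m$amp, length(t)),
    pulsating = {
      p <- m$f_hz * t
      i <- pmin(length(m$duty), floor(p) + 1L)
      frac <- p - floor(p)
      u <- frac / m$duty[i]
      ifelse(u < 1, 2 * m$amp[i] * sin(pi * pmin(u, 1))^2, 0)
    },
    burst = {
      f <- rep(0, length(t))
      for (j in seq_along(m$starts)) {
        u <- (t - m$starts[j]) / m$width
        inb <- u >= 0 & u < 1
        f[inb] <- f[inb] + 2 * m$amp[j] * sin(pi * u[inb])^2
      }
      f
    }
  )
  if (!is.null(m$gate)) {
    flux <- flux * gate_transmission(m$gate, t)
  }
  flux
}

#' @export
print.emission_train <- function(x, ...) {
  cat("<emission_train> mode = ", x$model$type, ", duration ",
      format(x$duration), " s, ", length(x$times), " grid points (dt ",
      format(x$dt * 1e6), " us)\n", sep = "")
  if (length(x$flux)) {
    cat("  mean flux ", format(signif(mean(x$flux), 4)),
        "; cone present ", format(signif(100 * mean(x$cone_state), 3)),
        "% of grid\n", sep = "")
  }
  invisible(x)
}

#' Sample a spray-current trace on the oscilloscope grid
#'
#' Resamples the emission flux onto a uniform oscilloscope grid (default
#' step 20 us) and adds Gaussian measurement noise, emulating a Faraday
#' plate + oscilloscope recording of the spray current.
#'
#' @param train an `emission_train`.
#' @param sample_step oscilloscope sampling step in seconds.
#' @param noise_sd Gaussian noise standard deviation, in the same
#'   (arbitrary) current units as the flux.
#' @param seed integer seed for the noise.
#' @return An object of class `current_trace`: list with `times`,
#'   `current`, `noise_sd`, `sample_step` and logical `aliased` (TRUE
#'   when the sampling step exceeds half the pulsation period, i.e. the
#'   trace cannot resolve the pulsation frequency).
#' @export
generate_current_trace <- function(train, sample_step = 20e-6,
                                   noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(train, "emission_train"))
  if (!is.numeric(sample_step) || sample_step <= 0) {
    stop("`sample_step` must be > 0", call. = FALSE)
  }
  n <- floor(train$duration / sample_step + 1e-9)
  times <- if (n > 0) (seq_len(n) - 1) * sample_step else numeric(0)
  current <- emission_flux_at(train, times)
  if (noise_sd > 0 && n > 0) {
    set.seed(as.integer(seed))
    current <- current + stats::rnorm(n, 0, noise_sd)
  }
  aliased <- FALSE
  f <- train$preset$pulsation_frequency * 1000
  if (train$model$type == "pulsating" && f > 0 &&
      sample_step > 1 / (2 * f)) {
    aliased <- TRUE
    warning("sampling step ", sample_step, " s exceeds half the pulsation ",
            "period; the pulsation frequency will alias", call. = FALSE)
  }
  structure(
    list(times = times, current = current, noise_sd = noise_sd,
         sample_step = sample_step, aliased = aliased),
    class = "current_trace"
  )
}

#' @export
print.current_trace <- function(x, ...) {
  cat("<current_trace> ", length(x$times), " samples at ",
      format(x$sample_step * 1e6), " us", if (isTRUE(x$aliased)) " [aliased]",
      "\n", sep = "")
  invisible(x)
}
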