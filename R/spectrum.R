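#' One-sided FFT magnitude spectrum of a uniformly sampled trace
#'
#' Mean-subtracts the trace, applies a window (Hann by default) and
#' returns the one-sided magnitude spectrum up to the Nyquist frequency.
#' Frequency resolution is `rate / length(values)`.
#'
#' @param values numeric vector (>= 64 samples) on a uniform grid, or an
#'   object with `times`: pass `times` to have uniformity checked.
#' @param rate sampling rate in Hz.
#' @param window `"hann"` or `"rectangular"`.
#' @param times optional timestamps; non-uniform grids (beyond 1% of the
#'   median step) are rejected — resample explicitly first.
#' @return object of class `spectrum_trace`: list with `frequencies`
#'   (Hz, from 0 to Nyquist), `magnitude` (non-negative), `source_rate`,
#'   `window_label`, `bin_width` (Hz).
#' @export
compute_spectrum <- function(values, rate, window = c("hann", "rectangular"),
                             times = NULL) {
  window <- match.arg(window)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 64) stop("need >= 64 samples for a spectrum", call. = FALSE)
  stopifnot(rate > 0, all(is.finite(values)))
  if (!is.null(times)) {
    d <- diff(times)
    if (max(abs(d - stats::median(d))) > 0.01 * stats::median(d)) {
      stop("timestamps are not uniform; resample explicitly first",
           call. = FALSE)
    }
  }
  x <- values - mean(values)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    x <- x * w
  }
  sp <- abs(stats::fft(x))[seq_len(n %/% 2 + 1)]
  structure(
    list(frequencies = (seq_len(n %/% 2 + 1) - 1) * rate / n,
         magnitude = sp, source_rate = rate, window_label = window,
         bin_width = rate / n),
    class = "spectrum_trace"
  )
}

#' @export
print.spectrum_trace <- function(x, ...) {
  cat("<spectrum_trace> ", length(x$frequencies), " bins up to ",
      format(max(x$frequencies)), " Hz (resolution ",
      format(signif(x$bin_width, 4)), " Hz, ", x$window_label,
      " window)\n", sep = "")
  invisible(x)
}

#' @export
plot.spectrum_trace <- function(x, xlim = NULL, ...) {
  graphics::plot(x$frequencies, x$magnitude, type = "l",
                 xlab = "frequency (Hz)", ylab = "magnitude",
                 xlim = xlim, ...)
  invisible(x)
}

#' Peak frequency of a spectrum within a band
#'
#' Returns the frequency of the maximum magnitude inside the band, ties
#' broken toward the lower frequency. The default band starts at 100 Hz
#' to exclude DC and slow drift. A warning is emitted when the peak
#' lands within one bin of the Nyquist frequency (the band's upper
#' limit), since the true oscillation may then be undersampled.
#'
#' @param spectrum a `spectrum_trace`.
#' @param band numeric length-2 interval in Hz; default
#'   `c(100, Nyquist)`.
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(spectrum, band = NULL) {
  stopifnot(inherits(spectrum, "spectrum_trace"))
  nyquist <- spectrum$source_rate / 2
  if (is.null(band)) band <- c(100, nyquist)
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0 ||
      band[1] > nyquist) {
    stop("invalid band: must be an interval within (0, Nyquist]",
         call. = FALSE)
  }
  band[2] <- min(band[2], nyquist)
  in_band <- spectrum$frequencies >= band[1] &
    spectrum$frequencies <= band[2]
  if (!any(in_band)) stop("band contains no frequency bins", call. = FALSE)
  f <- spectrum$frequencies[in_band]
  m <- spectrum$magnitude[in_band]
  fpk <- f[which.max(m)]  # which.max takes the first (lowest-frequency) tie
  if (fpk >= nyquist - spectrum$bin_width) {
    warning("peak within one bin of Nyquist (", format(nyquist),
            " Hz): the trace may be undersampled", call. = FALSE)
  }
  fpk
}

#' Compare meniscus-oscillation and spray-current frequencies
#'
#' Computes the FFT peak frequency of the per-frame black-pixel-count
#' trace (image channel) and of the spray-current trace (oscilloscope
#' channel) and their absolute difference. Agreement is flagged when
#' `|delta_f|` does not exceed the larger of the two bin widths. When a
#' preset is supplied, a warning is emitted if either channel's
#' sampling rate is below twice the preset's pulsation frequency — the
#' reason online 5000-fps data is binned rather than Fourier-analysed.
#'
#' @param pixel_trace numeric vector of per-frame black-pixel counts
#'   (or a `cone_trace`, whose `black_count` is used).
#' @param current_trace numeric vector of spray-current samples (or a
#'   `current_trace`, whose `current` is used).
#' @param pixel_rate,current_rate sampling rates in Hz. Inferred from
#'   `cone_trace` / `current_trace` objects when omitted.
#' @param band frequency band passed to [peak_frequency()].
#' @param preset optional [make_preset()] for the undersampling check.
#' @param window FFT window.
#' @return object of class `channel_comparison`: list with `f_pixel`,
#'   `f_current`, `delta_f` (Hz), `agree` (logical), `bin_widths`, and
#'   the two spectra.
#' @export
compare_channels <- function(pixel_trace, current_trace,
                             pixel_rate = NULL, current_rate = NULL,
                             band = NULL, preset = NULL,
                             window = "hann") {
  if (inherits(pixel_trace, "cone_trace")) {
    if (is.null(pixel_rate)) {
      pixel_rate <- 1 / stats::median(diff(pixel_trace$timestamps))
    }
    pixel_trace <- pixel_trace$black_count
  }
  if (inherits(current_trace, "current_trace")) {
    if (is.null(current_rate)) current_rate <- 1 / current_trace$sample_step
    current_trace <- current_trace$current
  }
  stopifnot(!is.null(pixel_rate), !is.null(current_rate))
  if (!is.null(preset) && preset$pulsation_frequency > 0) {
    f <- preset$pulsation_frequency * 1000
    for (r in c(pixel = pixel_rate, current = current_rate)) {
      if (r < 2 * f) {
        warning("sampling rate ", format(r), " Hz is below twice the ",
                "preset pulsation frequency (", format(f), " Hz): the ",
                "estimate will alias", call. = FALSE)
      }
    }
  }
  sp_p <- compute_spectrum(pixel_trace, pixel_rate, window = window)
  sp_c <- compute_spectrum(current_trace, current_rate, window = window)
  f_p <- peak_frequency(sp_p, band)
  f_c <- peak_frequency(sp_c, band)
  d <- abs(f_p - f_c)
  structure(
    list(f_pixel = f_p, f_current = f_c, delta_f = d,
         agree = d <= max(sp_p$bin_width, sp_c$bin_width) + 1e-9,
         bin_widths = c(pixel = sp_p$bin_width, current = sp_c$bin_width),
         pixel_spectrum = sp_p, current_spectrum = sp_c),
    class = "channel_comparison"
  )
}

#' @export
print.channel_comparison <- function(x, ...) {
  cat("<channel_comparison> image ", format(signif(x$f_pixel / 1000, 4)),
      " kHz vs current ", format(signif(x$f_current / 1000, 4)),
      " kHz; |delta f| = ", format(signif(x$delta_f, 4)), " Hz (",
      if (x$agree) "agree" else "disagree", ")\n", sep = "")
  invisible(x)
}
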