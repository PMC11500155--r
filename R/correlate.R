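#' Bin cone presence into occupancy percentages
#'
#' Groups consecutive frames into bins of `bin_size` frames (default 20,
#' which at 5000 fps makes 4 ms bins, one per SIM acquisition event) and
#' reports the percentage of frames per bin in which the cone was
#' classified present. A trailing partial bin is discarded.
#'
#' @param trace a `cone_trace` from [analyze_stack()].
#' @param bin_size frames per bin (>= 1).
#' @return object of class `occupancy_trace`: list with `bin_times`
#'   (time of the first frame in each bin, s), `percent` (0-100) and
#'   `bin_size`.
#' @export
bin_occupancy <- function(trace, bin_size = 20L) {
  stopifnot(inherits(trace, "cone_trace"), bin_size >= 1)
  bin_size <- as.integer(bin_size)
  n_bins <- length(trace$present) %/% bin_size
  if (n_bins == 0) {
    return(structure(list(bin_times = numeric(0), percent = numeric(0),
                          bin_size = bin_size),
                     class = "occupancy_trace"))
  }
  used <- seq_len(n_bins * bin_size)
  counts <- colSums(matrix(trace$present[used], nrow = bin_size))
  structure(
    list(bin_times = trace$timestamps[(seq_len(n_bins) - 1L) * bin_size + 1L],
         percent = 100 * counts / bin_size,
         bin_size = bin_size),
    class = "occupancy_trace"
  )
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat("<occupancy_trace> ", length(x$percent), " bins of ", x$bin_size,
      " frames; mean occupancy ", format(signif(mean(x$percent), 3)),
      "%\n", sep = "")
  invisible(x)
}

#' Spearman's rank correlation
#'
#' Computed explicitly as the Pearson correlation of average-ranked data
#' (ties receive average ranks), so the tie-handling convention is
#' visible and testable. A constant input vector has no defined rank
#' correlation; the result is then `NA` with attribute
#' `reason = "constant input"` — this occurs naturally for zero-signal
#' voltage runs and is never coerced to 0.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs containing NA
#'   are dropped.
#' @return Spearman's rho in \[-1, 1\], or flagged `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    return(structure(NA_real_, reason = "constant input"))
  }
  sum(dx * dy) / sqrt(sx * sy)
}

#' Scan Spearman correlation over a grid of time shifts
#'
#' For each shift `s`, every occupancy bin (at time `bin_time + s`) is
#' matched to the nearest MS acquisition event; pairs farther than half
#' an event period from any event are dropped, and Spearman's rho is
#' computed on the remaining pairs. This compensates for unknown delays
#' between image capture and MS acquisition (droplet transit, instrument
#' lag).
#'
#' @param occupancy an `occupancy_trace`.
#' @param ms an `ms_trace` (see [sample_sim_events()]).
#' @param shifts numeric vector of time shifts in seconds; defaults to
#'   -2 ms .. +10 ms in 0.2 ms steps, covering ~1 ms droplet transit
#'   plus instrument lag.
#' @return object of class `shift_scan`: list with `shifts` (s), `rho`,
#'   and `n_pairs` per shift. Shifts with fewer than 3 overlapping pairs
#'   or constant inputs carry `NA` rho.
#' @export
shift_scan <- function(occupancy, ms,
                       shifts = seq(-2e-3, 10e-3, by = 0.2e-3)) {
  stopifnot(inherits(occupancy, "occupancy_trace"),
            inherits(ms, "ms_trace"))
  ev <- ms$event_times
  if (length(ev) < 2) stop("MS trace must contain >= 2 events", call. = FALSE)
  step <- ev[2] - ev[1]
  rho <- rep(NA_real_, length(shifts))
  n_pairs <- integer(length(shifts))
  for (k in seq_along(shifts)) {
    target <- occupancy$bin_times + shifts[k]
    j <- round((target - ev[1]) / step) + 1
    ok <- j >= 1 & j <= length(ev)
    ok[ok] <- abs(ev[j[ok]] - target[ok]) <= step / 2 + 1e-12
    n_pairs[k] <- sum(ok)
    if (n_pairs[k] >= 3) {
      r <- spearman_rho(occupancy$percent[ok], ms$intensity[j[ok]])
      rho[k] <- as.numeric(r)
    }
  }
  structure(list(shifts = shifts, rho = rho, n_pairs = n_pairs),
            class = "shift_scan")
}

#' @export
print.shift_scan <- function(x, ...) {
  ok <- is.finite(x$rho)
  cat("<shift_scan> ", length(x$shifts), " shifts (",
      format(min(x$shifts) * 1e3), " .. ", format(max(x$shifts) * 1e3),
      " ms)\n", sep = "")
  if (any(ok)) {
    i <- which.max(abs(x$rho))
    cat("  max |rho| = ", format(signif(abs(x$rho[i]), 3)), " at shift ",
        format(x$shifts[i] * 1e3), " ms (n = ", x$n_pairs[i], ")\n",
        sep = "")
  } else {
    cat("  all rho undefined (constant or insufficient pairs)\n")
  }
  invisible(x)
}

#' @export
summary.shift_scan <- function(object, ...) {
  data.frame(shift_ms = object$shifts * 1e3, rho = object$rho,
             n_pairs = object$n_pairs)
}

#' @export
plot.shift_scan <- function(x, ...) {
  graphics::plot(x$shifts * 1e3, x$rho, type = "b", pch = 16,
                 xlab = "time shift (ms)", ylab = expression(rho),
                 ylim = c(-1, 1), ...)
  graphics::abline(h = c(-0.2, 0.2), lty = 2, col = "grey40")
  invisible(x)
}
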