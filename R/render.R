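#' Acquisition settings for the high-speed camera
#'
#' @param frame_rate frames per second; 5000 (online) and 50000
#'   (offline) are the conventional rates, but any positive value is
#'   allowed.
#' @param duration acquisition length in seconds.
#' @param width,height frame size in pixels.
#' @param exposure exposure time in microseconds (metadata only; the
#'   renderer samples instantaneously at the frame timestamp).
#' @return An object of class `acquisition_settings`. The implied frame
#'   count is `round(frame_rate * duration)`.
#' @export
acquisition_settings <- function(frame_rate = 5000, duration = 1,
                                 width = 256, height = 256,
                                 exposure = NULL) {
  stopifnot(frame_rate > 0, duration >= 0, width >= 8, height >= 8)
  structure(
    list(frame_rate = frame_rate, duration = duration,
         width = as.integer(width), height = as.integer(height),
         bit_depth = 8L, exposure = exposure,
         n_frames = as.integer(round(frame_rate * duration))),
    class = "acquisition_settings"
  )
}

# Deterministic per-(frame, column) noise seed so that lazy region
# rendering and full in-memory rendering are bit-identical.
pixel_noise_seed <- function(seed, frame, col) {
  ((as.double(seed) %% 1000003) * 1000003 +
     as.double(frame) * 2053 + as.double(col) * 7919) %% 2147483629
}

# Column intensities (0-based column x) of one synthetic frame, before
# noise: 255 background, 0 silhouette. Returns numeric vector of length
# `height` (rows 0 .. height-1 top to bottom).
render_column_clean <- function(x, cone_present, geom) {
  col <- rep(255, geom$height)
  y <- seq_len(geom$height) - 1L
  if (x <= geom$tip_x) {
    col[abs(y - geom$tip_y) <= geom$emitter_half_width] <- 0
  } else if (cone_present && x <= geom$tip_x + geom$cone_length) {
    h <- tan(geom$cone_half_angle * pi / 180) *
      (geom$cone_length - (x - geom$tip_x))
    col[abs(y - geom$tip_y) <= h] <- 0
  }
  col
}

add_column_noise <- function(col, seed, frame, x, noise_sd) {
  if (noise_sd > 0) {
    set.seed(as.integer(pixel_noise_seed(seed, frame, x)))
    col <- col + stats::rnorm(length(col), 0, noise_sd)
  }
  round(pmin(255, pmax(0, col)))
}

#' Render a shadowgraph frame stack from an emission train
#'
#' Draws the emitter silhouette (dark pixels on a bright background) and,
#' whenever the train's analytic cone state is true at a frame timestamp,
#' an isoceles triangular Taylor cone extending past the tip. The cone
#' length exceeds the preset's reference-line offset by `cone_margin`
#' pixels, so the cone always crosses the detection line while present.
#' Additive Gaussian pixel noise (8-bit levels) is seeded per
#' (frame, column), making lazily rendered regions bit-identical to full
#' frames.
#'
#' Stacks whose total pixel count exceeds `max_pixels_in_memory` are
#' returned as lazy stacks: frames are rendered on demand through
#' `stack$render_frames(idx)` / `stack$render_region(idx, rows, cols)`
#' (indices 1-based, rows/cols 0-based), which is how [analyze_stack()]
#' processes 150,000-frame acquisitions without holding ~10 GB of pixels.
#'
#' @param train an `emission_train` covering `settings$duration`.
#' @param settings an [acquisition_settings()] object.
#' @param preset the [make_preset()] the train was generated from
#'   (supplies the reference-line offset the cone must cross).
#' @param seed integer seed for pixel noise.
#' @param noise_sd pixel noise standard deviation in 8-bit levels
#'   (default 5); 0 gives noiseless frames.
#' @param tip_x,tip_y emitter tip midpoint, 0-based pixel coordinates
#'   (x rightward along the spray axis, y downward).
#' @param emitter_half_width half-width of the capillary silhouette, px.
#' @param cone_half_angle cone half-angle in degrees (default 49.3, the
#'   Taylor angle).
#' @param cone_margin how far the cone extends beyond the reference-line
#'   offset, px.
#' @param max_pixels_in_memory threshold above which the stack is lazy.
#' @return An object of class `frame_stack` with fields `n_frames`,
#'   `width`, `height`, `frame_rate`, `timestamps`, `backend`
#'   (`"array"` or `"lazy"`), `geometry` (the render geometry), and
#'   either `frames` (list of height x width matrices, 0-255) or the
#'   two renderer closures.
#' @export
render_shadowgraph_stack <- function(train, settings, preset, seed = 1,
                                     noise_sd = 5,
                                     tip_x = 100, tip_y = 128,
                                     emitter_half_width = 12,
                                     cone_half_angle = 49.3,
                                     cone_margin = 10,
                                     max_pixels_in_memory = 2e7) {
  stopifnot(inherits(train, "emission_train"),
            inherits(settings, "acquisition_settings"))
  if (train$duration + 1e-9 < settings$duration) {
    stop("emission train (", train$duration, " s) does not cover the ",
         "acquisition duration (", settings$duration, " s)", call. = FALSE)
  }
  cone_length <- preset$horizontal_offset + cone_margin
  geom <- list(tip_x = tip_x, tip_y = tip_y,
               emitter_half_width = emitter_half_width,
               cone_half_angle = cone_half_angle,
               cone_length = cone_length,
               width = settings$width, height = settings$height,
               horizontal_offset = preset$horizontal_offset)
  if (tip_x + cone_length >= settings$width) {
    stop("frame too small: tip_x + cone length (", tip_x + cone_length,
         ") exceeds frame width ", settings$width, call. = FALSE)
  }

  n <- settings$n_frames
  timestamps <- if (n > 0) (seq_len(n) - 1) / settings$frame_rate else numeric(0)
  cone_state <- emission_cone_at(train, timestamps)

  render_region <- function(idx, rows, cols) {
    # rows, cols 0-based; returns length(rows) x length(cols) x length(idx)
    out <- array(0, dim = c(length(rows), length(cols), length(idx)))
    # clean columns depend only on (x, cone state): cache both variants
    clean_absent <- lapply(cols, render_column_clean, cone_present = FALSE,
                           geom = geom)
    clean_present <- lapply(cols, render_column_clean, cone_present = TRUE,
                            geom = geom)
    sub <- rows + 1L
    if (noise_sd > 0) {
      for (k in seq_along(idx)) {
        i <- idx[k]
        base <- if (cone_state[i]) clean_present else clean_absent
        for (j in seq_along(cols)) {
          set.seed(as.integer(pixel_noise_seed(seed, i, cols[j])))
          noise <- stats::rnorm(geom$height, 0, noise_sd)
          out[, j, k] <- (base[[j]] + noise)[sub]
        }
      }
      out <- round(pmin(255, pmax(0, out)))
    } else {
      for (k in seq_along(idx)) {
        base <- if (cone_state[idx[k]]) clean_present else clean_absent
        for (j in seq_along(cols)) out[, j, k] <- base[[j]][sub]
      }
    }
    out
  }
  render_frames <- function(idx) {
    lapply(idx, function(i) {
      m <- render_region(i, 0:(geom$height - 1L), 0:(geom$width - 1L))
      matrix(m, geom$height, geom$width)
    })
  }

  stack <- structure(
    list(n_frames = n, width = settings$width, height = settings$height,
         frame_rate = settings$frame_rate, timestamps = timestamps,
         geometry = geom, noise_sd = noise_sd, seed = seed,
         backend = "lazy",
         render_frames = render_frames, render_region = render_region,
         truth_cone_state = cone_state),
    class = "frame_stack"
  )
  if (as.double(n) * settings$width * settings$height <= max_pixels_in_memory) {
    stack$backend <- "array"
    stack$frames <- render_frames(seq_len(n))
  }
  stack
}

#' Construct a frame stack from in-memory matrices
#'
#' Entry point for frames that did not come from the synthetic renderer
#' (e.g. read from disk). All matrices must share one dimension.
#'
#' @param frames list of height x width intensity matrices (0-255).
#' @param frame_rate frames per second (used to synthesize timestamps
#'   when `timestamps` is NULL).
#' @param timestamps optional explicit per-frame times in seconds.
#' @return a `frame_stack` with backend `"array"`.
#' @export
frame_stack <- function(frames, frame_rate = NULL, timestamps = NULL) {
  stopifnot(is.list(frames))
  n <- length(frames)
  if (n > 0) {
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("all frames must have identical dimensions", call. = FALSE)
    }
  }
  if (is.null(timestamps)) {
    if (is.null(frame_rate)) {
      stop("either `frame_rate` or `timestamps` must be given", call. = FALSE)
    }
    timestamps <- if (n > 0) (seq_len(n) - 1) / frame_rate else numeric(0)
  } else if (is.null(frame_rate) && n > 1) {
    frame_rate <- 1 / stats::median(diff(timestamps))
  }
  structure(
    list(n_frames = n,
         width = if (n > 0) ncol(frames[[1]]) else NA_integer_,
         height = if (n > 0) nrow(frames[[1]]) else NA_integer_,
         frame_rate = frame_rate, timestamps = timestamps,
         backend = "array", frames = frames),
    class = "frame_stack"
  )
}

#' Retrieve frames from a stack as matrices
#'
#' @param stack a `frame_stack`.
#' @param idx 1-based frame indices.
#' @return list of height x width matrices.
#' @export
get_frames <- function(stack, idx) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(idx) && (min(idx) < 1 || max(idx) > stack$n_frames)) {
    stop("frame index out of range", call. = FALSE)
  }
  if (stack$backend == "array") stack$frames[idx] else stack$render_frames(idx)
}

#' @export
print.frame_stack <- function(x, ...) {
  cat("<frame_stack> ", x$n_frames, " frames, ", x$height, "x", x$width,
      " px, ", format(x$frame_rate), " fps [", x$backend, "]\n", sep = "")
  invisible(x)
}
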