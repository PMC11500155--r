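#' Detection geometry for the reference-line cone classifier
#'
#' The classifier extracts a vertical reference line of `line_length`
#' pixels (default 120), centred on the user-selected emitter-tip
#' midpoint and placed `horizontal_offset` pixels in front of the tip,
#' then counts pixels darker than `intensity_threshold`. A frame is
#' classified cone-present when the count reaches `count_threshold`.
#'
#' All pixel coordinates are 0-based with origin at the top-left corner,
#' x rightward (spray direction) and y downward.
#'
#' @param tip_x,tip_y emitter-tip midpoint (0-based pixels). Interactive
#'   tip selection is out of scope; [propose_tip()] can suggest one but
#'   is never applied silently.
#' @param horizontal_offset distance of the line from the tip, px. The
#'   offset is voltage-dependent (30-50 px; 40 px at 4.0 kV) and is
#'   usually taken from a [make_preset()].
#' @param line_length number of rows in the reference line.
#' @param intensity_threshold 8-bit level strictly below which a pixel
#'   counts as black (default 128, mid-gray).
#' @param count_threshold minimum black pixels for cone presence
#'   (default 10 of 120). Both thresholds are mandatory, explicit
#'   configuration: the classifier never guesses them from data.
#' @return an object of class `detection_geometry`.
#' @export
detection_geometry <- function(tip_x, tip_y, horizontal_offset = 40,
                               line_length = 120,
                               intensity_threshold = 128,
                               count_threshold = 10) {
  stopifnot(tip_x >= 0, tip_y >= 0, line_length >= 1,
            intensity_threshold >= 0, intensity_threshold <= 255,
            count_threshold >= 0, count_threshold <= line_length)
  if (horizontal_offset < 30 || horizontal_offset > 50) {
    stop("`horizontal_offset` must lie in [30, 50] px", call. = FALSE)
  }
  structure(
    list(tip_x = as.integer(tip_x), tip_y = as.integer(tip_y),
         horizontal_offset = as.integer(round(horizontal_offset)),
         line_length = as.integer(line_length),
         intensity_threshold = intensity_threshold,
         count_threshold = count_threshold),
    class = "detection_geometry"
  )
}

# 0-based row indices of the reference line, centred on tip_y.
line_rows <- function(geometry) {
  geometry$tip_y - geometry$line_length %/% 2 +
    seq_len(geometry$line_length) - 1L
}

check_geometry_fits <- function(geometry, width, height) {
  x <- geometry$tip_x + geometry$horizontal_offset
  rows <- line_rows(geometry)
  if (x < 0 || x >= width || min(rows) < 0 || max(rows) >= height) {
    stop("reference line (x = ", x, ", rows ", min(rows), "..", max(rows),
         ") does not fit inside a ", height, "x", width, " frame",
         call. = FALSE)
  }
  invisible(x)
}

#' Extract the reference-line column from a frame
#'
#' @param frame height x width intensity matrix (0-255).
#' @param geometry a [detection_geometry()].
#' @return numeric vector of `line_length` intensities at
#'   `x = tip_x + horizontal_offset`, rows centred on `tip_y`.
#' @export
extract_reference_column <- function(frame, geometry) {
  stopifnot(is.matrix(frame), inherits(geometry, "detection_geometry"))
  x <- check_geometry_fits(geometry, ncol(frame), nrow(frame))
  frame[line_rows(geometry) + 1L, x + 1L]
}

#' Count black pixels in a reference column
#'
#' @param column numeric vector of intensities.
#' @param intensity_threshold pixels strictly below this level count as
#'   black.
#' @return integer count.
#' @export
count_black_pixels <- function(column, intensity_threshold = 128) {
  sum(column < intensity_threshold)
}

#' Classify cone presence from a black-pixel count
#'
#' @param black_count integer count from [count_black_pixels()].
#' @param count_threshold presence requires `black_count >=
#'   count_threshold` (the boundary count classifies as present).
#' @return logical.
#' @export
classify_presence <- function(black_count, count_threshold = 10) {
  black_count >= count_threshold
}

#' Run the cone classifier over a frame stack
#'
#' Produces one (black-pixel count, presence) pair per frame. For lazy
#' synthetic stacks only the reference-line region is rendered, in
#' chunks, so 150,000-frame acquisitions are processed without
#' materialising full frames.
#'
#' @param stack a `frame_stack`.
#' @param geometry a [detection_geometry()].
#' @param chunk_size frames per chunk for lazy stacks.
#' @return an object of class `cone_trace`: list with `timestamps` (s),
#'   `black_count` (integer per frame), `present` (logical per frame)
#'   and the `geometry` used.
#' @export
analyze_stack <- function(stack, geometry, chunk_size = 2000L) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(geometry, "detection_geometry"))
  n <- stack$n_frames
  if (n == 0) {
    return(structure(list(timestamps = numeric(0),
                          black_count = integer(0), present = logical(0),
                          geometry = geometry),
                     class = "cone_trace"))
  }
  check_geometry_fits(geometry, stack$width, stack$height)
  counts <- integer(n)
  if (stack$backend == "lazy") {
    x <- geometry$tip_x + geometry$horizontal_offset
    rows <- line_rows(geometry)
    starts <- seq.int(1L, n, by = chunk_size)
    for (s in starts) {
      idx <- s:min(n, s + chunk_size - 1L)
      region <- stack$render_region(idx, rows, x)  # line_length x 1 x |idx|
      counts[idx] <- as.integer(
        colSums(matrix(region, length(rows), length(idx)) <
                  geometry$intensity_threshold))
    }
  } else {
    for (i in seq_len(n)) {
      col <- tryCatch(
        extract_reference_column(stack$frames[[i]], geometry),
        error = function(e) {
          stop("frame ", i, ": ", conditionMessage(e), call. = FALSE)
        }
      )
      counts[i] <- count_black_pixels(col, geometry$intensity_threshold)
    }
  }
  structure(
    list(timestamps = stack$timestamps, black_count = counts,
         present = classify_presence(counts, geometry$count_threshold),
         geometry = geometry),
    class = "cone_trace"
  )
}

#' Propose an emitter-tip anchor from a single frame
#'
#' Scans for the rightmost column that is contiguous with the left-edge
#' silhouette and still contains dark pixels; the proposed tip is that
#' column and the midpoint of its dark rows. This is a convenience for
#' interactive use: it is never applied automatically, the tip anchor is
#' always an explicit input to [detection_geometry()].
#'
#' @param frame height x width intensity matrix.
#' @param intensity_threshold darkness threshold (8-bit level).
#' @return list with 0-based `tip_x` and `tip_y`, or NULL when the frame
#'   contains no silhouette touching the left edge.
#' @export
propose_tip <- function(frame, intensity_threshold = 128) {
  dark <- frame < intensity_threshold
  has_dark <- colSums(dark) > 0
  if (!has_dark[1]) return(NULL)
  run <- which(!has_dark)
  tip_col <- if (length(run)) min(run) - 1L else ncol(frame)
  rows <- which(dark[, tip_col])
  list(tip_x = tip_col - 1L, tip_y = as.integer(round(mean(rows))) - 1L)
}

#' @export
print.cone_trace <- function(x, ...) {
  cat("<cone_trace> ", length(x$timestamps), " frames; cone present in ",
      sum(x$present), " (", format(signif(100 * mean(x$present), 3)),
      "%)\n", sep = "")
  invisible(x)
}

#' @export
plot.cone_trace <- function(x, max_points = 5000, ...) {
  idx <- seq_len(min(length(x$timestamps), max_points))
  graphics::plot(x$timestamps[idx], x$black_count[idx], type = "l",
                 xlab = "time (s)", ylab = "black pixels on reference line",
                 ...)
  graphics::abline(h = x$geometry$count_threshold, lty = 2, col = "red")
  invisible(x)
}
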