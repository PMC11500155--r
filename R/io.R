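#' Write a frame stack to disk
#'
#' @param stack a `frame_stack` (lazy stacks are rendered; intended for
#'   modest sizes).
#' @param dir output directory (created if needed).
#' @param format `"png"` (one numbered file per frame), `"tiff"`
#'   (multi-page), or `"raw"` (8-bit binary plus JSON sidecar).
#' @param prefix filename prefix for PNG sequences.
#' @return invisibly, the paths written. A JSON sidecar with width,
#'   height, frame count and frame rate accompanies every format.
#' @export
write_frame_stack <- function(stack, dir, format = c("png", "tiff", "raw"),
                              prefix = "frame") {
  format <- match.arg(format)
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- get_frames(stack, seq_len(stack$n_frames))
  meta <- list(width = stack$width, height = stack$height,
               n_frames = stack$n_frames, frame_rate = stack$frame_rate)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- switch(format,
    png = {
      p <- file.path(dir, sprintf("%s_%06d.png", prefix,
                                  seq_len(stack$n_frames) - 1L))
      for (i in seq_along(frames)) png::writePNG(frames[[i]] / 255, p[i])
      p
    },
    tiff = {
      p <- file.path(dir, paste0(prefix, ".tiff"))
      tiff::writeTIFF(lapply(frames, function(f) f / 255), p,
                      bits.per.sample = 8L)
      p
    },
    raw = {
      p <- file.path(dir, paste0(prefix, ".raw"))
      con <- file(p, "wb")
      on.exit(close(con))
      for (f in frames) {
        writeBin(as.raw(as.integer(t(f))), con)  # row-major per frame
      }
      p
    }
  )
  invisible(c(paths, file.path(dir, "stack.json")))
}

read_sidecar <- function(dir) {
  p <- file.path(dir, "stack.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
}

#' Read a frame stack from disk
#'
#' Supported layouts: a numbered PNG sequence, a multi-page TIFF, or a
#' raw 8-bit binary with a JSON header sidecar (`stack.json` giving
#' width, height, n_frames, frame_rate). Frames are returned in
#' filename/temporal order, and timestamps are synthesized from the
#' frame rate (sidecar or `frame_rate` argument).
#'
#' With `frames_per_image > 1`, each stored image is a merged buffer of
#' that many frames tiled vertically (the camera convention of merging
#' every 100 buffers into one image), and is split back into individual
#' frames, so 1500 merged images expand to 150,000 frames.
#'
#' @param path directory (PNG sequence / raw) or file (TIFF).
#' @param format `"png"`, `"tiff"` or `"raw"`.
#' @param frame_rate frames per second; overrides the sidecar. An error
#'   is raised when neither is available.
#' @param frames_per_image frames merged vertically per stored image.
#' @return a `frame_stack` with backend `"array"`.
#' @export
read_frame_stack <- function(path, format = c("png", "tiff", "raw"),
                             frame_rate = NULL, frames_per_image = 1L) {
  format <- match.arg(format)
  frames_per_image <- as.integer(frames_per_image)
  stopifnot(frames_per_image >= 1)
  frames <- switch(format,
    png = {
      files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
      if (length(files) == 0) stop("no PNG files in ", path, call. = FALSE)
      nums <- suppressWarnings(
        as.integer(sub(".*_(\\d+)\\.png$", "\\1", basename(files)))
      )
      if (!anyNA(nums)) {
        expected <- seq(min(nums), max(nums))
        missing <- setdiff(expected, nums)
        if (length(missing)) {
          stop("PNG sequence has gaps: missing index ",
               paste(utils::head(missing, 5), collapse = ", "),
               call. = FALSE)
        }
        files <- files[order(nums)]
      }
      lapply(files, function(f) round(png::readPNG(f) * 255))
    },
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, function(f) round(f * 255))
    },
    raw = {
      meta <- read_sidecar(if (dir.exists(path)) path else dirname(path))
      if (is.null(meta)) {
        stop("raw format requires a stack.json sidecar", call. = FALSE)
      }
      file <- if (dir.exists(path)) {
        list.files(path, pattern = "\\.raw$", full.names = TRUE)[1]
      } else {
        path
      }
      bytes <- readBin(file, "raw", n = file.size(file))
      per <- meta$width * meta$height
      n <- length(bytes) %/% per
      lapply(seq_len(n), function(i) {
        matrix(as.integer(bytes[((i - 1) * per + 1):(i * per)]),
               nrow = meta$height, byrow = TRUE)
      })
    }
  )
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames have mixed dimensions", call. = FALSE)
  }
  if (frames_per_image > 1) {
    sub_h <- dims[1, 1] %/% frames_per_image
    if (sub_h * frames_per_image != dims[1, 1]) {
      stop("image height ", dims[1, 1], " is not divisible by ",
           "frames_per_image = ", frames_per_image, call. = FALSE)
    }
    frames <- unlist(lapply(frames, function(img) {
      lapply(seq_len(frames_per_image), function(k) {
        img[((k - 1) * sub_h + 1):(k * sub_h), , drop = FALSE]
      })
    }), recursive = FALSE)
  }
  if (is.null(frame_rate)) {
    meta <- read_sidecar(if (dir.exists(path)) path else dirname(path))
    frame_rate <- meta$frame_rate
    if (is.null(frame_rate)) {
      stop("no frame-rate metadata found; pass `frame_rate` explicitly",
           call. = FALSE)
    }
  }
  frame_stack(frames, frame_rate = frame_rate)
}

#' Write a time/value trace as CSV
#'
#' @param trace a `current_trace` or `ms_trace`.
#' @param path output path.
#' @return invisibly, `path`. Columns are `time,value` with full double
#'   precision.
#' @export
write_trace_csv <- function(trace, path) {
  df <- if (inherits(trace, "ms_trace")) {
    data.frame(time = trace$event_times, value = trace$intensity)
  } else if (inherits(trace, "current_trace")) {
    data.frame(time = trace$times, value = trace$current)
  } else {
    stop("`trace` must be a current_trace or ms_trace", call. = FALSE)
  }
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an oscilloscope/MS trace from a two-column CSV
#'
#' Accepts the common oscilloscope export dialect: two numeric columns
#' (time, value), with or without a header row. The time grid must be
#' uniform to within 1% of the median step; jittered grids are rejected
#' with a hint to resample first.
#'
#' @param path CSV file path.
#' @param as return a `"current"` (`current_trace`) or `"ms"`
#'   (`ms_trace`) object.
#' @param mz_label m/z metadata when `as = "ms"`.
#' @return a `current_trace` or `ms_trace`.
#' @export
read_trace_csv <- function(path, as = c("current", "ms"), mz_label = 152) {
  as <- match.arg(as)
  raw <- utils::read.csv(path, header = FALSE,
                         colClasses = "character",
                         blank.lines.skip = TRUE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("empty trace file: ", path, call. = FALSE)
  }
  first_numeric <- !anyNA(suppressWarnings(as.numeric(raw[1, 1:2])))
  if (!first_numeric) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) stop("trace file has a header but no data rows: ",
                           path, call. = FALSE)
  times <- suppressWarnings(as.numeric(raw[, 1]))
  values <- suppressWarnings(as.numeric(raw[, 2]))
  if (anyNA(times) || anyNA(values)) {
    stop("non-numeric rows in trace file: ", path, call. = FALSE)
  }
  if (length(times) >= 3) {
    d <- diff(times)
    med <- stats::median(d)
    if (med <= 0 || max(abs(d - med)) > 0.01 * med) {
      stop("time grid is not uniform (tolerance 1% of median step); ",
           "resample the trace before importing", call. = FALSE)
    }
  }
  step <- if (length(times) >= 2) times[2] - times[1] else NA_real_
  if (as == "current") {
    structure(list(times = times, current = values, noise_sd = NA_real_,
                   sample_step = step, aliased = FALSE),
              class = "current_trace")
  } else {
    structure(list(event_times = times, intensity = values,
                   mz_label = mz_label, dwell = NA_real_, event = step),
              class = "ms_trace")
  }
}

#' Assemble, write and read a run configuration
#'
#' A `run_config` captures everything needed to reproduce a run: spray
#' preset parameters, detection geometry, chain parameters, acquisition
#' settings and seed. Every pipeline command writes its resolved config
#' next to its outputs so each artifact is reproducible byte-for-byte.
#'
#' @param esi_voltage kV.
#' @param duration s.
#' @param frame_rate fps.
#' @param seed integer.
#' @param geometry a [detection_geometry()] or NULL for defaults.
#' @param chain a [chain_params()].
#' @param extra named list of additional serializable fields.
#' @return object of class `run_config` (a plain named list).
#' @export
run_config <- function(esi_voltage = 4.0, duration = 30,
                       frame_rate = 5000, seed = 1,
                       geometry = NULL, chain = chain_params(),
                       extra = list()) {
  cfg <- c(list(esi_voltage = esi_voltage, duration = duration,
                frame_rate = frame_rate, seed = as.integer(seed),
                geometry = if (is.null(geometry)) NULL else unclass(geometry),
                chain = unclass(chain)),
           extra)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("esi_voltage", "duration", "frame_rate", "seed", "geometry",
             "chain", "shifts_ms", "voltage", "condition", "set_delay_ms",
             "bin_size", "pixel_noise_sd", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         " (thresholds and parameters must be spelled explicitly; ",
         "no silent defaults)", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}
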