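# Per-frame joint angles and maximum-ROM extraction.
#
# The angle at vertex B between rays BA and BC is
#   theta = | (180 / pi) * atan2(BA x BC, BA . BC) |
# with x the scalar 2D cross product and . the dot product. The absolute
# value makes the result independent of side, winding and the image-axis
# convention, matching goniometric practice: theta is always in [0, 180].

.eps_len_default <- 1e-9

#' Angle between two 2D vectors
#'
#' Computes `|180/pi * atan2(ba x bc, ba . bc)|`, the unsigned angle in
#' degrees between displacement vectors `ba` and `bc` sharing a vertex.
#'
#' @param ba,bc Numeric length-2 vectors `(dx, dy)` in pixels.
#' @param eps_len Vectors with magnitude below this are degenerate and
#'   raise an error (default `1e-9` px).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
#' @examples
#' angle_between(c(1, 0), c(0, 1))  # 90
angle_between <- function(ba, bc, eps_len = .eps_len_default) {
  if (length(ba) != 2 || length(bc) != 2 ||
      !all(is.finite(ba)) || !all(is.finite(bc))) {
    rom_input_error("vectors must be finite numeric length-2 (dx, dy)")
  }
  if (sqrt(sum(ba^2)) < eps_len || sqrt(sum(bc^2)) < eps_len) {
    rom_degenerate_error("degenerate (near zero-length) vector")
  }
  cross <- ba[1] * bc[2] - ba[2] * bc[1]
  dot <- ba[1] * bc[1] + ba[2] * bc[2]
  abs(atan2(cross, dot)) * 180 / pi
}

new_angle_series <- function(df, task, side, fps, source) {
  stopifnot(all(c("frame", "time_s", "angle_deg", "invalid_reason") %in%
                names(df)))
  rownames(df) <- NULL
  structure(df, task = task, side = side, fps = fps, source = source,
            class = c("angle_series", "data.frame"))
}

angle_sample <- function(frame, fps, angle, reason) {
  list(frame_index = frame, angle = angle, invalid_reason = reason,
       time_s = frame / fps)
}

#' Joint angle for one motion task in one frame
#'
#' Applies the task's angle definition (see [angle_definition()]) to the
#' landmarks of a single frame. Missing landmarks, detections below the
#' confidence threshold and degenerate geometry do not raise errors:
#' invalidity is data, reported in the sample's `invalid_reason`.
#'
#' @param landmarks Named list of landmarks as returned by
#'   [frame_landmarks()], or a `landmark_sequence` together with `frame`.
#' @param task One of [motion_tasks()].
#' @param side `"left"` or `"right"`.
#' @param confidence_threshold Detections with confidence strictly below
#'   this are treated as absent for angle purposes (reason
#'   `low-confidence`). `0` disables the check.
#' @param eps_len Degeneracy threshold in pixels.
#' @return A list with `angle` (degrees, `NA` when invalid) and
#'   `invalid_reason` (`"none"`, `"absent-landmark"`, `"low-confidence"`,
#'   `"degenerate-geometry"`).
#' @export
task_angle <- function(landmarks, task, side = c("right", "left"),
                       confidence_threshold = 0,
                       eps_len = .eps_len_default) {
  task <- match_task(task)
  side <- match.arg(side)
  def <- angle_definition(task, side)
  need <- c(def$vertex, def$ray_a_end, def$ray_c_end)
  pts <- landmarks[need]
  if (any(vapply(pts, is.null, logical(1)))) {
    return(list(angle = NA_real_, invalid_reason = "absent-landmark"))
  }
  conf <- vapply(pts, function(p) {
    if (is.null(p$confidence) || is.na(p$confidence)) 1 else p$confidence
  }, numeric(1))
  if (confidence_threshold > 0 && any(conf < confidence_threshold)) {
    return(list(angle = NA_real_, invalid_reason = "low-confidence"))
  }
  b <- c(pts[[1]]$x, pts[[1]]$y)
  ba <- c(pts[[2]]$x, pts[[2]]$y) - b
  bc <- c(pts[[3]]$x, pts[[3]]$y) - b
  raw <- tryCatch(angle_between(ba, bc, eps_len = eps_len),
                  rom_degenerate_error = function(e) NA_real_)
  if (is.na(raw)) {
    return(list(angle = NA_real_, invalid_reason = "degenerate-geometry"))
  }
  ang <- if (def$transform == "supplement") 180 - raw else raw
  list(angle = ang, invalid_reason = "none")
}

#' Per-frame angle series for a motion task
#'
#' Computes one angle sample per frame of a landmark sequence, in frame
#' order. Frames missing a required landmark, failing the confidence
#' threshold, or with degenerate geometry yield invalid samples; the rest
#' of the series is unaffected.
#'
#' An optional running-median filter can suppress single-frame jitter
#' spikes before maximum extraction. It operates on the subsequence of
#' valid samples only (invalid samples pass through unfilled) and keeps
#' the end samples unchanged. The default is no smoothing: the raw
#' per-frame angles feed directly into the max, which is the literal
#' measurement procedure; enabling smoothing is a documented deviation.
#'
#' @param seq A [landmark_sequence()].
#' @param task One of [motion_tasks()].
#' @param side `"left"` or `"right"`.
#' @param smoothing `"none"` (default) or `"median"`.
#' @param window Odd integer window (>= 3) for the median filter.
#' @param confidence_threshold See [task_angle()].
#' @param eps_len Degeneracy threshold in pixels.
#' @return An `angle_series`: a data.frame with columns `frame`, `time_s`,
#'   `angle_deg`, `invalid_reason` and attributes `task`, `side`, `fps`,
#'   `source`.
#' @export
compute_series <- function(seq, task, side = c("right", "left"),
                           smoothing = c("none", "median"), window = 3L,
                           confidence_threshold = 0,
                           eps_len = .eps_len_default) {
  stopifnot(inherits(seq, "landmark_sequence"))
  task <- match_task(task)
  side <- match.arg(side)
  smoothing <- match.arg(smoothing)
  if (smoothing == "median") {
    window <- as.integer(window)
    if (is.na(window) || window < 3L || window %% 2L == 0L) {
      rom_input_error("median smoothing window must be an odd integer >= 3")
    }
  }
  def <- angle_definition(task, side)
  n <- seq$n_frames
  lm <- seq$landmarks
  key <- paste(lm$frame, lm$joint)
  get_joint <- function(joint) {
    idx <- match(paste(seq_len(n) - 1L, joint), key)
    cbind(x = lm$x[idx], y = lm$y[idx], conf = lm$confidence[idx])
  }
  B <- get_joint(def$vertex)
  A <- get_joint(def$ray_a_end)
  C <- get_joint(def$ray_c_end)

  absent <- is.na(B[, "x"]) | is.na(A[, "x"]) | is.na(C[, "x"])
  conf_of <- function(M) ifelse(is.na(M[, "conf"]), 1, M[, "conf"])
  lowconf <- !absent & confidence_threshold > 0 &
    (conf_of(B) < confidence_threshold | conf_of(A) < confidence_threshold |
     conf_of(C) < confidence_threshold)
  bax <- A[, "x"] - B[, "x"]; bay <- A[, "y"] - B[, "y"]
  bcx <- C[, "x"] - B[, "x"]; bcy <- C[, "y"] - B[, "y"]
  degen <- !absent & !lowconf &
    (sqrt(bax^2 + bay^2) < eps_len | sqrt(bcx^2 + bcy^2) < eps_len)

  raw <- abs(atan2(bax * bcy - bay * bcx, bax * bcx + bay * bcy)) * 180 / pi
  ang <- if (def$transform == "supplement") 180 - raw else raw
  reason <- rep("none", n)
  reason[degen] <- "degenerate-geometry"
  reason[lowconf] <- "low-confidence"
  reason[absent] <- "absent-landmark"
  ang[reason != "none"] <- NA_real_

  if (smoothing == "median") {
    valid <- which(reason == "none")
    if (length(valid) >= window) {
      ang[valid] <- stats::runmed(ang[valid], k = window, endrule = "keep")
    }
  }
  frames <- seq_len(n) - 1L
  new_angle_series(
    data.frame(frame = frames, time_s = frames / seq$fps,
               angle_deg = ang, invalid_reason = reason,
               stringsAsFactors = FALSE),
    task = task, side = side, fps = seq$fps, source = seq$source)
}

#' @export
print.angle_series <- function(x, ...) {
  nv <- sum(x$invalid_reason == "none")
  cat(sprintf("angle_series: task=%s side=%s, %d frames (%d valid)\n",
              attr(x, "task"), attr(x, "side"), nrow(x), nv))
  NextMethod()
}

#' Scatterplot of an angle series
#'
#' Plots the per-frame joint angle against time, the display the analysis
#' produces for a processed motion-task video. Invalid frames are marked
#' along the axis.
#'
#' @param x An `angle_series`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.angle_series <- function(x, ...) {
  graphics::plot(x$time_s, x$angle_deg, xlab = "time (s)",
                 ylab = "angle (degrees)",
                 main = sprintf("%s (%s)", attr(x, "task"), attr(x, "side")),
                 pch = 16, ...)
  bad <- x$invalid_reason != "none"
  if (any(bad)) graphics::rug(x$time_s[bad], col = "red")
  invisible(x)
}

#' Maximum range of motion from an angle series
#'
#' The largest computed angle across all frames is taken as the maximum
#' ROM; the frame achieving it (earliest, on ties) is reported alongside
#' validity counts.
#'
#' @param series An `angle_series` from [compute_series()].
#' @param min_valid Minimum number of valid samples required (default 1).
#' @return A `rom_result`: list with `max_angle` (degrees), `argmax_frame`
#'   (0-based), `n_valid_frames`, `n_total_frames`, `task`, `side`.
#' @export
max_rom <- function(series, min_valid = 1L) {
  stopifnot(inherits(series, "angle_series"))
  min_valid <- max(1L, as.integer(min_valid))
  valid <- series$invalid_reason == "none"
  if (sum(valid) < min_valid) {
    rom_insufficient_data_error(sprintf(
      "only %d valid angle samples (need >= %d)", sum(valid), min_valid))
  }
  idx <- which(valid)[which.max(series$angle_deg[valid])]
  structure(
    list(max_angle = series$angle_deg[idx],
         argmax_frame = series$frame[idx],
         n_valid_frames = sum(valid),
         n_total_frames = nrow(series),
         task = attr(series, "task"), side = attr(series, "side")),
    class = "rom_result")
}

#' @export
print.rom_result <- function(x, ...) {
  cat(sprintf(
    "max ROM %.3f deg at frame %d (%s, %s side; %d/%d frames valid)\n",
    x$max_angle, x$argmax_frame, x$task, x$side,
    x$n_valid_frames, x$n_total_frames))
  invisible(x)
}

#' Measure maximum ROM from landmarks or video frames
#'
#' End-to-end measurement: (optionally) run a pose backend over frames,
#' compute the per-frame task angle, and extract the maximum ROM. Accepts
#' a [landmark_sequence()], the path of a landmark CSV/JSON file, or raw
#' frames (a list of image arrays, or a directory of PNG frames) together
#' with a pose backend.
#'
#' @param x Input: `landmark_sequence`, file path, or frames.
#' @param task One of [motion_tasks()].
#' @param side `"left"` or `"right"`.
#' @param ... Passed on to [compute_series()] (`smoothing`, `window`,
#'   `confidence_threshold`) and, for frame input, to
#'   [estimate_sequence()] (`fps`, `source`).
#' @param min_valid Minimum valid frames required by [max_rom()].
#' @param backend A pose backend (frame input only); see
#'   [marker_backend()].
#' @return A `rom_measurement`: list with elements `rom` (a `rom_result`)
#'   and `series` (the `angle_series`).
#' @export
#' @examples
#' sim <- simulate_motion(motion_config(task = "shoulder_abduction",
#'                                      peak_angle = 90, seed = 1))
#' measure(sim$sequence, "shoulder_abduction", "right")
measure <- function(x, task, side = c("right", "left"), ...,
                    min_valid = 1L, backend = NULL) {
  UseMethod("measure")
}

measure_impl <- function(seq, task, side, ..., min_valid) {
  args <- list(...)
  cs_args <- args[names(args) %in%
                  c("smoothing", "window", "confidence_threshold", "eps_len")]
  series <- do.call(compute_series,
                    c(list(seq = seq, task = task, side = side), cs_args))
  valid_frac <- mean(series$invalid_reason == "none")
  if (valid_frac < 0.25) {
    warning(sprintf("only %.0f%% of frames produced a valid angle",
                    100 * valid_frac), call. = FALSE)
  }
  rom <- max_rom(series, min_valid = min_valid)
  structure(list(rom = rom, series = series), class = "rom_measurement")
}

#' @rdname measure
#' @export
measure.landmark_sequence <- function(x, task, side = c("right", "left"),
                                      ..., min_valid = 1L, backend = NULL) {
  side <- match.arg(side)
  measure_impl(x, task, side, ..., min_valid = min_valid)
}

#' @rdname measure
#' @export
measure.character <- function(x, task, side = c("right", "left"), ...,
                              min_valid = 1L, backend = NULL) {
  side <- match.arg(side)
  if (length(x) == 1 && dir.exists(x)) {
    if (is.null(backend)) {
      rom_input_error("frame-directory input requires a pose backend")
    }
    args <- list(...)
    es_args <- args[names(args) %in% c("fps", "source")]
    seq <- do.call(estimate_sequence,
                   c(list(frames = x, backend = backend), es_args))
    return(measure_impl(seq, task, side, ..., min_valid = min_valid))
  }
  seq <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
    read_landmark_json(x)
  } else {
    read_landmark_csv(x)
  }
  measure_impl(seq, task, side, ..., min_valid = min_valid)
}

#' @rdname measure
#' @export
measure.list <- function(x, task, side = c("right", "left"), ...,
                         min_valid = 1L, backend = NULL) {
  side <- match.arg(side)
  if (is.null(backend)) {
    rom_input_error("frame-list input requires a pose backend")
  }
  args <- list(...)
  es_args <- args[names(args) %in% c("fps", "source")]
  seq <- do.call(estimate_sequence,
                 c(list(frames = x, backend = backend), es_args))
  measure_impl(seq, task, side, ..., min_valid = min_valid)
}

#' @export
print.rom_measurement <- function(x, ...) {
  print(x$rom)
  invisible(x)
}

#' @export
summary.rom_measurement <- function(object, ...) {
  s <- object$series
  valid <- s$invalid_reason == "none"
  out <- list(rom = object$rom,
              task = attr(s, "task"), side = attr(s, "side"),
              n_frames = nrow(s), n_valid = sum(valid),
              angle_range = if (any(valid)) range(s$angle_deg[valid])
                            else c(NA_real_, NA_real_),
              invalid_reasons = table(s$invalid_reason[!valid]))
  class(out) <- "summary.rom_measurement"
  out
}

#' @export
print.summary.rom_measurement <- function(x, ...) {
  print(x$rom)
  cat(sprintf("angle range over valid frames: [%.2f, %.2f] deg\n",
              x$angle_range[1], x$angle_range[2]))
  if (length(x$invalid_reasons)) {
    cat("invalid frames by reason:\n")
    print(x$invalid_reasons)
  }
  invisible(x)
}

#' @export
plot.rom_measurement <- function(x, ...) {
  plot(x$series, ...)
  graphics::abline(v = x$rom$argmax_frame / attr(x$series, "fps"),
                   lty = 2, col = "grey40")
  graphics::points(x$rom$argmax_frame / attr(x$series, "fps"),
                   x$rom$max_angle, col = "red", pch = 1, cex = 2)
  invisible(x)
}
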