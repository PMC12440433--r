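# Landmark sequence container.
#
# A sequence stores one row per (frame, joint) detection in a long
# data.frame. Absent joints simply have no row: a (0,0) coordinate is a
# valid pixel, so absence is never encoded by sentinel values. Image
# coordinates follow the video-frame convention: origin at the top-left,
# x to the right, y downward, units of pixels.

#' Construct a landmark sequence
#'
#' @param landmarks A data.frame with columns `frame` (0-based integer),
#'   `joint` (one of [joint_names()]), `x`, `y` (pixels) and optionally
#'   `confidence` (in `[0,1]`, `NA` when the backend reports none).
#' @param fps Frames per second (> 0). Timestamps are derived as
#'   `frame / fps`; the capture frame rate is always carried as metadata,
#'   never assumed.
#' @param width,height Frame dimensions in pixels.
#' @param source Free-text provenance (file name, backend, simulation id).
#' @param n_frames Total number of frames, including frames in which no
#'   joint was detected. Defaults to `max(frame) + 1` (0 when empty).
#' @return An object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(landmarks, fps, width, height,
                              source = "", n_frames = NULL) {
  if (!is.data.frame(landmarks)) {
    rom_input_error("`landmarks` must be a data.frame")
  }
  needed <- c("frame", "joint", "x", "y")
  if (!all(needed %in% names(landmarks))) {
    rom_input_error(sprintf("landmark table must have columns %s",
                            paste(needed, collapse = ", ")))
  }
  if (is.null(landmarks$confidence)) landmarks$confidence <- NA_real_
  landmarks <- landmarks[, c("frame", "joint", "x", "y", "confidence")]
  landmarks$frame <- as.integer(landmarks$frame)
  landmarks$joint <- as.character(landmarks$joint)
  landmarks$x <- as.numeric(landmarks$x)
  landmarks$y <- as.numeric(landmarks$y)
  landmarks$confidence <- as.numeric(landmarks$confidence)

  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0) {
    rom_input_error("`fps` must be a single positive number")
  }
  n <- nrow(landmarks)
  if (n > 0) {
    bad <- setdiff(unique(landmarks$joint), joint_names())
    if (length(bad) > 0) {
      rom_input_error(sprintf("unknown joint name(s): %s",
                              paste(bad, collapse = ", ")))
    }
    if (anyNA(landmarks$frame) || any(landmarks$frame < 0)) {
      rom_input_error("frame indices must be non-negative integers")
    }
    if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
      rom_input_error("landmark coordinates must be finite")
    }
    conf <- landmarks$confidence
    if (any(!is.na(conf) & (conf < 0 | conf > 1))) {
      rom_input_error("confidence values must lie in [0, 1]")
    }
    if (anyDuplicated(paste(landmarks$frame, landmarks$joint))) {
      rom_input_error("duplicate (frame, joint) landmark entries")
    }
  }
  if (is.null(n_frames)) {
    n_frames <- if (n == 0) 0L else max(landmarks$frame) + 1L
  }
  n_frames <- as.integer(n_frames)
  if (n > 0 && any(landmarks$frame >= n_frames)) {
    rom_input_error("frame index beyond declared n_frames")
  }
  landmarks <- landmarks[order(landmarks$frame, landmarks$joint), ,
                         drop = FALSE]
  rownames(landmarks) <- NULL
  structure(
    list(landmarks = landmarks, fps = as.numeric(fps),
         width = as.integer(width), height = as.integer(height),
         source = as.character(source), n_frames = n_frames),
    class = "landmark_sequence"
  )
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf(
    "landmark_sequence: %d frames @ %g fps, %dx%d px, %d detections\n",
    x$n_frames, x$fps, x$width, x$height, nrow(x$landmarks)))
  if (nzchar(x$source)) cat("source:", x$source, "\n")
  invisible(x)
}

#' @export
format.landmark_sequence <- function(x, ...) {
  sprintf("<landmark_sequence: %d frames, %d detections>",
          x$n_frames, nrow(x$landmarks))
}

#' Landmarks present in one frame
#'
#' @param seq A [landmark_sequence()].
#' @param frame 0-based frame index.
#' @return A named list of landmarks, each a list with `x`, `y`,
#'   `confidence`. Joints not detected in the frame are absent from the
#'   list.
#' @export
frame_landmarks <- function(seq, frame) {
  stopifnot(inherits(seq, "landmark_sequence"))
  rows <- seq$landmarks[seq$landmarks$frame == frame, , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    list(x = rows$x[i], y = rows$y[i], confidence = rows$confidence[i])
  })
  names(out) <- rows$joint
  out
}
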