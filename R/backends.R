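# Pose backends: anything that maps a color image to the landmarks it can
# detect. The backend contract is a list with an `estimate(image)` function
# returning a named list of landmarks (joints it did not detect are simply
# absent; coordinates lie within image bounds), a `name`, and a
# `deterministic` flag.
#
# Two backends ship: a deterministic color-fiducial marker detector that
# needs no model weights (used for end-to-end testing against rendered
# synthetic clips), and an adapter for a pretrained pose-estimation network
# whose weights and keypoint schema are user-supplied.

new_pose_backend <- function(name, estimate, deterministic) {
  structure(list(name = name, estimate = estimate,
                 deterministic = deterministic),
            class = "pose_backend")
}

#' @export
print.pose_backend <- function(x, ...) {
  cat(sprintf("pose_backend '%s' (%s)\n", x$name,
              if (x$deterministic) "deterministic" else "stochastic"))
  invisible(x)
}

# 12 reference colors on a {0,85,170,255} channel grid: any pair differs by
# >= 85 in some channel, comfortably above the 2 * tolerance separability
# requirement at the default tolerance of 30.
.default_marker_colors <- function() {
  cols <- rbind(
    c(255,   0,   0), c(  0, 255,   0), c(  0,   0, 255),
    c(255, 255,   0), c(255,   0, 255), c(  0, 255, 255),
    c(255,  85,   0), c( 85,   0, 255), c(  0, 170,  85),
    c(170, 255,   0), c(255,   0, 170), c( 85, 170, 255))
  rownames(cols) <- joint_names()
  cols
}

#' Color palette mapping joints to fiducial marker colors
#'
#' Each tracked joint is assigned a reference color; a pixel matches a
#' joint when all three channels are within `tolerance` of the reference.
#' The palette must be separable: no two reference colors may lie within
#' `2 * tolerance` on every channel, otherwise a pixel could match two
#' joints.
#'
#' @param colors Numeric matrix, one row per joint (rownames = joint
#'   names), three columns (RGB, 0-255). Defaults to a built-in separable
#'   12-color palette.
#' @param tolerance Per-channel maximum absolute difference for a match
#'   (default 30).
#' @return A `marker_palette` object.
#' @export
marker_palette <- function(colors = .default_marker_colors(),
                           tolerance = 30) {
  if (!is.matrix(colors) || ncol(colors) != 3 ||
      is.null(rownames(colors))) {
    rom_config_error("palette colors must be a named-row matrix with 3 columns")
  }
  bad <- setdiff(rownames(colors), joint_names())
  if (length(bad)) {
    rom_config_error(sprintf("unknown joints in palette: %s",
                             paste(bad, collapse = ", ")))
  }
  if (any(colors < 0 | colors > 255)) {
    rom_config_error("palette channels must lie in [0, 255]")
  }
  n <- nrow(colors)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && max(abs(colors[i, ] - colors[j, ])) <= 2 * tolerance) {
        rom_config_error(sprintf(
          "palette colors for %s and %s are not separable at tolerance %g",
          rownames(colors)[i], rownames(colors)[j], tolerance))
      }
    }
  }
  structure(list(colors = colors, tolerance = tolerance),
            class = "marker_palette")
}

# Normalize an image array to H x W x 3 in 0..255.
as_image_255 <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3) {
    rom_input_error("image must be an H x W x 3 array")
  }
  if (dim(image)[3] > 3) image <- image[, , 1:3, drop = FALSE]
  if (dim(image)[3] != 3) {
    rom_input_error("image must have 3 color channels")
  }
  if (max(image) <= 1) image <- image * 255
  image
}

#' Detect color fiducial markers in one frame
#'
#' For each joint in the palette, pixels matching the joint's reference
#' color (all channels within tolerance) are grouped into connected
#' components; if the largest component has at least `min_blob_area`
#' pixels, the joint's landmark is the component centroid and its
#' confidence is the component's share of all matching pixels. Equal-size
#' components are broken deterministically in favor of the component whose
#' top-left-most pixel has the smaller (row, col).
#'
#' @param image H x W x 3 numeric array (0-255, or 0-1 which is rescaled).
#' @param palette A [marker_palette()].
#' @param min_blob_area Minimum component size in pixels (default 4).
#' @return Named list of landmarks (`x`, `y` pixel coordinates of the
#'   centroid with the pixel-center convention, `confidence`); undetected
#'   joints absent.
#' @export
detect_markers <- function(image, palette = marker_palette(),
                           min_blob_area = 4L) {
  stopifnot(inherits(palette, "marker_palette"))
  img <- as_image_255(image)
  tol <- palette$tolerance
  out <- list()
  for (joint in rownames(palette$colors)) {
    ref <- palette$colors[joint, ]
    mask <- abs(img[, , 1] - ref[1]) <= tol &
            abs(img[, , 2] - ref[2]) <= tol &
            abs(img[, , 3] - ref[3]) <= tol
    total <- sum(mask)
    if (total == 0) next
    lab <- EBImage::bwlabel(mask * 1L)
    sizes <- tabulate(lab[lab > 0])
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      # tie: component containing the first pixel in column-major-transposed
      # (row, col) order, i.e. smallest row then smallest col
      first_pix <- sapply(best, function(k) {
        idx <- which(lab == k, arr.ind = TRUE)
        idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
        idx[1, 1] * 1e9 + idx[1, 2]
      })
      best <- best[which.min(first_pix)]
    }
    if (sizes[best] < min_blob_area) next
    px <- which(lab == best, arr.ind = TRUE)
    # pixel (row i, col j) covers x in [j-1, j), y in [i-1, i): center
    # (j - 0.5, i - 0.5)
    out[[joint]] <- list(x = mean(px[, 2]) - 0.5,
                         y = mean(px[, 1]) - 0.5,
                         confidence = sizes[best] / total)
  }
  out
}

#' Deterministic color-marker pose backend
#'
#' Wraps [detect_markers()] in the pose-backend contract. Bit-identical
#' output on identical input.
#'
#' @param palette A [marker_palette()].
#' @param min_blob_area Minimum blob size in pixels.
#' @return A `pose_backend`.
#' @export
marker_backend <- function(palette = marker_palette(), min_blob_area = 4L) {
  force(palette); force(min_blob_area)
  new_pose_backend(
    name = "marker",
    estimate = function(image) detect_markers(image, palette, min_blob_area),
    deterministic = TRUE)
}

#' Run a pose backend over a sequence of frames
#'
#' @param frames A list of H x W x 3 image arrays, or the path of a
#'   directory containing PNG frames (processed in lexicographic order),
#'   or a character vector of PNG file paths.
#' @param backend A `pose_backend` (e.g. [marker_backend()]).
#' @param fps Frame rate to attach to the output sequence (default 30;
#'   PNG frame series carry no timing metadata).
#' @param source Free-text provenance recorded in the sequence.
#' @return A [landmark_sequence()] with one frame per input frame, in
#'   order.
#' @export
estimate_sequence <- function(frames, backend, fps = 30, source = "") {
  stopifnot(inherits(backend, "pose_backend"))
  if (is.character(frames)) {
    paths <- if (length(frames) == 1 && dir.exists(frames)) {
      sort(list.files(frames, pattern = "\\.png$", full.names = TRUE,
                      ignore.case = TRUE))
    } else frames
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      rom_io_error(sprintf("frame file(s) not found: %s",
                           paste(missing, collapse = ", ")))
    }
    if (!nzchar(source) && length(paths)) source <- dirname(paths[1])
    frames <- lapply(paths, function(p) {
      a <- png::readPNG(p)
      if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
      a
    })
  }
  if (!is.list(frames) || length(frames) == 0) {
    rom_input_error("no decodable frames in input")
  }
  first <- as_image_255(frames[[1]])
  h <- dim(first)[1]; w <- dim(first)[2]
  rows <- list()
  for (i in seq_along(frames)) {
    lms <- backend$estimate(frames[[i]])
    for (jn in names(lms)) {
      p <- lms[[jn]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = i - 1L, joint = jn, x = p$x, y = p$y,
        confidence = if (is.null(p$confidence)) NA_real_ else p$confidence)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), joint = character(), x = numeric(),
               y = numeric(), confidence = numeric())
  landmark_sequence(df, fps = fps, width = w, height = h,
                    source = if (nzchar(source)) source else backend$name,
                    n_frames = length(frames))
}

#' Adapter for a pretrained pose-estimation network
#'
#' Builds a pose backend around user-supplied model files and inference
#' function. The adapter validates the configuration up front: model
#' files must exist locally (they are never downloaded), and the keypoint
#' map must either cover all 12 tracked joints or explicitly declare the
#' joints the model cannot produce.
#'
#' @param model_spec A list with fields:
#'   \describe{
#'     \item{model_files}{Character vector of required local file paths
#'       (e.g. network definition + weights).}
#'     \item{keypoint_map}{Named integer vector mapping joint names to
#'       row indices of the inference output.}
#'     \item{infer}{Function taking an H x W x 3 image and returning a
#'       numeric matrix with columns `x`, `y`, `confidence`, one row per
#'       model keypoint.}
#'     \item{missing_joints}{Optional character vector of tracked joints
#'       the model does not produce.}
#'     \item{confidence_threshold}{Keypoints below this confidence are
#'       reported absent (default 0.1).}
#'   }
#' @return A `pose_backend` named `"dnn"`.
#' @export
dnn_backend <- function(model_spec) {
  if (!is.list(model_spec) || is.null(model_spec$model_files) ||
      is.null(model_spec$keypoint_map) || is.null(model_spec$infer)) {
    rom_config_error(
      "model_spec needs fields 'model_files', 'keypoint_map' and 'infer'")
  }
  missing_files <- model_spec$model_files[!file.exists(model_spec$model_files)]
  if (length(missing_files)) {
    rom_config_error(sprintf(
      "pose model file(s) not found (supply them locally): %s",
      paste(missing_files, collapse = ", ")))
  }
  km <- model_spec$keypoint_map
  bad <- setdiff(names(km), joint_names())
  if (length(bad)) {
    rom_config_error(sprintf("keypoint_map has unknown joints: %s",
                             paste(bad, collapse = ", ")))
  }
  declared_missing <- if (is.null(model_spec$missing_joints)) character()
                      else model_spec$missing_joints
  uncovered <- setdiff(joint_names(), c(names(km), declared_missing))
  if (length(uncovered)) {
    rom_config_error(sprintf(
      "keypoint_map neither maps nor declares missing: %s",
      paste(uncovered, collapse = ", ")))
  }
  thr <- if (is.null(model_spec$confidence_threshold)) 0.1
         else model_spec$confidence_threshold
  infer <- model_spec$infer
  new_pose_backend(
    name = "dnn",
    estimate = function(image) {
      img <- as_image_255(image)
      kp <- infer(img)
      out <- list()
      for (jn in names(km)) {
        i <- km[[jn]]
        if (i > nrow(kp)) next
        conf <- kp[i, 3]
        if (is.na(conf) || conf < thr) next
        x <- kp[i, 1]; y <- kp[i, 2]
        if (x < 0 || y < 0 || x > dim(img)[2] || y > dim(img)[1]) next
        out[[jn]] <- list(x = x, y = y, confidence = conf)
      }
      out
    },
    deterministic = !isTRUE(model_spec$stochastic))
}
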