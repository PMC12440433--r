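# Plain-text readers/writers for landmark sequences, angle series, and
# rater matrices.
#
# Landmark CSV dialect: UTF-8, comma separated, '.' decimal. Comment header
# lines carry sequence metadata:
#   # fps=<float>
#   # width=<int>
#   # height=<int>
#   # n_frames=<int>      (optional; inferred from the data when missing)
#   # source=<text>
# followed by the column header `frame,joint,x,y,confidence` and one row
# per detected (frame, joint). Absent joints are encoded by row omission;
# confidence may be empty.

read_header_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 1) rom_format_error(sprintf("malformed header line: '%s'", ln))
    key <- trimws(substr(body, 1, eq - 1))
    val <- substr(body, eq + 1, nchar(body))
    meta[[key]] <- val
  }
  meta
}

header_num <- function(meta, key) {
  v <- suppressWarnings(as.numeric(meta[[key]]))
  if (length(v) != 1 || is.na(v)) {
    rom_format_error(sprintf("missing or non-numeric header field '%s'", key))
  }
  v
}

#' Read a landmark sequence from CSV
#'
#' Reads the landmark CSV dialect written by [write_landmark_csv()]:
#' `# key=value` comment headers (fps, width, height, optional n_frames,
#' source) followed by `frame,joint,x,y,confidence` rows. Joints absent in
#' a frame have no row. When the file does not declare `n_frames`, frame
#' indices must be contiguous from 0; gaps are a format error because the
#' total frame count would be ambiguous.
#'
#' @param path Path to a landmark CSV file.
#' @return A [landmark_sequence()].
#' @export
read_landmark_csv <- function(path) {
  if (!file.exists(path)) {
    rom_io_error(sprintf("landmark file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- read_header_meta(hdr)
  fps <- header_num(meta, "fps")
  width <- header_num(meta, "width")
  height <- header_num(meta, "height")
  source <- if (is.null(meta$source)) "" else meta$source
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0 || trimws(body[1]) != "frame,joint,x,y,confidence") {
    rom_format_error("missing 'frame,joint,x,y,confidence' column header")
  }
  df <- if (length(body) > 1) {
    utils::read.csv(text = body, stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "numeric",
                                   "numeric", "numeric"))
  } else {
    data.frame(frame = integer(), joint = character(), x = numeric(),
               y = numeric(), confidence = numeric())
  }
  declared_n <- if (!is.null(meta$n_frames)) {
    as.integer(header_num(meta, "n_frames"))
  } else NULL
  if (is.null(declared_n) && nrow(df) > 0) {
    idx <- sort(unique(df$frame))
    if (!identical(idx, seq(0L, max(idx)))) {
      rom_format_error(
        "frame indices are not contiguous from 0 and no n_frames header is present")
    }
  }
  landmark_sequence(df, fps = fps, width = width, height = height,
                    source = source, n_frames = declared_n)
}

#' Write a landmark sequence to CSV
#'
#' @param seq A [landmark_sequence()].
#' @param path Output path. The file round-trips through
#'   [read_landmark_csv()] with coordinates preserved to 6 decimal places.
#' @return Invisibly, `path`.
#' @export
write_landmark_csv <- function(seq, path) {
  stopifnot(inherits(seq, "landmark_sequence"))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) rom_io_error(conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    sprintf("# fps=%.6g", seq$fps),
    sprintf("# width=%d", seq$width),
    sprintf("# height=%d", seq$height),
    sprintf("# n_frames=%d", seq$n_frames),
    sprintf("# source=%s", seq$source),
    "frame,joint,x,y,confidence"
  ), con)
  lm <- seq$landmarks
  if (nrow(lm) > 0) {
    conf <- ifelse(is.na(lm$confidence), "",
                   sprintf("%.6f", lm$confidence))
    writeLines(sprintf("%d,%s,%.6f,%.6f,%s",
                       lm$frame, lm$joint, lm$x, lm$y, conf), con)
  }
  invisible(path)
}

#' Landmark sequence JSON round-trip
#'
#' JSON mirror of the CSV dialect: a top-level object with `fps`, `width`,
#' `height`, `n_frames`, `source` and a `frames` array holding one object
#' per frame with `frame`, `timestamp` (seconds, `frame / fps`) and a
#' `joints` object mapping joint names to `{x, y, confidence}`. Absent
#' joints are absent keys.
#'
#' @param seq A [landmark_sequence()].
#' @param path File path.
#' @return `write_landmark_json()` returns `path` invisibly;
#'   `read_landmark_json()` returns a [landmark_sequence()].
#' @export
write_landmark_json <- function(seq, path) {
  stopifnot(inherits(seq, "landmark_sequence"))
  frames <- lapply(seq_len(seq$n_frames) - 1L, function(f) {
    jl <- frame_landmarks(seq, f)
    jl <- lapply(jl, function(p) {
      if (is.na(p$confidence)) p["confidence"] <- NULL
      p
    })
    list(frame = f, timestamp = f / seq$fps, joints = jl)
  })
  obj <- list(fps = seq$fps, width = seq$width, height = seq$height,
              n_frames = seq$n_frames, source = seq$source, frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmark_json
#' @export
read_landmark_json <- function(path) {
  if (!file.exists(path)) {
    rom_io_error(sprintf("landmark file not found: %s", path))
  }
  obj <- jsonlite::read_json(path)
  for (key in c("fps", "width", "height", "n_frames")) {
    if (is.null(obj[[key]])) {
      rom_format_error(sprintf("landmark JSON missing field '%s'", key))
    }
  }
  rows <- list()
  for (fr in obj$frames) {
    for (jn in names(fr$joints)) {
      p <- fr$joints[[jn]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = as.integer(fr$frame), joint = jn,
        x = as.numeric(p$x), y = as.numeric(p$y),
        confidence = if (is.null(p$confidence)) NA_real_
                     else as.numeric(p$confidence))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), joint = character(), x = numeric(),
               y = numeric(), confidence = numeric())
  landmark_sequence(df, fps = obj$fps, width = obj$width,
                    height = obj$height,
                    source = if (is.null(obj$source)) "" else obj$source,
                    n_frames = obj$n_frames)
}

#' Write an angle series to CSV
#'
#' One row per frame with columns `frame`, `time_s`, `angle_deg` and
#' `invalid_reason`. Frames whose angle could not be computed leave the
#' `angle_deg` cell empty and carry the reason
#' (`absent-landmark`, `low-confidence`, `degenerate-geometry`); valid
#' frames carry `none`.
#'
#' @param series An [angle_series][compute_series()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_angle_csv <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) rom_io_error(conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    sprintf("# task=%s", attr(series, "task")),
    sprintf("# side=%s", attr(series, "side")),
    sprintf("# fps=%.6g", attr(series, "fps")),
    sprintf("# source=%s", attr(series, "source")),
    "frame,time_s,angle_deg,invalid_reason"
  ), con)
  ang <- ifelse(is.na(series$angle_deg), "",
                sprintf("%.6f", series$angle_deg))
  writeLines(sprintf("%d,%.6f,%s,%s", series$frame, series$time_s, ang,
                     series$invalid_reason), con)
  invisible(path)
}

#' Read an angle series from CSV
#'
#' Inverse of [write_angle_csv()].
#'
#' @param path Path to an angle CSV file.
#' @return An `angle_series` data.frame.
#' @export
read_angle_csv <- function(path) {
  if (!file.exists(path)) {
    rom_io_error(sprintf("angle file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  meta <- read_header_meta(grep("^#", lines, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0 ||
      trimws(body[1]) != "frame,time_s,angle_deg,invalid_reason") {
    rom_format_error("missing 'frame,time_s,angle_deg,invalid_reason' header")
  }
  df <- if (length(body) > 1) {
    utils::read.csv(text = body, stringsAsFactors = FALSE,
                    colClasses = c("integer", "numeric", "numeric",
                                   "character"))
  } else {
    data.frame(frame = integer(), time_s = numeric(),
               angle_deg = numeric(), invalid_reason = character())
  }
  new_angle_series(df,
                   task = if (is.null(meta$task)) NA_character_ else meta$task,
                   side = if (is.null(meta$side)) NA_character_ else meta$side,
                   fps = if (is.null(meta$fps)) NA_real_
                         else header_num(meta, "fps"),
                   source = if (is.null(meta$source)) "" else meta$source)
}

#' Read a rater-by-subject measurement matrix from CSV
#'
#' Expected layout: first column subject ids, remaining columns one per
#' rater or method, header row carrying rater ids. All cells must be
#' numeric angle measurements in degrees; missing cells are rejected
#' (complete designs only).
#'
#' @param path Path to the CSV file.
#' @return A numeric matrix, subjects in rows (rownames = subject ids),
#'   raters in columns (colnames = rater ids).
#' @export
read_rater_csv <- function(path) {
  if (!file.exists(path)) {
    rom_io_error(sprintf("rater matrix file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) rom_format_error(conditionMessage(e)))
  if (ncol(df) < 2) {
    rom_format_error("rater matrix needs a subject column plus >= 1 rater column")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) {
    rom_input_error("rater matrix has missing cells; only complete designs are supported")
  }
  rownames(m) <- as.character(df[[1]])
  m
}
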