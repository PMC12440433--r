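# Rasterization of landmark sequences into marker frames. Each joint is
# drawn as a filled disk of its palette color on black; the stick style
# adds dark-grey limb/trunk segments whose color can never match a palette
# reference, so detection is unaffected.

.stick_color <- c(40, 40, 40)

draw_disk <- function(canvas, x, y, radius, color) {
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  r0 <- max(1, floor(y - radius)); r1 <- min(h, ceiling(y + radius + 1))
  c0 <- max(1, floor(x - radius)); c1 <- min(w, ceiling(x + radius + 1))
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1
  cols <- c0:c1
  cy <- rows - 0.5; cx <- cols - 0.5
  hit <- outer((cy - y)^2, (cx - x)^2, "+") <= radius^2
  for (ch in 1:3) {
    plane <- canvas[rows, cols, ch]
    plane[hit] <- color[ch]
    canvas[rows, cols, ch] <- plane
  }
  canvas
}

draw_segment <- function(canvas, p1, p2, thickness, color) {
  len <- sqrt(sum((p2 - p1)^2))
  ts <- seq(0, 1, length.out = max(2L, ceiling(len * 2)))
  for (t in ts) {
    q <- p1 + t * (p2 - p1)
    canvas <- draw_disk(canvas, q[1], q[2], thickness / 2, color)
  }
  canvas
}

#' Render a landmark sequence as marker frames
#'
#' Produces one H x W x 3 image array (0-255) per frame, with every
#' present joint drawn as a filled disk of its palette color on a black
#' background. Useful for exercising the full render -> detect -> measure
#' round trip without any real video.
#'
#' @param seq A [landmark_sequence()].
#' @param palette A [marker_palette()]; only joints in the palette are
#'   drawn.
#' @param radius Disk radius in pixels (default 5).
#' @param style `"dots"` (default) or `"stick"`, which additionally draws
#'   neutral-colored segments along upper arm, forearm and trunk.
#' @return List of image arrays, one per frame.
#' @export
render_motion <- function(seq, palette = marker_palette(), radius = 5,
                          style = c("dots", "stick")) {
  stopifnot(inherits(seq, "landmark_sequence"))
  style <- match.arg(style)
  h <- seq$height; w <- seq$width
  lapply(seq_len(seq$n_frames) - 1L, function(f) {
    canvas <- array(0, dim = c(h, w, 3))
    lms <- frame_landmarks(seq, f)
    oob <- vapply(lms, function(p) {
      p$x < 0 || p$y < 0 || p$x > w || p$y > h
    }, logical(1))
    if (any(oob)) {
      warning(sprintf("frame %d: landmark(s) outside canvas clipped: %s",
                      f, paste(names(lms)[oob], collapse = ", ")),
              call. = FALSE)
    }
    if (style == "stick") {
      for (side in c("left", "right")) {
        segs <- list(c("shoulder", "elbow"), c("elbow", "wrist"),
                     c("shoulder", "hip"))
        for (sg in segs) {
          a <- lms[[paste(side, sg[1], sep = "_")]]
          b <- lms[[paste(side, sg[2], sep = "_")]]
          if (!is.null(a) && !is.null(b)) {
            canvas <- draw_segment(canvas, c(a$x, a$y), c(b$x, b$y),
                                   thickness = 3, color = .stick_color)
          }
        }
      }
    }
    for (jn in names(lms)) {
      if (!jn %in% rownames(palette$colors)) next
      canvas <- draw_disk(canvas, lms[[jn]]$x, lms[[jn]]$y, radius,
                          palette$colors[jn, ])
    }
    canvas
  })
}

#' Write rendered frames as a PNG series
#'
#' @param frames List of H x W x 3 arrays (0-255) from [render_motion()].
#' @param dir Output directory (created if needed). Files are named
#'   `frame_000000.png`, `frame_000001.png`, ...
#' @return Invisibly, the vector of file paths.
#' @export
write_png_frames <- function(frames, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    rom_io_error(sprintf("cannot create directory %s", dir))
  }
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_along(frames) - 1L))
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]] / 255, paths[i])
  }
  invisible(paths)
}
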