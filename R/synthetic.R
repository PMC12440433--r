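# Ground-truthed synthetic planar arm motion.
#
# The generator realizes the planarity assumption under which the angle
# formulas are exact: a two-segment arm (upper arm + forearm) attached to
# a fixed trunk, moving in the image plane. For shoulder tasks the whole
# (straight) arm rotates about the shoulder from the side of the trunk up
# to the configured peak angle and back; for elbow flexion the upper arm
# hangs fixed and the forearm rotates so flexion runs 0 -> peak -> 0.
# Landmark noise is modelled as i.i.d. Gaussian pixel jitter plus
# whole-frame dropout of the moving arm's landmarks, mimicking how pose
# models typically fail (losing the limb, not one joint).

#' Configuration for a synthetic motion sequence
#'
#' Defaults place the shoulder at (240, 160) on a 480x480 px canvas with an
#' 80 px upper arm, 70 px forearm and 120 px trunk -- pixel proportions
#' roughly matching a subject filmed from six feet by a shoulder-height
#' camera.
#'
#' @param task One of [motion_tasks()].
#' @param side `"left"` or `"right"` (moving side).
#' @param peak_angle Peak task angle in degrees, in `(0, 180]`. Attained
#'   exactly at the trajectory apex frame.
#' @param n_frames Number of frames (>= 2).
#' @param fps Frame rate (frames/second).
#' @param trajectory `"raised-cosine"` (smooth, unique apex; default) or
#'   `"linear-ramp"` (triangular).
#' @param upper_arm_len,forearm_len,trunk_len Segment lengths in pixels.
#' @param shoulder_pos Shoulder position `(x, y)` in pixels.
#' @param width,height Canvas size in pixels.
#' @param jitter_sd Standard deviation of i.i.d. Gaussian landmark jitter
#'   (pixels, >= 0).
#' @param dropout_prob Per-frame probability that the moving arm's
#'   landmarks (shoulder, elbow, wrist of the moving side) are dropped.
#' @param confidence_model `"constant"` (all confidences 1) or
#'   `"distance-decay"` (confidence decays exponentially with a landmark's
#'   distance from the shoulder, scale = arm length).
#' @param seed Integer seed; the generator draws from its own RNG stream
#'   and restores the caller's RNG state.
#' @return A `motion_config` list.
#' @export
motion_config <- function(task = "shoulder_abduction",
                          side = c("right", "left"),
                          peak_angle = 90, n_frames = 61L, fps = 30,
                          trajectory = c("raised-cosine", "linear-ramp"),
                          upper_arm_len = 80, forearm_len = 70,
                          trunk_len = 120, shoulder_pos = c(240, 160),
                          width = 480L, height = 480L,
                          jitter_sd = 0, dropout_prob = 0,
                          confidence_model = c("constant", "distance-decay"),
                          seed = 1L) {
  task <- match_task(task)
  side <- match.arg(side)
  trajectory <- match.arg(trajectory)
  confidence_model <- match.arg(confidence_model)
  if (!is.numeric(peak_angle) || peak_angle <= 0 || peak_angle > 180) {
    rom_config_error("peak_angle must lie in (0, 180] degrees")
  }
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) {
    rom_config_error("n_frames must be an integer >= 2")
  }
  if (fps <= 0) rom_config_error("fps must be positive")
  if (min(upper_arm_len, forearm_len, trunk_len) <= 0) {
    rom_config_error("segment lengths must be positive")
  }
  if (jitter_sd < 0) rom_config_error("jitter_sd must be >= 0")
  if (dropout_prob < 0 || dropout_prob > 1) {
    rom_config_error("dropout_prob must lie in [0, 1]")
  }
  structure(list(
    task = task, side = side, peak_angle = peak_angle,
    n_frames = n_frames, fps = fps, trajectory = trajectory,
    upper_arm_len = upper_arm_len, forearm_len = forearm_len,
    trunk_len = trunk_len, shoulder_pos = shoulder_pos,
    width = as.integer(width), height = as.integer(height),
    jitter_sd = jitter_sd, dropout_prob = dropout_prob,
    confidence_model = confidence_model, seed = as.integer(seed)
  ), class = "motion_config")
}

# Angular trajectory over n frames, rescaled so that the configured peak
# is attained exactly at the apex frame regardless of grid parity. The
# apex is the central frame (earlier of the two central frames on even
# grids, where the symmetric partner can tie only to within clipping);
# all other frames are capped at the peak so the apex is always maximal.
trajectory_profile <- function(n, peak, trajectory) {
  u <- seq(0, 1, length.out = n)
  h <- switch(trajectory,
    "raised-cosine" = (1 - cos(2 * pi * u)) / 2,
    "linear-ramp" = 1 - abs(2 * u - 1))
  apex <- (n - 1L) %/% 2L + 1L
  theta <- pmin(peak * h / h[apex], peak)
  theta[apex] <- peak
  list(theta = theta, apex_frame = apex - 1L)
}

#' Generate a synthetic planar arm-motion sequence
#'
#' @param config A [motion_config()].
#' @return A list of class `synthetic_motion` with elements:
#'   \describe{
#'     \item{sequence}{A [landmark_sequence()] (with jitter/dropout
#'       applied when configured).}
#'     \item{truth}{Ground truth: `config`, `true_angle_series` (the
#'       noise-free task angle per frame, degrees), `true_max`
#'       (= `peak_angle`) and `apex_frame` (0-based frame attaining it).}
#'   }
#' @export
#' @examples
#' sim <- simulate_motion(motion_config(peak_angle = 120, seed = 7))
#' sim$truth$true_max
simulate_motion <- function(config) {
  stopifnot(inherits(config, "motion_config"))
  cf <- config
  prof <- trajectory_profile(cf$n_frames, cf$peak_angle, cf$trajectory)
  theta <- prof$theta
  n <- cf$n_frames
  sx <- cf$shoulder_pos[1]; sy <- cf$shoulder_pos[2]
  lat <- if (cf$side == "right") 1 else -1
  hip <- c(sx, sy + cf$trunk_len)
  rad <- theta * pi / 180

  if (cf$task == "elbow_flexion") {
    # upper arm hangs straight down, forearm rotates; flexion = theta
    ex <- rep(sx, n); ey <- rep(sy + cf$upper_arm_len, n)
    wx <- ex + cf$forearm_len * sin(rad) * lat
    wy <- ey + cf$forearm_len * cos(rad)
  } else {
    # straight arm rotates about shoulder, measured against the trunk
    ex <- sx + cf$upper_arm_len * sin(rad) * lat
    ey <- sy + cf$upper_arm_len * cos(rad)
    reach <- cf$upper_arm_len + cf$forearm_len
    wx <- sx + reach * sin(rad) * lat
    wy <- sy + reach * cos(rad)
  }

  side_joint <- function(j) paste(cf$side, j, sep = "_")
  frames <- rep(seq_len(n) - 1L, times = 4)
  df <- data.frame(
    frame = frames,
    joint = rep(side_joint(c("shoulder", "elbow", "wrist", "hip")),
                each = n),
    x = c(rep(sx, n), ex, wx, rep(hip[1], n)),
    y = c(rep(sy, n), ey, wy, rep(hip[2], n)),
    stringsAsFactors = FALSE)

  # private RNG stream: caller's state restored afterwards
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(cf$seed)

  if (cf$jitter_sd > 0) {
    df$x <- df$x + stats::rnorm(nrow(df), 0, cf$jitter_sd)
    df$y <- df$y + stats::rnorm(nrow(df), 0, cf$jitter_sd)
  }
  df$confidence <- if (cf$confidence_model == "constant") {
    1.0
  } else {
    d <- sqrt((df$x - sx)^2 + (df$y - sy)^2)
    exp(-d / (cf$upper_arm_len + cf$forearm_len))
  }
  if (cf$dropout_prob > 0) {
    dropped_frames <- which(stats::runif(n) < cf$dropout_prob) - 1L
    arm <- side_joint(c("shoulder", "elbow", "wrist"))
    keep <- !(df$frame %in% dropped_frames & df$joint %in% arm)
    df <- df[keep, , drop = FALSE]
  }

  seqn <- landmark_sequence(
    df, fps = cf$fps, width = cf$width, height = cf$height,
    source = sprintf("synthetic:%s:%s:seed%d", cf$task, cf$side, cf$seed),
    n_frames = n)
  structure(list(
    sequence = seqn,
    truth = list(config = cf, true_angle_series = theta,
                 true_max = cf$peak_angle, apex_frame = prof$apex_frame)
  ), class = "synthetic_motion")
}

#' @export
print.synthetic_motion <- function(x, ...) {
  cf <- x$truth$config
  cat(sprintf(
    "synthetic_motion: %s (%s), peak %.1f deg at frame %d, %d frames\n",
    cf$task, cf$side, x$truth$true_max, x$truth$apex_frame, cf$n_frames))
  cat(sprintf("jitter_sd=%.2g px, dropout_prob=%.2g, seed=%d\n",
              cf$jitter_sd, cf$dropout_prob, cf$seed))
  invisible(x)
}
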