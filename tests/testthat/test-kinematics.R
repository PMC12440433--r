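test_that("angle_between handles canonical geometries", {
  expect_equal(angle_between(c(1, 0), c(0, 1)), 90)
  expect_equal(angle_between(c(1, 0), c(2, 0)), 0)
  expect_equal(angle_between(c(1, 0), c(-3, 0)), 180)
  expect_equal(angle_between(c(2, 1), c(-1, 3)),
               arccos_angle(c(2, 1), c(-1, 3)), tolerance = 1e-10)
  expect_error(angle_between(c(0, 0), c(1, 0)),
               class = "rom_degenerate_error")
  expect_error(angle_between(c(1, NA), c(1, 0)),
               class = "rom_input_error")
})

test_that("angle_between matches the arccos oracle and is invariant under
           rotation, translation handling, scaling and mirroring", {
  set.seed(42)
  n <- 2000
  for (i in seq_len(n)) {
    ba <- rnorm(2); bc <- rnorm(2)
    if (sqrt(sum(ba^2)) < 1e-3 || sqrt(sum(bc^2)) < 1e-3) next
    a <- angle_between(ba, bc)
    expect_true(a >= 0 && a <= 180)
    expect_equal(a, arccos_angle(ba, bc), tolerance = 1e-9)
    # symmetry
    expect_equal(a, angle_between(bc, ba), tolerance = 1e-12)
    # rotation
    phi <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    expect_equal(a, angle_between(drop(R %*% ba), drop(R %*% bc)),
                 tolerance = 1e-9)
    # uniform scaling
    s <- runif(1, 0.1, 10)
    expect_equal(a, angle_between(s * ba, s * bc), tolerance = 1e-9)
    # mirror reflection (x -> -x)
    expect_equal(a, angle_between(ba * c(-1, 1), bc * c(-1, 1)),
                 tolerance = 1e-9)
  }
})

test_that("task_angle reproduces hand-computed poses", {
  # arm hanging at the side: abduction 0
  lms <- list(right_shoulder = list(x = 100, y = 100, confidence = 1),
              right_elbow = list(x = 100, y = 140, confidence = 1),
              right_hip = list(x = 100, y = 200, confidence = 1))
  s <- task_angle(lms, "shoulder_abduction", "right")
  expect_equal(s$invalid_reason, "none")
  expect_equal(s$angle, 0)

  # elbow at full extension: supplement maps raw 180 to 0
  lme <- list(right_wrist = list(x = 100, y = 180, confidence = 1),
              right_elbow = list(x = 100, y = 140, confidence = 1),
              right_shoulder = list(x = 100, y = 100, confidence = 1))
  expect_equal(task_angle(lme, "elbow_flexion", "right")$angle, 0)
  lme$right_wrist <- list(x = 140, y = 140, confidence = 1)
  expect_equal(task_angle(lme, "elbow_flexion", "right")$angle, 90)

  # shoulder flexion against the arccos oracle: BA=(30,-40), BC=(-2,90)
  lmf <- list(right_shoulder = list(x = 100, y = 100, confidence = 1),
              right_elbow = list(x = 130, y = 60, confidence = 1),
              right_hip = list(x = 98, y = 190, confidence = 1))
  expect_equal(task_angle(lmf, "shoulder_flexion", "right")$angle,
               arccos_angle(c(30, -40), c(-2, 90)), tolerance = 1e-9)
  expect_equal(task_angle(lmf, "shoulder_flexion", "right")$angle,
               144.4, tolerance = 0.05)
})

test_that("task_angle reports invalidity as data, not errors", {
  lms <- list(right_shoulder = list(x = 0, y = 0, confidence = 1),
              right_hip = list(x = 0, y = 10, confidence = 1))
  s <- task_angle(lms, "shoulder_abduction", "right")
  expect_true(is.na(s$angle))
  expect_equal(s$invalid_reason, "absent-landmark")

  lms$right_elbow <- list(x = 5, y = 5, confidence = 0.05)
  s <- task_angle(lms, "shoulder_abduction", "right",
                  confidence_threshold = 0.1)
  expect_equal(s$invalid_reason, "low-confidence")
  # threshold 0 disables the check
  s <- task_angle(lms, "shoulder_abduction", "right",
                  confidence_threshold = 0)
  expect_equal(s$invalid_reason, "none")

  lms$right_elbow <- list(x = 0, y = 0, confidence = 1)  # coincides w/ vertex
  s <- task_angle(lms, "shoulder_abduction", "right")
  expect_equal(s$invalid_reason, "degenerate-geometry")
})

test_that("compute_series is frame-local and preserves order", {
  seq <- tiny_sequence(n = 3)
  # knock the elbow out of frame 1
  lm <- seq$landmarks[!(seq$landmarks$frame == 1 &
                        seq$landmarks$joint == "right_elbow"), ]
  seq2 <- landmark_sequence(lm, fps = 30, width = 200, height = 200,
                            n_frames = 3L)
  series <- compute_series(seq2, "shoulder_abduction", "right")
  expect_equal(nrow(series), 3)
  expect_equal(series$frame, 0:2)
  expect_equal(series$invalid_reason,
               c("none", "absent-landmark", "none"))
  full <- compute_series(seq, "shoulder_abduction", "right")
  expect_equal(series$angle_deg[c(1, 3)], full$angle_deg[c(1, 3)])
})

test_that("median smoothing replaces isolated spikes, leaves invalids alone", {
  mk_seq <- function(angles) {
    # elbow placed so the abduction angle equals `angles` exactly
    rows <- do.call(rbind, lapply(seq_along(angles) - 1L, function(f) {
      th <- angles[f + 1] * pi / 180
      data.frame(frame = f,
                 joint = c("right_shoulder", "right_elbow", "right_hip"),
                 x = c(100, 100 + 50 * sin(th), 100),
                 y = c(100, 100 + 50 * cos(th), 200),
                 confidence = 1)
    }))
    landmark_sequence(rows, fps = 30, width = 300, height = 300)
  }
  seq <- mk_seq(c(10, 80, 12))
  raw <- compute_series(seq, "shoulder_abduction", "right")
  expect_equal(raw$angle_deg, c(10, 80, 12), tolerance = 1e-9)
  sm <- compute_series(seq, "shoulder_abduction", "right",
                       smoothing = "median", window = 3)
  expect_equal(sm$angle_deg, c(10, 12, 12), tolerance = 1e-9)
  expect_error(compute_series(seq, "shoulder_abduction", "right",
                              smoothing = "median", window = 2),
               class = "rom_input_error")
})

test_that("max_rom takes the earliest maximal frame and validates counts", {
  df <- data.frame(frame = 0:2, time_s = (0:2) / 30,
                   angle_deg = c(10, 45, 30),
                   invalid_reason = "none")
  series <- romkin:::new_angle_series(df, "shoulder_abduction", "right",
                                      30, "t")
  r <- max_rom(series)
  expect_equal(r$max_angle, 45)
  expect_equal(r$argmax_frame, 1L)
  expect_equal(r$n_valid_frames, 3L)

  df$angle_deg <- c(30, 45, 45)
  series <- romkin:::new_angle_series(df, "shoulder_abduction", "right",
                                      30, "t")
  expect_equal(max_rom(series)$argmax_frame, 1L)

  df$angle_deg <- NA_real_
  df$invalid_reason <- "absent-landmark"
  series <- romkin:::new_angle_series(df, "shoulder_abduction", "right",
                                      30, "t")
  expect_error(max_rom(series), class = "rom_insufficient_data_error")
})

test_that("max_rom dominates every valid sample and ignores non-argmax frames", {
  sim <- simulate_motion(motion_config(peak_angle = 130, jitter_sd = 1.2,
                                       seed = 9))
  series <- compute_series(sim$sequence, "shoulder_abduction", "right")
  r <- max_rom(series)
  valid <- series$invalid_reason == "none"
  expect_true(all(r$max_angle >= series$angle_deg[valid]))
  # removing any non-argmax frame leaves the result unchanged
  for (drop_frame in setdiff(series$frame[valid], r$argmax_frame)[1:5]) {
    sub <- series[series$frame != drop_frame, ]
    sub2 <- romkin:::new_angle_series(sub, "shoulder_abduction", "right",
                                      30, "t")
    expect_equal(max_rom(sub2)$max_angle, r$max_angle)
  }
})

test_that("measure composes the pipeline deterministically", {
  sim <- simulate_motion(motion_config(peak_angle = 90, seed = 2))
  m1 <- measure(sim$sequence, "shoulder_abduction", "right")
  m2 <- measure(sim$sequence, "shoulder_abduction", "right")
  expect_identical(m1$rom, m2$rom)
  expect_equal(m1$rom$max_angle, 90, tolerance = 1e-6)
  expect_s3_class(m1, "rom_measurement")
  expect_s3_class(m1$series, "angle_series")

  # path input
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_csv(sim$sequence, path)
  m3 <- measure(path, "shoulder_abduction", "right")
  expect_equal(m3$rom$max_angle, m1$rom$max_angle, tolerance = 1e-6)
})

test_that("measure warns when most frames are invalid", {
  sim <- simulate_motion(motion_config(peak_angle = 90, dropout_prob = 0.9,
                                       n_frames = 80, seed = 14))
  expect_warning(measure(sim$sequence, "shoulder_abduction", "right"),
                 "valid")
})
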