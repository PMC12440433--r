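# Shared fixture builders: everything is generated in code at test time.

# Small hand-built landmark sequence: n frames of an arm raising on a
# 200x200 canvas.
tiny_sequence <- function(n = 3, fps = 30) {
  rows <- do.call(rbind, lapply(seq_len(n) - 1L, function(f) {
    data.frame(
      frame = f,
      joint = c("right_shoulder", "right_elbow", "right_hip"),
      x = c(100, 100 + 10 * f, 100),
      y = c(100, 140, 180),
      confidence = c(0.9, 0.8, NA))
  }))
  landmark_sequence(rows, fps = fps, width = 200, height = 200,
                    source = "tiny")
}

# Independent angle oracle: arccos of the normalized dot product.
arccos_angle <- function(ba, bc) {
  cosang <- sum(ba * bc) / (sqrt(sum(ba^2)) * sqrt(sum(bc^2)))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Independent ICC(2,1) oracle via R's ANOVA fit (distinct route from the
# package's direct sums-of-squares implementation).
icc_agreement_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(lm(value ~ subject + rater, data = df))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Draw a random complete rater matrix with subject and rater effects.
random_rater_matrix <- function(n, k, subject_sd = 15, rater_sd = 4,
                                noise_sd = 3) {
  subj <- rnorm(n, 100, subject_sd)
  rat <- rnorm(k, 0, rater_sd)
  outer(subj, rat, "+") + matrix(rnorm(n * k, 0, noise_sd), n, k)
}
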