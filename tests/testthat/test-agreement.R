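test_that("mean_difference handles both modes with hand-checked values", {
  expect_equal(mean_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_difference(c(10, 20), c(12, 16), "absolute"), 3.0)
  expect_equal(mean_difference(c(10, 20), c(12, 16), "signed"), 1.0)
  expect_error(mean_difference(1:3, 1:2), class = "rom_input_error")
})

test_that("absolute mean difference dominates the signed magnitude", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(8, 100, 20); y <- rnorm(8, 100, 20)
    expect_gte(mean_difference(x, y, "absolute"),
               abs(mean_difference(x, y, "signed")))
  }
})

test_that("pearson_cc matches the textbook formula and edge cases", {
  x <- c(1, 5, 9)
  expect_equal(pearson_cc(x, 2 * x + 1), 1.0)
  expect_equal(pearson_cc(x, -x), -1.0)
  expect_equal(pearson_cc(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(pearson_cc(c(1, 1, 1), c(1, 2, 3)),
               class = "rom_undefined_stat_error")
  expect_error(pearson_cc(c(1, 2), c(1, 2)), class = "rom_input_error")
})

test_that("two-way random ICC matches the independent ANOVA oracle", {
  # fixed small integer matrix
  m <- matrix(c(9, 2, 5, 8, 6, 1, 6, 1, 3, 2, 8, 4, 8, 4, 6, 8, 9, 5),
              nrow = 6, ncol = 3)
  expect_equal(icc_two_way(m), icc_agreement_oracle(m), tolerance = 1e-10)

  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:12, 1); k <- sample(2:8, 1)
    m <- random_rater_matrix(n, k)
    expect_equal(icc_two_way(m, "agreement", "single"),
                 icc_agreement_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC limiting and ordering behaviors hold", {
  base <- c(80, 100, 120, 140)
  # identical rater columns, nonconstant across subjects -> 1
  expect_equal(icc_two_way(cbind(base, base, base)), 1.0)
  # constant rater offset: consistency ignores the bias, agreement cannot
  shifted <- cbind(base, base + 10)
  expect_gt(icc_two_way(shifted, "consistency"),
            icc_two_way(shifted, "agreement"))
  expect_equal(icc_two_way(shifted, "consistency"), 1.0)
  # average-measure reliability is at least single-measure reliability
  set.seed(5)
  m <- random_rater_matrix(8, 4)
  expect_gte(icc_two_way(m, "agreement", "average"),
             icc_two_way(m, "agreement", "single"))
  expect_error(icc_two_way(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "rom_input_error")
  expect_error(icc_two_way(matrix(1:3, 3, 1)), class = "rom_input_error")
})

test_that("ICC interpretation bands are total over (-Inf, 1]", {
  expect_equal(interpret_icc(0.85), "excellent")
  expect_equal(interpret_icc(0.50), "good")
  expect_equal(interpret_icc(0.805), "excellent")  # gap value
  expect_equal(interpret_icc(0.70), "very good")
  expect_equal(interpret_icc(0.30), "questionable")
  expect_equal(interpret_icc(-0.4), "unacceptable")
  labels <- c("unacceptable", "questionable", "good", "very good",
              "excellent")
  for (v in seq(-1, 1, by = 0.01)) {
    expect_true(interpret_icc(v) %in% labels)
  }
  expect_error(interpret_icc(1.2), class = "rom_input_error")
})

test_that("mean CV uses sample sd per subject and its bands label correctly", {
  expect_equal(mean_cv(matrix(c(90, 100, 110), 1, 3)), 10.0)
  expect_equal(mean_cv(cbind(c(100, 50), c(100, 50))), 0)
  expect_error(mean_cv(cbind(c(0, 1), c(0, -1))),
               class = "rom_undefined_stat_error")
  expect_equal(interpret_cv(4.097), "low variability")
  expect_equal(interpret_cv(14.97), "moderate variability")
  expect_equal(interpret_cv(25), "high variability")
})

test_that("regression R2 equals squared Pearson correlation", {
  x <- c(1, 4, 6, 9)
  expect_equal(regression_r2(x, 3 * x - 2), 1.0)
  expect_equal(regression_r2(x, rep(5, 4)), 0.0)
  set.seed(21)
  for (i in 1:30) {
    x <- rnorm(10); y <- rnorm(10) + 0.5 * x
    expect_equal(regression_r2(x, y), pearson_cc(x, y)^2,
                 tolerance = 1e-12)
  }
  expect_error(regression_r2(rep(1, 4), 1:4), class = "rom_input_error")
})

test_that("paired t test matches an independently coded t distribution", {
  expect_error(paired_t_test(1:4, 1:4), class = "rom_degenerate_error")

  # differences symmetric about zero
  tt <- paired_t_test(c(9, 11), c(10, 10))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  x <- c(95, 102, 88, 110, 97, 105, 92, 100)
  y <- c(90, 104, 85, 103, 95, 99, 94, 96)
  tt <- paired_t_test(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(d) - 1)
  expect_equal(tt$t, t_hand, tolerance = 1e-9)
  expect_equal(tt$p, p_hand, tolerance = 1e-9)
  expect_equal(tt$df, 7)
})

test_that("power-based sample size reproduces the closed form and monotonicity", {
  expect_equal(power_sample_size(5, 9, 0.05, 0.85), 30L)
  # z_power = 0 boundary: with power = 0.5 and delta = z_{1-a/2} * sd the
  # closed form collapses to n = 1
  expect_equal(power_sample_size(1.959964 * 9, 9, 0.05, 0.5), 1L)
  # the exact t-based calculation is more conservative
  expect_gte(power_sample_size(5, 9, 0.05, 0.85, method = "t"), 30L)

  n_base <- power_sample_size(5, 9, 0.05, 0.85)
  expect_lte(power_sample_size(8, 9, 0.05, 0.85), n_base)   # larger delta
  expect_gte(power_sample_size(5, 14, 0.05, 0.85), n_base)  # larger sd
  expect_gte(power_sample_size(5, 9, 0.05, 0.95), n_base)   # more power
  expect_gte(power_sample_size(5, 9, 0.01, 0.85), n_base)   # stricter alpha
  # monotone nondecreasing along an sd sweep
  ns <- sapply(seq(4, 20, by = 2),
               function(s) power_sample_size(5, s, 0.05, 0.85))
  expect_true(all(diff(ns) >= 0))
  expect_error(power_sample_size(-1, 9), class = "rom_input_error")
  expect_error(power_sample_size(5, 9, alpha = 1.2),
               class = "rom_input_error")
})

test_that("consensus averages raters and commutes with signed differences", {
  m <- rbind(s1 = c(100, 110), s2 = c(80, 90))
  expect_equal(unname(consensus(m)), c(105, 85))
  expect_equal(consensus(m[, 1, drop = FALSE]), m[, 1])

  set.seed(31)
  m <- random_rater_matrix(6, 4)
  ref <- rnorm(6, 100, 15)
  per_rater <- mean(sapply(1:4, function(j) {
    mean_difference(m[, j], ref, "signed")
  }))
  expect_equal(mean_difference(consensus(m), ref, "signed"), per_rater,
               tolerance = 1e-12)
  # the same identity fails for absolute differences in general
  per_rater_abs <- mean(sapply(1:4, function(j) {
    mean_difference(m[, j], ref, "absolute")
  }))
  expect_gte(per_rater_abs, mean_difference(consensus(m), ref, "absolute"))
})

test_that("agreement and reliability reports assemble consistent fields", {
  set.seed(41)
  truth <- rnorm(8, 100, 25)
  x <- truth + rnorm(8, 0, 4)
  y <- truth + rnorm(8, 0, 4)
  rep <- agreement_report(x, y, label = "method A vs benchmark")
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$icc_label, interpret_icc(rep$icc))
  expect_equal(rep$r_squared, rep$pearson_r^2, tolerance = 1e-12)
  expect_gte(rep$mean_difference, abs(rep$mean_difference_signed))
  expect_output(print(rep), "Pearson r")

  m <- random_rater_matrix(8, 8)
  rel <- reliability_report(m)
  expect_equal(rel$icc_label, interpret_icc(rel$intraclass_cc))
  expect_equal(rel$cv_label, interpret_cv(rel$mean_cv_percent))
  expect_gte(rel$mean_cv_percent, 0)
})
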