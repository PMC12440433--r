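# Method-agreement and rater-reliability statistics for ROM validation
# studies: mean difference against a benchmark, Pearson correlation,
# two-way random-effects intraclass correlation with its interpretation
# bands, per-subject coefficient of variation, simple-regression R^2,
# paired t tests, and a paired-design power/sample-size calculation.
# All dispersion statistics use the sample (n - 1) convention.

check_paired <- function(x, y, min_len = 1L) {
  if (!is.numeric(x) || !is.numeric(y)) {
    rom_input_error("inputs must be numeric vectors")
  }
  if (length(x) != length(y)) {
    rom_input_error("paired vectors must have equal length")
  }
  if (length(x) < min_len) {
    rom_input_error(sprintf("need at least %d paired observations", min_len))
  }
}

#' Mean difference between two paired measurement methods
#'
#' The per-subject differences `x - y` are averaged either as magnitudes
#' (`mode = "absolute"`, the default: mean of `|x_i - y_i|`) or signed
#' (`mode = "signed"`: mean of `x_i - y_i`, positive when `x` reads
#' higher). The absolute mode always dominates the magnitude of the
#' signed mode.
#'
#' @param x,y Numeric vectors of paired measurements (degrees).
#' @param mode `"absolute"` or `"signed"`.
#' @return Mean difference in degrees.
#' @export
mean_difference <- function(x, y, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  check_paired(x, y, 1L)
  d <- x - y
  if (mode == "absolute") mean(abs(d)) else mean(d)
}

#' Pearson correlation between two measurement series
#'
#' @param x,y Numeric vectors (length >= 3, both nonconstant).
#' @return Sample Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  check_paired(x, y, 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rom_undefined_stat_error("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

two_way_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Two-way random-effects intraclass correlation
#'
#' ICC under the two-way random-effects model, computed from the ANOVA
#' mean squares of the subjects-by-raters table (`MSR` between subjects,
#' `MSC` between raters, `MSE` residual). The default form is absolute
#' agreement for a single measurement, ICC(2,1):
#' \deqn{\frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)}}
#' Consistency and average-measurement variants follow the standard
#' two-way-random formulas. The same function serves as an interclass
#' correlation between two methods by passing a 2-column subjects-by-
#' methods matrix.
#'
#' @param m Numeric matrix, subjects in rows (n >= 2), raters/methods in
#'   columns (k >= 2), no missing cells.
#' @param form `"agreement"` (absolute agreement; default) or
#'   `"consistency"`.
#' @param unit `"single"` (default) or `"average"` (reliability of the
#'   mean of the k raters).
#' @return The ICC estimate (<= 1).
#' @export
#' @examples
#' m <- cbind(a = c(80, 100, 120), b = c(82, 101, 118))
#' icc_two_way(m)
icc_two_way <- function(m, form = c("agreement", "consistency"),
                        unit = c("single", "average")) {
  form <- match.arg(form)
  unit <- match.arg(unit)
  if (!is.matrix(m)) m <- as.matrix(m)
  if (!is.numeric(m) || anyNA(m)) {
    rom_input_error("rater matrix must be numeric and complete (no missing cells)")
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    rom_input_error("ICC needs at least 2 subjects and 2 raters")
  }
  ms <- two_way_mean_squares(m)
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  n <- ms$n; k <- ms$k
  if (form == "agreement") {
    if (unit == "single") {
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    } else {
      (msr - mse) / (msr + (msc - mse) / n)
    }
  } else {
    if (unit == "single") {
      (msr - mse) / (msr + (k - 1) * mse)
    } else {
      (msr - mse) / msr
    }
  }
}

#' Interpretation label for an ICC value
#'
#' Clinical interpretation bands: below 0.20 unacceptable, 0.20 to 0.40
#' questionable, 0.40 to 0.60 good, 0.60 to 0.80 very good, 0.80 and
#' above excellent. The printed cutoff lists leave gaps between bands
#' (e.g. 0.40 vs 0.41); these are closed with half-open intervals at the
#' lower printed cutoff so every value up to 1 receives exactly one
#' label.
#'
#' @param icc ICC value (<= 1; two-way-random ICCs can be negative).
#' @return One of `"unacceptable"`, `"questionable"`, `"good"`,
#'   `"very good"`, `"excellent"`.
#' @export
interpret_icc <- function(icc) {
  if (!is.numeric(icc) || length(icc) != 1 || is.na(icc) || icc > 1) {
    rom_input_error("icc must be a single number <= 1")
  }
  if (icc < 0.20) "unacceptable"
  else if (icc < 0.40) "questionable"
  else if (icc < 0.60) "good"
  else if (icc < 0.80) "very good"
  else "excellent"
}

#' Mean coefficient of variation across subjects
#'
#' For each subject (row), CV = 100 * sd / mean across raters, with the
#' sample (n-1) standard deviation; the per-subject CVs are averaged.
#'
#' @param m Numeric subjects-by-raters matrix (>= 2 raters), no missing
#'   cells, no zero subject means.
#' @return Mean CV in percent.
#' @export
mean_cv <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (anyNA(m)) rom_input_error("rater matrix must be complete")
  if (ncol(m) < 2) rom_input_error("CV needs at least 2 raters")
  means <- rowMeans(m)
  if (any(means == 0)) {
    rom_undefined_stat_error("coefficient of variation undefined: a subject mean is zero")
  }
  cvs <- 100 * apply(m, 1, stats::sd) / means
  mean(cvs)
}

#' Interpretation label for a mean coefficient of variation
#'
#' Below 10% low variability, 10 to 20% moderate, 20% and above high.
#'
#' @param cv Mean CV in percent (>= 0).
#' @return One of `"low variability"`, `"moderate variability"`,
#'   `"high variability"`.
#' @export
interpret_cv <- function(cv) {
  if (!is.numeric(cv) || length(cv) != 1 || is.na(cv) || cv < 0) {
    rom_input_error("cv must be a single non-negative number")
  }
  if (cv < 10) "low variability"
  else if (cv < 20) "moderate variability"
  else "high variability"
}

#' R-squared of a simple linear regression
#'
#' Ordinary least squares of `y` on `x`; returns
#' `R^2 = 1 - SSE / SST`. A constant response has no variance to explain
#' and returns 0.
#'
#' @param x Predictor (length >= 3, nonconstant).
#' @param y Response.
#' @return R-squared in `[0, 1]`.
#' @export
regression_r2 <- function(x, y) {
  check_paired(x, y, 3L)
  if (stats::sd(x) == 0) {
    rom_input_error("regression undefined for constant predictor")
  }
  if (stats::sd(y) == 0) return(0)
  fit <- stats::lm(y ~ x)
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Two-sided paired t test
#'
#' Student t test on the paired differences `x - y`.
#'
#' @param x,y Paired numeric vectors (length >= 2); the differences must
#'   not be constant.
#' @return List with `t` (statistic), `p` (two-sided p-value), `df`.
#' @export
paired_t_test <- function(x, y) {
  check_paired(x, y, 2L)
  d <- x - y
  if (stats::sd(d) == 0) {
    rom_degenerate_error("paired differences have zero variance; t test undefined")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Sample size for detecting a mean paired difference
#'
#' Normal-approximation sample size for a two-sided paired test:
#' \deqn{n = \lceil ((z_{1-\alpha/2} + z_{power}) \; \sigma_d / \delta)^2 \rceil}
#' where `delta` is the mean paired difference to detect and `sd` the
#' standard deviation of the paired differences. With the default
#' parameters (delta 5 degrees, sd 9 degrees, alpha 0.05, power 0.85)
#' this gives n = 30. `method = "t"` instead iterates the noncentral-t
#' calculation (via [stats::power.t.test()]), which is slightly more
#' conservative (31-32 for the defaults).
#'
#' @param delta Mean paired difference to detect (> 0), degrees.
#' @param sd Standard deviation of paired differences (> 0), degrees.
#' @param alpha Two-sided type-I error rate, in (0, 1).
#' @param power Target power, in `[0.5, 1)`.
#' @param method `"normal"` (default) or `"t"`.
#' @return Required number of pairs (integer).
#' @export
#' @examples
#' power_sample_size(5, 9, 0.05, 0.85)  # 30
power_sample_size <- function(delta, sd, alpha = 0.05, power = 0.85,
                              method = c("normal", "t")) {
  method <- match.arg(method)
  if (!is.numeric(delta) || delta <= 0) rom_input_error("delta must be > 0")
  if (!is.numeric(sd) || sd <= 0) rom_input_error("sd must be > 0")
  if (alpha <= 0 || alpha >= 1) rom_input_error("alpha must lie in (0, 1)")
  if (power < 0.5 || power >= 1) {
    rom_input_error("power must lie in [0.5, 1)")
  }
  if (method == "normal") {
    z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
    as.integer(ceiling((z * sd / delta)^2))
  } else {
    pt <- stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                              power = power, type = "paired")
    as.integer(ceiling(pt$n))
  }
}

#' Per-subject consensus across raters
#'
#' Averages each subject's measurements across raters into a single
#' consensus value per subject.
#'
#' @param m Numeric subjects-by-raters matrix, no missing cells.
#' @return Named numeric vector of per-subject means.
#' @export
consensus <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (anyNA(m)) rom_input_error("rater matrix must be complete")
  rowMeans(m)
}

#' Agreement report between two measurement methods
#'
#' Bundles the agreement statistics comparing a candidate method `x`
#' against a benchmark `y` on the same subjects: mean difference
#' (absolute and signed), Pearson correlation, interclass correlation
#' (two-way random ICC on the subjects-by-methods matrix) with its
#' interpretation label, regression R-squared, and the paired t test.
#'
#' @param x Candidate method measurements (degrees).
#' @param y Benchmark measurements (degrees), same subjects.
#' @param icc_form,icc_unit Passed to [icc_two_way()].
#' @param label Optional description of the comparison.
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(x, y, icc_form = "agreement",
                             icc_unit = "single", label = "") {
  check_paired(x, y, 3L)
  icc <- icc_two_way(cbind(x = x, y = y), form = icc_form, unit = icc_unit)
  tt <- paired_t_test(x, y)
  structure(list(
    label = label,
    n = length(x),
    mean_difference = mean_difference(x, y, "absolute"),
    mean_difference_signed = mean_difference(x, y, "signed"),
    pearson_r = pearson_cc(x, y),
    icc = icc,
    icc_label = interpret_icc(icc),
    r_squared = regression_r2(x, y),
    t_statistic = tt$t, p_value = tt$p
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  if (nzchar(x$label)) cat(x$label, "\n")
  cat(sprintf("n = %d paired measurements\n", x$n))
  cat(sprintf("mean difference: %.3f deg (signed %.3f deg)\n",
              x$mean_difference, x$mean_difference_signed))
  cat(sprintf("Pearson r: %.3f   ICC: %.3f (%s)   R-squared: %.4f\n",
              x$pearson_r, x$icc, x$icc_label, x$r_squared))
  cat(sprintf("paired t: t = %.3f, p = %.4f\n", x$t_statistic, x$p_value))
  invisible(x)
}

#' Interobserver reliability report for a rater matrix
#'
#' Intraclass correlation (two-way random) across raters plus the mean
#' per-subject coefficient of variation, each with its interpretation
#' label.
#'
#' @param m Numeric subjects-by-raters matrix, no missing cells.
#' @param icc_form,icc_unit Passed to [icc_two_way()].
#' @return A `reliability_report` list with `intraclass_cc`, `icc_label`,
#'   `mean_cv_percent`, `cv_label`.
#' @export
reliability_report <- function(m, icc_form = "agreement",
                               icc_unit = "single") {
  icc <- icc_two_way(m, form = icc_form, unit = icc_unit)
  cv <- mean_cv(m)
  structure(list(
    n_subjects = nrow(as.matrix(m)), k_raters = ncol(as.matrix(m)),
    intraclass_cc = icc, icc_label = interpret_icc(icc),
    mean_cv_percent = cv, cv_label = interpret_cv(cv)
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("%d subjects x %d raters\n", x$n_subjects, x$k_raters))
  cat(sprintf("intraclass CC: %.3f (%s)\n", x$intraclass_cc, x$icc_label))
  cat(sprintf("mean CV: %.3f%% (%s)\n", x$mean_cv_percent, x$cv_label))
  invisible(x)
}
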