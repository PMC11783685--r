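## Test-retest reliability and method-agreement statistics.
##
## Reliability of the repeated app measurements: two-way random-effects
## intraclass correlation, single measure. The default form is ABSOLUTE
## AGREEMENT, ICC(A,1) in McGraw & Wong's nomenclature / ICC(2,1) in
## Shrout & Fleiss's, because the downstream SEM is declared for absolute
## reliability; the consistency variant ICC(C,1) is available for
## sensitivity checks. From the two-way ANOVA mean squares (rows = subjects
## MSR, columns = sessions MSC, residual MSE), with n subjects and k
## sessions:
##
##   ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)
##
## with the F-distribution confidence interval of McGraw & Wong (1996).
## SEM = S * sqrt(1 - ICC) with S the SD of the pooled session scores, and
## MDC = SEM * sqrt(2) * 1.96.

# two-way ANOVA mean squares for an n x k complete table
anova_mean_squares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - k * sum((rm_ - grand)^2) - n * sum((cm_ - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Two-way random-effects intraclass correlation for test-retest data
#'
#' Single-measure ICC from a two-session test-retest design, with its 95%
#' confidence interval from the F-distribution method. The default
#' `type = "agreement"` is ICC(A,1) (equivalently ICC(2,1)), which penalises
#' systematic session offsets; `type = "consistency"` is ICC(C,1).
#'
#' @param session1,session2 Numeric vectors of per-participant scores,
#'   paired by position; length `n >= 3`.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `type`, `n` and the ANOVA
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_two_way_random <- function(session1, session2,
                               type = c("agreement", "consistency"),
                               conf_level = 0.95) {
  type <- match.arg(type)
  if (length(session1) != length(session2)) {
    abort_validation("sessions must be paired: lengths %d vs %d",
                     length(session1), length(session2))
  }
  n <- length(session1)
  if (n < 3) abort_insufficient("ICC needs at least 3 participants, got %d", n)
  x <- cbind(session1, session2)
  if (anyNA(x)) abort_validation("ICC input contains missing values")
  if (all(x == x[1])) abort_domain("zero total variance: ICC undefined")
  ms <- anova_mean_squares(x)
  k <- ms$k
  alpha <- 1 - conf_level

  if (type == "agreement") {
    denom <- ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n
    icc <- (ms$msr - ms$mse) / denom
    # McGraw & Wong F-based interval for ICC(A,1)
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {      # icc == 1: degenerate interval
      ci <- c(1, 1)
    } else {
      v <- (a * ms$msc + b * ms$mse)^2 /
        ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (ms$msr - fl * ms$mse) /
        (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
      hi <- n * (fu * ms$msr - ms$mse) /
        (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
      ci <- c(lo, hi)
    }
  } else {
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    if (ms$mse == 0) {
      ci <- c(1, 1)
    } else {
      f0 <- ms$msr / ms$mse
      fl <- f0 / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- f0 * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  }
  list(icc = unname(icc), ci_low = unname(min(ci, icc)),
       ci_high = unname(max(ci, icc)),
       type = type, n = n, msr = ms$msr, msc = ms$msc, mse = ms$mse)
}

#' Standard error of measurement
#'
#' `SEM = S * sqrt(1 - ICC)` where `S` is by default the sample SD
#' (denominator 2N-1) of the pooled first- and second-session scores;
#' `pooling = "session_mean"` instead averages the two per-session SDs, an
#' alternative reading of "SD of first and second measurement scores".
#'
#' @param scores_both_sessions Numeric vector of all 2N session scores, or a
#'   two-column matrix (sessions in columns).
#' @param icc ICC in `[0, 1]`.
#' @param pooling `"pooled"` (default) or `"session_mean"`.
#' @return SEM in the scores' units (degrees).
#' @export
sem <- function(scores_both_sessions, icc, pooling = c("pooled", "session_mean")) {
  pooling <- match.arg(pooling)
  if (!is.finite(icc) || icc < 0 || icc > 1) {
    abort_domain("icc must be in [0, 1], got %s", format(icc))
  }
  s <- if (pooling == "pooled") {
    stats::sd(as.numeric(scores_both_sessions))
  } else {
    x <- as.matrix(scores_both_sessions)
    mean(apply(x, 2, stats::sd))
  }
  s * sqrt(1 - icc)
}

#' Minimal detectable change
#'
#' `MDC = SEM * sqrt(2) * 1.96`: the smallest change exceeding measurement
#' noise at 95% confidence for a test-retest design.
#'
#' @param sem SEM in degrees, `>= 0`.
#' @return MDC in degrees.
#' @export
mdc <- function(sem) {
  if (!is.numeric(sem) || any(sem < 0)) abort_domain("sem must be >= 0")
  sem * sqrt(2) * 1.96
}

#' Landis-Koch classification of an ICC
#'
#' Bands (lower bound inclusive): 0.81-1.00 almost perfect, 0.61-0.80
#' substantial, 0.41-0.60 moderate, 0.21-0.40 fair, 0-0.20 slight. A
#' negative ICC is classified `"slight"` with a warning (the scale starts
#' at 0).
#'
#' @param icc ICC value.
#' @return Character label.
#' @export
classify_icc <- function(icc) {
  vapply(icc, function(v) {
    if (v < 0) {
      warning("negative ICC classified as 'slight'")
      return("slight")
    }
    if (v > 1 + 1e-9) abort_domain("icc must be <= 1")
    if (v >= 0.81) "almost perfect"
    else if (v >= 0.61) "substantial"
    else if (v >= 0.41) "moderate"
    else if (v >= 0.21) "fair"
    else "slight"
  }, character(1))
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors, `n >= 3`, both non-constant.
#' @return Correlation coefficient `r`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort_validation("paired vectors differ in length: %d vs %d",
                     length(x), length(y))
  }
  if (length(x) < 3) abort_insufficient("correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_domain("constant input: correlation undefined")
  }
  stats::cor(x, y)
}

#' Correlation strength classification
#'
#' On `|r|`, lower bound inclusive: 0.90-1.00 very strong, 0.70-0.89
#' strong, 0.50-0.69 moderate, 0.30-0.49 weak, 0-0.29 very weak.
#'
#' @param r Correlation in `[-1, 1]`.
#' @return Character label.
#' @export
classify_r <- function(r) {
  vapply(r, function(v) {
    if (abs(v) > 1 + 1e-9) abort_domain("|r| must be <= 1")
    a <- abs(v)
    if (a >= 0.90) "very strong"
    else if (a >= 0.70) "strong"
    else if (a >= 0.50) "moderate"
    else if (a >= 0.30) "weak"
    else "very weak"
  }, character(1))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `app - reference`, so a method that reads low
#' relative to the reference yields a negative bias. Limits of agreement are
#' `bias +/- 1.96 * SD(d)` with the sample SD (denominator n-1); the
#' interval is expected to contain about 95% of differences.
#'
#' @param app,reference Paired numeric vectors, `n >= 2`.
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n_outside_loa` (differences strictly outside the limits), `n`, and
#'   per-pair `means` and `diffs` for plotting.
#' @export
bland_altman <- function(app, reference) {
  if (length(app) != length(reference)) {
    abort_validation("paired vectors differ in length: %d vs %d",
                     length(app), length(reference))
  }
  if (length(app) < 2) abort_insufficient("Bland-Altman needs n >= 2")
  d <- app - reference
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sdd
  list(bias = bias, sd_diff = sdd, loa_low = loa[1], loa_high = loa[2],
       n_outside_loa = sum(d < loa[1] | d > loa[2]), n = length(d),
       means = (app + reference) / 2, diffs = d)
}

#' Reliability summary for one movement
#'
#' Bundles ICC (with CI and classification), pooled SD, SEM and MDC for one
#' movement's two-session app scores.
#'
#' @inheritParams icc_two_way_random
#' @param movement Movement label carried into the result.
#' @param pooling Passed to [sem()].
#' @return One-row tibble: movement, n, icc, ci_low, ci_high, icc_class,
#'   s_pooled, sem, mdc.
#' @export
reliability_result <- function(movement, session1, session2,
                               type = "agreement", pooling = "pooled") {
  fit <- icc_two_way_random(session1, session2, type = type)
  icc_for_sem <- min(1, max(0, fit$icc))  # SEM formula domain
  s <- if (pooling == "pooled") stats::sd(c(session1, session2))
       else mean(c(stats::sd(session1), stats::sd(session2)))
  sem_v <- sem(cbind(session1, session2), icc_for_sem, pooling = pooling)
  tibble::tibble(
    movement = movement, n = fit$n,
    icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
    icc_class = classify_icc(fit$icc),
    s_pooled = s, sem = sem_v, mdc = mdc(sem_v)
  )
}

#' Validity summary for one movement
#'
#' Pearson correlation (with strength label) and Bland-Altman agreement of
#' the app against the reference method.
#'
#' @param movement Movement label carried into the result.
#' @param app,reference Paired session-1 scores of the two methods.
#' @return One-row tibble: movement, n, r, r_class, bias, sd_diff, loa_low,
#'   loa_high, n_outside_loa.
#' @export
validity_result <- function(movement, app, reference) {
  r <- pearson_r(app, reference)
  ba <- bland_altman(app, reference)
  tibble::tibble(
    movement = movement, n = ba$n, r = r, r_class = classify_r(r),
    bias = ba$bias, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    n_outside_loa = ba$n_outside_loa
  )
}
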