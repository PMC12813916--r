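#' Population reference interval
#'
#' Central 95 % range of a healthy sample: `mean +/- 1.96 SD` for normally
#' distributed variables, or the 2.5th and 97.5th percentiles for skewed
#' variables. Percentiles use linear interpolation between the closest order
#' statistics (R quantile type 7).
#'
#' @param values Numeric sample (finite, n >= 2).
#' @param method `"normal"` or `"percentile"`.
#' @return An object of class `reference_interval`: list with `lower`,
#'   `upper`, `method`, `n`.
#' @examples
#' x <- rnorm(200)
#' x <- (x - mean(x)) / sd(x) * 310 + 1975 # moment-matched GWI sample
#' reference_interval(x, "normal") # 1367.4 to 2582.6 mmHg%
#' @export
reference_interval <- function(values, method = c("normal", "percentile")) {
  method <- match.arg(method)
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 2L) stopf("reference interval needs at least 2 finite values")
  if (method == "normal") {
    m <- mean(x); s <- stats::sd(x)
    lim <- c(m - 1.96 * s, m + 1.96 * s)
  } else {
    if (n < 40L)
      warnf("percentile reference interval from n = %d (< 40): tail estimates are unstable", n)
    lim <- stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  }
  structure(list(lower = lim[1L], upper = lim[2L], method = method, n = n),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  cat(sprintf("95%% reference interval (%s, n = %d): %.4g to %.4g\n",
              x$method, x$n, x$lower, x$upper))
  invisible(x)
}

#' Tukey fence outlier flags
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation of order statistics (quantile type 7).
#'
#' @param values Numeric sample, n >= 4.
#' @return Logical vector of flags, one per input value (`NA` inputs flag
#'   `NA`).
#' @export
tukey_outliers <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 4L) stopf("Tukey outlier detection needs at least 4 finite values")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  values < q[1L] - 1.5 * iqr | values > q[2L] + 1.5 * iqr
}

#' Back-transform a log-scale regression slope
#'
#' Converts a slope fitted on log-transformed outcome to the relative
#' percent change per unit of the predictor: `100 * (exp(beta) - 1)`.
#'
#' @param beta_log Slope on the natural-log scale.
#' @return Percent change per predictor unit.
#' @examples
#' back_transform_log_beta(0.011) # 1.1 % higher per year
#' @export
back_transform_log_beta <- function(beta_log) {
  check_number(beta_log, "beta_log")
  100 * (exp(beta_log) - 1)
}

#' Back-transform a logit-scale regression slope
#'
#' Converts a slope fitted on a logit-transformed outcome to the
#' multiplicative percent change in the odds per unit of the predictor:
#' `100 * (exp(beta) - 1)`.
#'
#' @param beta_logit Slope on the logit scale.
#' @return Percent odds change per predictor unit.
#' @examples
#' back_transform_logit_beta(-0.009) # 0.9 % lower odds per year
#' @export
back_transform_logit_beta <- function(beta_logit) {
  check_number(beta_logit, "beta_logit")
  100 * (exp(beta_logit) - 1)
}

#' Bland-Altman agreement statistics
#'
#' Mean bias and 95 % limits of agreement (`bias +/- 1.96 SD` of the paired
#' differences) between two raters or methods.
#'
#' @param x,y Paired measurements of equal length (n >= 2).
#' @return An object of class `agreement_stats`: list with `bias`,
#'   `loa_lower`, `loa_upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stopf("'x' and 'y' must be paired (equal length)")
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  if (length(d) < 2L) stopf("Bland-Altman needs at least 2 complete pairs")
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s, sd_diff = s, n = length(d)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("Bias %.4g, 95%% limits of agreement %.4g to %.4g (n = %d)\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  if (!is.null(x$icc))
    cat(sprintf("ICC(2,1) %.3f (95%% CI %.3f to %.3f)\n",
                x$icc, x$icc_ci[1L], x$icc_ci[2L]))
  invisible(x)
}

#' Intraclass correlation for single random raters
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(2,1)) computed from the ANOVA mean squares of a complete
#' subjects-by-raters table, with the standard F-based 95 % confidence
#' interval.
#'
#' @param ratings Numeric matrix or data.frame, one row per subject and one
#'   column per rater; must be complete (no missing cells, no imputation).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `icc_result`: list with `icc`, `icc_ci`
#'   (length-2), `n_subjects`, `n_raters` and the mean squares.
#' @export
icc_single_random <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (!is.numeric(x)) stopf("'ratings' must be numeric")
  if (anyNA(x)) stopf("'ratings' table must be complete (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stopf("need at least 2 subjects and 2 raters")
  grand <- mean(x)
  sm <- rowMeans(x); rm_ <- colMeans(x)
  msr <- k * sum((sm - grand)^2) / (n - 1)            # between subjects
  msc <- n * sum((rm_ - grand)^2) / (k - 1)           # between raters
  mse <- sum((x - outer(sm, rep(1, k)) - outer(rep(1, n), rm_) + grand)^2) /
    ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) NA_real_ else (msr - mse) / denom

  if (!is.finite(icc) || mse <= .Machine$double.eps * max(msr, 1)) {
    ci <- c(icc, icc)
  } else {
    alpha <- 1 - conf_level
    fc <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc * fc + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fc^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f2u <- stats::qf(1 - alpha / 2, n - 1, v)
    f2l <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f2u * mse) /
      (f2u * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f2l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2l * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, icc_ci = ci, n_subjects = n, n_raters = k,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (95%% CI %.3f to %.3f), %d subjects x %d raters\n",
              x$icc, x$icc_ci[1L], x$icc_ci[2L], x$n_subjects, x$n_raters))
  invisible(x)
}

#' Univariable least-squares slope
#'
#' Ordinary least-squares regression of an outcome on a single predictor,
#' optionally after transforming the outcome to the log or logit scale
#' (logit expects percentages in (0, 100)). Returns the slope with its
#' standard error and two-sided p-value; used for age-effect estimation and
#' parameter-recovery checks.
#'
#' @param y Outcome sample.
#' @param x Predictor sample of equal length with nonzero variance.
#' @param scale `"identity"`, `"log"` or `"logit"`.
#' @return An object of class `regression_effect`: list with `beta`, `se`,
#'   `p`, `intercept`, `scale`, `n`.
#' @export
univariable_slope <- function(y, x, scale = c("identity", "log", "logit")) {
  scale <- match.arg(scale)
  if (length(y) != length(x)) stopf("'y' and 'x' must have equal length")
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(x) < 3L) stopf("need at least 3 complete observations")
  if (stats::var(x) == 0) stopf("predictor 'x' is constant; slope undefined")
  yt <- switch(scale,
               identity = y,
               log = {
                 if (any(y <= 0)) stopf("log scale requires positive outcomes")
                 log(y)
               },
               logit = {
                 if (any(y <= 0 | y >= 100))
                   stopf("logit scale requires percentages strictly inside (0, 100)")
                 stats::qlogis(y / 100)
               })
  fit <- stats::lm(yt ~ x)
  co <- summary(fit)$coefficients
  structure(list(beta = co[2L, 1L], se = co[2L, 2L], p = co[2L, 4L],
                 intercept = co[1L, 1L], scale = scale, n = length(x)),
            class = "regression_effect")
}

#' @export
print.regression_effect <- function(x, ...) {
  cat(sprintf("slope %.4g (SE %.3g, p = %.3g, %s scale, n = %d)\n",
              x$beta, x$se, x$p, x$scale, x$n))
  invisible(x)
}
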