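#' Recovery of a spiked (fortified) sample
#'
#' Accuracy surrogate for analytical validation:
#' `R = (C1 - C2) / C3 * 100`, where `C1` is the concentration measured in
#' the fortified sample, `C2` the concentration of the unfortified sample
#' and `C3` the added (spike) concentration. The acceptance window is the
#' conventional 80-120% interval.
#'
#' @param c1_fortified,c2_unfortified,c3_added Concentrations in mg/mL;
#'   vectorised. `c3_added` must be strictly positive.
#' @param accept Length-2 numeric acceptance interval in percent.
#'   Default `c(80, 120)`.
#' @return A tibble with the three inputs, `recovery_pct` and a logical
#'   `passes` flag.
#' @examples
#' recovery(1.05e-2, 5.0e-4, 1.0e-2)
#' @export
recovery <- function(c1_fortified, c2_unfortified, c3_added,
                     accept = c(80, 120)) {
  if (any(c3_added <= 0)) {
    abort("The added (spike) concentration `c3_added` must be > 0.",
          class = "chromaquant_spike_error")
  }
  pct <- (c1_fortified - c2_unfortified) / c3_added * 100
  tibble(c1_fortified = c1_fortified,
         c2_unfortified = c2_unfortified,
         c3_added = c3_added,
         recovery_pct = pct,
         passes = pct >= accept[1] & pct <= accept[2])
}

#' Coefficient of variation (precision)
#'
#' `CV% = SD / mean * 100`, with the sample standard deviation (n - 1
#' denominator). The usual acceptance rule for this kind of assay is
#' CV at most 20%.
#'
#' @param values Numeric vector of at least two replicate measurements with
#'   non-zero mean.
#' @return The coefficient of variation in percent (scalar).
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    abort("At least two replicate values are required.",
          class = "chromaquant_degenerate_error")
  }
  m <- mean(values)
  if (m == 0) {
    abort("CV is undefined for a zero mean.",
          class = "chromaquant_degenerate_error")
  }
  sd(values) / m * 100
}

#' Detection and quantification limits
#'
#' `LOD = 3.3 * sigma / m` and `LOQ = 10 * sigma / m`, where `sigma` is the
#' standard deviation of ten blank measurements or of the replicates at the
#' lowest calibration level, and `m` the calibration slope. When `sigma` is
#' already expressed in concentration units, leave `slope_m = 1`. The pair
#' is tied by construction: `LOQ / LOD = 10 / 3.3` for every input.
#'
#' @param sigma Non-negative standard deviation (response units, or mg/mL
#'   with `slope_m = 1`).
#' @param slope_m Calibration slope (response per mg/mL); must be > 0.
#' @return A one-row tibble with `sigma`, `slope_m`, `lod`, `loq` (mg/mL).
#' @examples
#' detection_limits(sigma = 2.26e-7, slope_m = 1)
#' @export
detection_limits <- function(sigma, slope_m = 1) {
  if (any(sigma < 0)) {
    abort("`sigma` must be non-negative.", class = "chromaquant_limit_error")
  }
  if (any(slope_m <= 0)) {
    abort("The calibration slope must be strictly positive.",
          class = "chromaquant_limit_error")
  }
  tibble(sigma = sigma, slope_m = slope_m,
         lod = 3.3 * sigma / slope_m,
         loq = 10 * sigma / slope_m)
}

#' Regression significance by ANOVA
#'
#' Partitions the calibration regression into model and residual mean
#' squares; `F = MS_regression / MS_residual` on (1, n - 2) degrees of
#' freedom. An exactly linear data set has zero residual variance; the F
#' statistic is then reported as `Inf` with p = 0 and a `degenerate` flag.
#'
#' @param fit A `linear_cal` object from [fit_linear()] (or an `lm`).
#' @return A one-row tibble: `f_value`, `df1`, `df2`, `p_value`,
#'   `degenerate`.
#' @export
regression_anova <- function(fit) {
  lmfit <- if (inherits(fit, "linear_cal")) fit$fit else fit
  stopifnot(inherits(lmfit, "lm"))
  n <- length(resid(lmfit))
  if (n < 3L) {
    abort("ANOVA needs at least 3 observations.",
          class = "chromaquant_dimension_error")
  }
  y <- fitted(lmfit) + resid(lmfit)
  ss_reg <- sum((fitted(lmfit) - mean(y))^2)
  ss_res <- sum(resid(lmfit)^2)
  df2 <- n - 2L
  if (ss_res < .Machine$double.eps * sum(y^2)) {
    return(tibble(f_value = Inf, df1 = 1L, df2 = df2, p_value = 0,
                  degenerate = TRUE))
  }
  f <- (ss_reg / 1) / (ss_res / df2)
  tibble(f_value = f, df1 = 1L, df2 = df2,
         p_value = pf(f, 1, df2, lower.tail = FALSE),
         degenerate = FALSE)
}

#' Breusch-Pagan test for heteroscedastic calibration residuals
#'
#' Lagrange-multiplier form: the squared residuals (scaled by their mean)
#' are regressed on the predictors and the statistic is `n * R^2` of that
#' auxiliary regression, referred to a chi-squared distribution with as many
#' degrees of freedom as predictors (the studentised form of the test,
#' computed through \pkg{lmtest}).
#'
#' @param fit A `linear_cal` object or an `lm`.
#' @return A one-row tibble: `bp_stat`, `df`, `p_value`.
#' @export
breusch_pagan <- function(fit) {
  lmfit <- if (inherits(fit, "linear_cal")) fit$fit else fit
  stopifnot(inherits(lmfit, "lm"))
  if (length(resid(lmfit)) < 4L) {
    abort("The Breusch-Pagan test needs at least 4 observations.",
          class = "chromaquant_dimension_error")
  }
  bp <- lmtest::bptest(lmfit, studentize = TRUE)
  tibble(bp_stat = unname(bp$statistic),
         df = unname(bp$parameter),
         p_value = unname(bp$p.value))
}

#' Shapiro-Wilk test for normality of residuals
#'
#' Royston's approximation of the W statistic with its normalising
#' transform, as implemented in [stats::shapiro.test()]; valid for
#' 3 <= n <= 5000.
#'
#' @param values Numeric vector (typically calibration residuals).
#' @return A one-row tibble: `w_stat`, `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L || length(values) > 5000L) {
    abort("The Shapiro-Wilk test requires 3 <= n <= 5000.",
          class = "chromaquant_dimension_error")
  }
  if (diff(range(values)) == 0) {
    abort("All values are identical; W is undefined.",
          class = "chromaquant_degenerate_error")
  }
  sw <- shapiro.test(values)
  tibble(w_stat = unname(sw$statistic), p_value = unname(sw$p.value))
}

#' Full regression-diagnostics report for a calibration
#'
#' Bundles [regression_anova()], [breusch_pagan()] and [shapiro_wilk()] on
#' the residuals into one tidy row with pass flags at the given level:
#' a valid calibration shows a significant regression, no evidence of
#' heteroscedasticity, and normally distributed residuals.
#'
#' @param fit A `linear_cal` object.
#' @param alpha Significance level for the flags (default 0.05).
#' @return A one-row tibble with the three statistics, their p-values and
#'   logical `significant_regression`, `homoscedastic`, `normal_residuals`.
#' @export
diagnostics_report <- function(fit, alpha = 0.05) {
  an <- regression_anova(fit)
  bp <- breusch_pagan(fit)
  sw <- shapiro_wilk(if (inherits(fit, "linear_cal")) fit$residuals
                     else resid(fit))
  tibble(anova_f = an$f_value, anova_p = an$p_value,
         bp_stat = bp$bp_stat, bp_p = bp$p_value,
         sw_w = sw$w_stat, sw_p = sw$p_value,
         significant_regression = an$p_value < alpha,
         homoscedastic = bp$p_value >= alpha,
         normal_residuals = sw$p_value >= alpha)
}
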