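#' Fit a univariate linear calibration curve
#'
#' Ordinary least squares of a single analytical response (absorbance, or one
#' colour/reflectance channel) on concentration: `response = m * conc + b`.
#' Prediction of unknowns inverts the curve, `conc = (response - b) / m`.
#'
#' @param data A data frame holding the calibration levels, one row per
#'   replicate measurement.
#' @param response,conc Columns holding the measured response and the
#'   reference concentration (mg/mL). Unquoted (tidy-eval).
#' @return A `linear_cal` object: the fitted `lm` plus `slope`, `intercept`,
#'   `r_squared` and `residuals`. Supports [predict()], [tidy()], [glance()]
#'   and [autoplot()].
#' @examples
#' curve <- tibble::tibble(conc = rep(c(1, 2, 4, 8), each = 3))
#' curve$abs <- 0.05 * curve$conc + 0.002
#' fit_linear(curve, abs, conc)
#' @export
fit_linear <- function(data, response, conc) {
  y <- dplyr::pull(data, {{ response }})
  x <- dplyr::pull(data, {{ conc }})
  if (length(x) < 2L || dplyr::n_distinct(x) < 2L) {
    abort("At least two distinct concentration levels are required.",
          class = "chromaquant_singular_error")
  }
  if (var(y) == 0) {
    abort("Responses are constant; the calibration slope is undefined (zero total sum of squares).",
          class = "chromaquant_degenerate_error")
  }
  df <- tibble(.conc = x, .response = y)
  fit <- lm(.response ~ .conc, data = df)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    fit = fit,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = 1 - ss_res / ss_tot,
    residuals = unname(resid(fit)),
    n = length(y),
    response_col = rlang::as_name(rlang::enquo(response)),
    conc_col = rlang::as_name(rlang::enquo(conc))
  ), class = "linear_cal")
}

#' @export
print.linear_cal <- function(x, ...) {
  cat(sprintf(
    "<linear_cal> response = %.6g * conc + %.6g   (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Predict concentrations from a univariate calibration
#'
#' @param object A `linear_cal` fit.
#' @param newdata Either a numeric vector of responses or a data frame
#'   containing the response column the model was fitted with.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (mg/mL). Negative
#'   predictions (below-blank signal) are returned as-is, with a warning.
#' @export
predict.linear_cal <- function(object, newdata, ...) {
  y <- if (is.data.frame(newdata)) {
    if (!object$response_col %in% names(newdata)) {
      abort(sprintf("`newdata` lacks the response column '%s'.",
                    object$response_col),
            class = "chromaquant_dimension_error")
    }
    newdata[[object$response_col]]
  } else {
    as.numeric(newdata)
  }
  pred <- (y - object$intercept) / object$slope
  if (any(pred < 0, na.rm = TRUE)) {
    warn("Some predicted concentrations are negative (signal below the blank); returned unclipped.")
  }
  pred
}

#' @export
tidy.linear_cal <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("(Intercept)", "conc"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.linear_cal <- function(x, ...) {
  an <- regression_anova(x)
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         statistic = an$f_value, p.value = an$p_value, n = x$n)
}

#' Calibration and prediction quality metrics
#'
#' Computes the standard figure-of-merit set for a calibration model:
#' \describe{
#'   \item{rmsec}{root-mean-square error of calibration,
#'     `sqrt(mean((pred - conc)^2))` over the calibration set;}
#'   \item{rmsep}{the same quantity over an independent validation set;}
#'   \item{bias}{mean signed prediction error on the validation set;}
#'   \item{relative_error_pct}{mean of `|pred - conc| / conc * 100`
#'     (rows with `conc == 0` are excluded, with a warning);}
#'   \item{r_squared}{squared Pearson correlation between predicted and
#'     reference concentrations.}
#' }
#' Metrics are reported for the calibration set and, when supplied, the
#' validation set, one row each.
#'
#' @param model A `linear_cal` or `pls_cal` object.
#' @param cal_data Calibration data frame (features/response + concentration).
#' @param val_data Optional validation data frame of the same shape.
#' @param conc Name of the concentration column (default `"conc"`).
#' @return A tibble with columns `set`, `n`, `rmse`, `bias`,
#'   `relative_error_pct`, `r_squared`. The `rmse` of the `"calibration"` row
#'   is the RMSEC, that of the `"validation"` row the RMSEP.
#' @export
calibration_metrics <- function(model, cal_data, val_data = NULL,
                                conc = "conc") {
  one_set <- function(data, set) {
    y <- data[[conc]]
    pred <- predict(model, data)
    keep <- y != 0
    if (!all(keep)) {
      warn("Rows with reference concentration 0 excluded from relative error.")
    }
    tibble(set = set,
           n = length(y),
           rmse = sqrt(mean((pred - y)^2)),
           bias = mean(pred - y),
           relative_error_pct = mean(abs(pred[keep] - y[keep]) / y[keep]) * 100,
           r_squared = if (var(y) > 0 && var(pred) > 0)
             stats::cor(pred, y)^2 else NA_real_)
  }
  out <- one_set(cal_data, "calibration")
  if (!is.null(val_data)) out <- dplyr::bind_rows(out, one_set(val_data, "validation"))
  out
}
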