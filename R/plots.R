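#' Plot a univariate calibration curve
#'
#' Observed responses against concentration with the fitted least-squares
#' line.
#'
#' @param object A `linear_cal` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.linear_cal <- function(object, ...) {
  df <- tibble(conc = object$fit$model$.conc,
               response = object$fit$model$.response)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "concentration (mg/mL)", y = "response",
                  title = sprintf("Calibration curve (R² = %.4f)",
                                  object$r_squared))
}

#' Plot a PLS calibration: predicted vs reference, and the RMSECV curve
#'
#' @param object A `pls_cal` model.
#' @param ... Unused.
#' @return A ggplot. When the model carries a cross-validation curve (LV
#'   count chosen automatically) the RMSECV-vs-LV panel can be drawn with
#'   [plot_rmsecv()].
#' @export
autoplot.pls_cal <- function(object, ...) {
  df <- tibble(reference = object$y, predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference concentration (mg/mL)",
                  y = "predicted concentration (mg/mL)",
                  title = sprintf("PLS1 calibration, %d LV", object$n_lv))
}

#' @rdname autoplot.pls_cal
#' @param model A `pls_cal` fitted with automatic LV selection, or the
#'   result of [select_n_lv()].
#' @export
plot_rmsecv <- function(model) {
  curve <- if (inherits(model, "pls_cal")) model$rmsecv
           else attr(model, "rmsecv")
  if (is.null(curve)) {
    abort("No RMSECV curve available; fit with `n_lv = NULL` or use select_n_lv().",
          class = "chromaquant_io_error")
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_lv, y = .data$rmsecv)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "latent variables", y = "RMSECV (mg/mL)",
                  title = "Leave-one-out cross-validation")
}

#' Pareto chart of factorial effects
#'
#' Bars of |t| per effect in decreasing order, with the critical t at the
#' centre-point degrees of freedom as a reference line.
#'
#' @param effects A `doe_effects` object.
#' @param alpha Significance level for the reference line (default 0.05).
#' @return A ggplot.
#' @export
plot_pareto <- function(effects, alpha = 0.05) {
  stopifnot(inherits(effects, "doe_effects"))
  df <- tidy(effects)
  df$term <- factor(df$term, levels = rev(effects$pareto_order))
  tcrit <- qt(1 - alpha / 2, df = effects$df)
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$t_value), y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = tcrit, linetype = 2, colour = "red") +
    ggplot2::labs(x = "|t|", y = NULL, title = "Pareto chart of effects")
}

#' Half-normal plot of factorial effects
#'
#' @param effects A `doe_effects` object.
#' @return A ggplot of |effect| against half-normal quantiles; inert effects
#'   fall on a line through the origin, active ones stand off it.
#' @export
plot_half_normal <- function(effects) {
  stopifnot(inherits(effects, "doe_effects"))
  ggplot2::ggplot(effects$half_normal,
                  ggplot2::aes(x = .data$quantile, y = .data$abs_effect,
                               label = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(nudge_x = 0.04, hjust = 0) +
    ggplot2::labs(x = "half-normal quantile", y = "|effect|",
                  title = "Half-normal plot of effects")
}

#' Plot per-sample relative error of a method comparison
#'
#' @param object A `method_comparison` tibble from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot bar chart of the relative error per sample.
#' @export
autoplot.method_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$relative_error_pct)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "relative error (%)",
                  title = "Between-method relative error per sample")
}

#' Display a rendered scene image
#'
#' @param object An [rgb_image].
#' @param ... Unused.
#' @return A ggplot raster of the image.
#' @export
autoplot.rgb_image <- function(object, ...) {
  px <- unclass(object)
  df <- expand.grid(row = seq_len(dim(px)[1]), col = seq_len(dim(px)[2]))
  df$fill <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3],
                            maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
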