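#' Variance-ratio F statistic between two methods
#'
#' `F = sd_ref^2 / sd_alt^2`, with the reference method's variance in the
#' numerator — no larger-variance reordering, so values below 1 simply mean
#' the reference method was more variable. Two exactly-zero SDs return 1 by
#' convention (flagged with a warning).
#'
#' @param sd_ref,sd_alt Replicate standard deviations of the reference and
#'   alternative method; vectorised.
#' @return Numeric vector of F values.
#' @export
variance_ratio_f <- function(sd_ref, sd_alt) {
  if (any(sd_alt == 0 & sd_ref > 0)) {
    abort("F is undefined when the denominator SD is 0 and the numerator is not.",
          class = "chromaquant_degenerate_error")
  }
  both0 <- sd_ref == 0 & sd_alt == 0
  if (any(both0)) {
    warn("Both SDs are zero for some samples; F reported as 1 by convention.")
  }
  ifelse(both0, 1, sd_ref^2 / sd_alt^2)
}

#' Critical value of the F distribution
#'
#' Upper-tail quantile `F(1 - alpha; df1, df2)`. With triplicates on both
#' sides (df 2 and 2) at the 95% level this is 19.00, the usual benchmark
#' for small-n method comparison.
#'
#' @param alpha Upper-tail probability (default 0.05).
#' @param df1,df2 Degrees of freedom.
#' @return The critical F value.
#' @export
critical_f <- function(alpha = 0.05, df1, df2) {
  stopifnot(df1 >= 1, df2 >= 1, alpha > 0, alpha < 1)
  qf(1 - alpha, df1, df2)
}

#' Paired t test from per-replicate differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`, two-sided p. Raw
#' paired replicate values are required — summary means/SDs do not determine
#' the paired statistic. Degenerate cases: all-zero differences give t = 0
#' (p = 1); equal nonzero differences give an infinite t, flagged.
#'
#' @param diffs Numeric vector of paired differences (method1 - method2 per
#'   replicate), `n >= 2`.
#' @param conf_level Confidence level used for the reported critical value.
#' @return A one-row tibble: `t_value`, `df`, `p_value`, `t_crit`,
#'   `degenerate`.
#' @export
paired_t <- function(diffs, conf_level = 0.95) {
  n <- length(diffs)
  if (n < 2L) {
    abort("At least two paired differences are required.",
          class = "chromaquant_dimension_error")
  }
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  s <- sd(diffs)
  m <- mean(diffs)
  if (s == 0) {
    if (m == 0) {
      return(tibble(t_value = 0, df = n - 1L, p_value = 1, t_crit = tcrit,
                    degenerate = FALSE))
    }
    warn("Zero SD of differences with nonzero mean; t reported as infinite.")
    return(tibble(t_value = Inf, df = n - 1L, p_value = 0, t_crit = tcrit,
                  degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  tibble(t_value = t, df = n - 1L,
         p_value = 2 * pt(abs(t), df = n - 1, lower.tail = FALSE),
         t_crit = tcrit, degenerate = FALSE)
}

#' Relative error between two concentration estimates
#'
#' `|c_ref - c_alt| / c_ref * 100`, the per-sample disagreement of the
#' alternative method against the reference one.
#'
#' @param c_ref Reference-method concentration (mg/mL), > 0; vectorised.
#' @param c_alt Alternative-method concentration (mg/mL).
#' @return Relative error in percent.
#' @export
relative_error_pct <- function(c_ref, c_alt) {
  if (any(c_ref <= 0)) {
    abort("The reference concentration must be strictly positive.",
          class = "chromaquant_degenerate_error")
  }
  abs(c_ref - c_alt) / c_ref * 100
}

#' Regulatory-limit compliance
#'
#' Whether a measured colorant concentration is strictly below the maximum
#' allowable limit; the default limit is 3.0e-1 mg/mL, the ceiling for
#' Allura Red AC (E129) in candies.
#'
#' @param conc Concentration in mg/mL, non-negative; vectorised.
#' @param limit Maximum allowable concentration (mg/mL).
#' @return Logical vector, `TRUE` when compliant.
#' @export
compliance <- function(conc, limit = 3.0e-1) {
  if (any(conc < 0)) {
    abort("Concentrations must be non-negative.",
          class = "chromaquant_degenerate_error")
  }
  conc < limit
}

#' Per-sample two-method comparison table
#'
#' For each sample measured by both a reference method (e.g. UV-vis
#' spectrophotometry) and an alternative method (e.g. image-based
#' quantification), computes the variance-ratio F against its critical
#' value, the relative error of the alternative method, and the
#' regulatory-limit compliance of both estimates. A sample is called
#' `equivalent` when its F value stays below the critical value (the paired
#' t enters the verdict only when raw replicates are available; printed
#' summary tables carry means/SDs only).
#'
#' @param data Long tibble with columns `sample_id`, `method`, `mean`, `sd`,
#'   `n` — two rows per sample, one per method (see [table3_fixture()] for
#'   the expected shape).
#' @param reference,alternative Values of `method` identifying the two
#'   sides. Defaults `"uvvis"` and `"dia"`.
#' @param alpha Significance level for the critical F (default 0.05).
#' @param limit Regulatory concentration limit in mg/mL passed to
#'   [compliance()].
#' @return A `method_comparison` tibble with one row per sample:
#'   concentrations, SDs, `f_value`, `f_crit`, `relative_error_pct`,
#'   `equivalent`, `compliant_ref`, `compliant_alt`. Use [glance()] for the
#'   cross-sample summary (concentration extrema per method, maximum
#'   relative error, overall verdicts).
#' @examples
#' cmp <- compare_methods(table3_fixture())
#' glance(cmp)
#' @export
compare_methods <- function(data, reference = "uvvis", alternative = "dia",
                            alpha = 0.05, limit = 3.0e-1) {
  need <- c("sample_id", "method", "mean", "sd", "n")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` needs columns: %s.", paste(need, collapse = ", ")),
          class = "chromaquant_io_error")
  }
  ref <- dplyr::filter(data, .data$method == reference)
  alt <- dplyr::filter(data, .data$method == alternative)
  if (!setequal(ref$sample_id, alt$sample_id) ||
      anyDuplicated(ref$sample_id) || anyDuplicated(alt$sample_id)) {
    abort("Both methods must report each sample id exactly once.",
          class = "chromaquant_io_error")
  }
  wide <- dplyr::inner_join(
    dplyr::select(ref, "sample_id", mean_ref = "mean", sd_ref = "sd",
                  n_ref = "n"),
    dplyr::select(alt, "sample_id", mean_alt = "mean", sd_alt = "sd",
                  n_alt = "n"),
    by = "sample_id")
  out <- dplyr::mutate(
    wide,
    f_value = variance_ratio_f(.data$sd_ref, .data$sd_alt),
    f_crit = critical_f(alpha, .data$n_ref - 1L, .data$n_alt - 1L),
    relative_error_pct = relative_error_pct(.data$mean_ref, .data$mean_alt),
    equivalent = .data$f_value < .data$f_crit,
    compliant_ref = compliance(.data$mean_ref, limit),
    compliant_alt = compliance(.data$mean_alt, limit))
  class(out) <- c("method_comparison", class(out))
  attr(out, "reference") <- reference
  attr(out, "alternative") <- alternative
  attr(out, "limit") <- limit
  out
}

#' Cross-sample summary of a method comparison
#'
#' @param x A `method_comparison` tibble from [compare_methods()].
#' @param ... Unused.
#' @return A one-row tibble with the concentration extrema of each method,
#'   the maximum relative error and the sample reaching it, and the overall
#'   equivalence / compliance verdicts.
#' @export
glance.method_comparison <- function(x, ...) {
  i <- which.max(x$relative_error_pct)
  tibble(n_samples = nrow(x),
         conc_min_ref = min(x$mean_ref), conc_max_ref = max(x$mean_ref),
         conc_min_alt = min(x$mean_alt), conc_max_alt = max(x$mean_alt),
         max_relative_error_pct = x$relative_error_pct[i],
         max_re_sample = x$sample_id[i],
         all_equivalent = all(x$equivalent),
         all_compliant = all(x$compliant_ref & x$compliant_alt))
}
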