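#' Build a two-factor full-factorial design with centre points
#'
#' The acquisition-condition optimiser runs a 2^2 full factorial (four
#' corners, each once) plus replicated centre points — by default five, so
#' nine runs in all. Factors are handled in coded units (-1, 0, +1) with the
#' linear mapping `actual = mid + coded * half_range`; the default factors
#' are the camera-to-cuvette distance (5-16 cm) and the chamber LED
#' intensity (anchored at 0-1124 lx, the low level being a nominal
#' "minimum"). Runs are listed in standard (Yates) order with the centre
#' runs last; a randomised execution order is drawn separately under `seed`.
#'
#' @param factors Named list of two length-2 numeric vectors
#'   `c(low, high)`. Default
#'   `list(distance_cm = c(5, 16), led_lx = c(0, 1124))`.
#' @param n_center Number of centre replicates (default 5).
#' @param seed Seed for the randomised `run_order` column (default 1).
#' @return A `factorial_design` tibble with columns `run`, `run_order`,
#'   `coded_a`, `coded_b`, `actual_a`, `actual_b` and an empty `response`
#'   column to be filled with the measured response (here: relative error in
#'   percent of the calibration predictions).
#' @export
build_design <- function(factors = list(distance_cm = c(5, 16),
                                        led_lx = c(0, 1124)),
                         n_center = 5L, seed = 1L) {
  if (length(factors) != 2L || is.null(names(factors))) {
    abort("`factors` must be a named list of exactly two c(low, high) ranges.",
          class = "chromaquant_doe_error")
  }
  rng <- lapply(factors, function(f) {
    if (length(f) != 2L || f[1] >= f[2]) {
      abort("Each factor needs low < high.", class = "chromaquant_doe_error")
    }
    c(mid = mean(f), half = diff(f) / 2)
  })
  coded_a <- c(-1, 1, -1, 1, rep(0, n_center))
  coded_b <- c(-1, -1, 1, 1, rep(0, n_center))
  n_runs <- 4L + n_center
  design <- tibble(
    run = seq_len(n_runs),
    run_order = withr::with_seed(seed, sample.int(n_runs)),
    coded_a = coded_a, coded_b = coded_b,
    actual_a = rng[[1]]["mid"] + coded_a * rng[[1]]["half"],
    actual_b = rng[[2]]["mid"] + coded_b * rng[[2]]["half"],
    response = NA_real_)
  class(design) <- c("factorial_design", class(design))
  attr(design, "factor_names") <- names(factors)
  attr(design, "n_center") <- as.integer(n_center)
  design
}

#' Estimate factorial effects, their significance, and curvature
#'
#' Main effects are corner-mean contrasts, `effect_X = mean(response at
#' X = +1) - mean(response at X = -1)` over the four corners; the
#' interaction uses the product column. With no corner replication, the
#' experimental error comes from the centre replicates:
#' `se_effect = 2 * s_center / sqrt(4)`, and each effect's t statistic is
#' referred to `n_center - 1` degrees of freedom. Curvature is the corner
#' mean minus the centre mean — a large value flags a response surface the
#' first-order model cannot represent.
#'
#' @param design A `factorial_design` with all `response` values filled in.
#' @return A `doe_effects` object. [tidy()] returns one row per term
#'   (`A`, `B`, `AB`) with `effect`, `se`, `t_value`, `p_value`,
#'   `significant`; the object also carries `curvature`, `pareto_order`
#'   (labels by decreasing `|t|`, ties alphabetical) and half-normal plot
#'   coordinates.
#' @export
estimate_effects <- function(design) {
  if (anyNA(design$response)) {
    abort("All runs need a response before effects can be estimated.",
          class = "chromaquant_doe_error")
  }
  corners <- design[design$coded_a != 0, ]
  centers <- design[design$coded_a == 0 & design$coded_b == 0, ]
  if (nrow(corners) != 4L) {
    abort("Expected exactly 4 corner runs.", class = "chromaquant_doe_error")
  }
  contrast <- function(col) {
    mean(corners$response[col > 0]) - mean(corners$response[col < 0])
  }
  eff <- c(A = contrast(corners$coded_a),
           B = contrast(corners$coded_b),
           AB = contrast(corners$coded_a * corners$coded_b))
  s_center <- sd(centers$response)
  se <- 2 * s_center / sqrt(4)
  df <- nrow(centers) - 1L
  tval <- eff / se
  pval <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  ord <- order(-abs(tval), names(eff))
  m <- length(eff)
  rk <- rank(abs(eff), ties.method = "first")
  half_normal <- tibble(term = names(eff),
                        abs_effect = abs(unname(eff)),
                        quantile = qnorm(0.5 + 0.5 * (rk - 0.5) / m))
  structure(list(
    effects = unname(eff), terms = names(eff),
    se_effect = se, df = df,
    t_values = unname(tval), p_values = unname(pval),
    curvature = mean(corners$response) - mean(centers$response),
    pareto_order = names(eff)[ord],
    half_normal = half_normal,
    factor_names = attr(design, "factor_names") %||% c("A", "B")
  ), class = "doe_effects")
}

#' @export
print.doe_effects <- function(x, ...) {
  cat("<doe_effects> 2^2 factorial with centre points\n")
  print(tidy(x))
  cat(sprintf("curvature (corner mean - centre mean): %.4g\n", x$curvature))
  invisible(x)
}

#' @export
tidy.doe_effects <- function(x, alpha = 0.05, ...) {
  tibble(term = x$terms,
         effect = x$effects,
         se = x$se_effect,
         t_value = x$t_values,
         df = x$df,
         p_value = x$p_values,
         significant = x$p_values < alpha)
}

#' @export
glance.doe_effects <- function(x, ...) {
  tibble(curvature = x$curvature, se_effect = x$se_effect, df = x$df,
         top_term = x$pareto_order[1])
}

#' Linear desirability for a minimise-type response
#'
#' `d = (high - y) / (high - low)`, clipped to \[0, 1\]: 1 at the best
#' (lowest) response, 0 at or beyond the worst. Used to score acquisition
#' conditions when the response is the relative error of the calibration.
#'
#' @param y Response value(s).
#' @param low Best (lowest) response, mapped to d = 1.
#' @param high Worst response, mapped to d = 0.
#' @return Desirability in \[0, 1\]; vectorised over `y`.
#' @export
desirability_minimize <- function(y, low, high) {
  if (low >= high) {
    abort("`low` must be strictly less than `high`.",
          class = "chromaquant_doe_error")
  }
  pmin(1, pmax(0, (high - y) / (high - low)))
}
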