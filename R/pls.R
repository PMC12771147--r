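#' PLS1 calibration by NIPALS
#'
#' Fits a single-response partial least-squares model linking the per-ROI
#' colour features (by default the three blank-referenced reflectance ratios)
#' to concentration. The algorithm is the classical NIPALS sequence for one
#' response: after mean-centering (and optional unit-variance scaling), each
#' latent variable takes its weight vector proportional to `X'y` (unit norm),
#' scores `t = X w`, X-loading `p = X't / t't`, y-loading `q = y't / t't`,
#' then deflates `X <- X - t p'` and `y <- y - q t`. The accumulated
#' regression vector is `b = W (P'W)^-1 q`, so prediction is a single inner
#' product on centred features.
#'
#' Mean-centering is always applied; unit-variance scaling is off by default
#' because the reflectance channels already share a common scale.
#'
#' @param data Data frame of calibration observations.
#' @param conc Concentration column (unquoted; default `conc`), in mg/mL.
#' @param features Feature columns (tidyselect; default the reflectance
#'   triple `c(refl_r, refl_g, refl_b)`).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#'   `NULL` (default) selects it by leave-one-out cross-validation via
#'   [select_n_lv()].
#' @param scale Autoscale features to unit variance? Default `FALSE`.
#' @param max_lv Upper bound handed to [select_n_lv()] when `n_lv` is `NULL`.
#' @return A `pls_cal` object with centering/scaling vectors, `weights` (W),
#'   `x_loadings` (P), `y_loadings` (q), `regression_vector` and, when LV
#'   selection ran, the `rmsecv` curve. Supports [predict()], [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' scene <- render_scene(default_calibration_scene(seed = 7))
#' sig <- extract_signals(scene$image, scene$layout)
#' cal <- dplyr::inner_join(sig, scene$truth[, c("label", "conc")], by = "label")
#' cal <- dplyr::filter(cal, grepl("^std|^blank", label))
#' fit_pls(cal, conc, n_lv = 2)
#' @export
fit_pls <- function(data, conc = conc,
                    features = c(refl_r, refl_g, refl_b),
                    n_lv = NULL, scale = FALSE, max_lv = NULL) {
  feat <- dplyr::select(dplyr::as_tibble(data), {{ features }})
  X <- as.matrix(feat)
  y <- dplyr::pull(data, {{ conc }})
  if (is.null(n_lv)) {
    max_lv <- max_lv %||% min(nrow(X) - 1L, ncol(X))
    sel <- select_n_lv_matrix(X, y, max_lv = max_lv, scale = scale)
    core <- pls1_nipals(X, y, n_lv = sel$n_lv, scale = scale)
    core$rmsecv <- sel$rmsecv
  } else {
    core <- pls1_nipals(X, y, n_lv = n_lv, scale = scale)
  }
  core$feature_cols <- colnames(feat)
  core$conc_col <- rlang::as_name(rlang::enquo(conc))
  core
}

pls_predict_core <- function(object, Xn) {
  Xc <- sweep(sweep(Xn, 2, object$x_mean), 2, object$x_scale, "/")
  drop(Xc %*% object$regression_vector) + object$y_mean
}

# NIPALS PLS1 core on plain matrices; returns a bare pls_cal
pls1_nipals <- function(X, y, n_lv, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) {
    abort("PLS calibration needs at least 3 observations.",
          class = "chromaquant_dimension_error")
  }
  if (n_lv < 1L || n_lv > min(n - 1L, p)) {
    abort(sprintf("`n_lv` must lie in [1, min(n - 1, p)] = [1, %d].",
                  min(n - 1L, p)),
          class = "chromaquant_dimension_error")
  }
  x_mean <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, sd) else rep(1, p)
  if (all(apply(X, 2, var) == 0)) {
    abort("All feature columns have zero variance.",
          class = "chromaquant_degenerate_error")
  }
  if (scale && any(x_scale == 0)) {
    abort("Cannot autoscale a zero-variance feature column.",
          class = "chromaquant_degenerate_error")
  }
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean

  W <- P <- matrix(0, p, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      abort(sprintf("Latent variable %d cannot be extracted: no covariance left between X and y.", a),
            class = "chromaquant_degenerate_error")
    }
    w <- w / nw
    tt <- drop(Xc %*% w)
    t2 <- sum(tt^2)
    P[, a] <- drop(crossprod(Xc, tt)) / t2
    q[a] <- sum(yc * tt) / t2
    W[, a] <- w
    Xc <- Xc - tcrossprod(tt, P[, a])
    yc <- yc - q[a] * tt
  }
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(
    n_lv = n_lv, n = n, p = p,
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = q,
    regression_vector = b,
    y = y, fitted = drop(sweep(sweep(X, 2, x_mean), 2, x_scale, "/") %*% b) + y_mean,
    feature_cols = colnames(X), conc_col = "conc"
  ), class = "pls_cal")
}

#' @export
print.pls_cal <- function(x, ...) {
  cat(sprintf("<pls_cal> PLS1/NIPALS, %d latent variable(s), %d obs x %d features\n",
              x$n_lv, x$n, x$p))
  cat("regression vector:",
      paste(sprintf("%.5g", x$regression_vector), collapse = "  "), "\n")
  invisible(x)
}

#' Choose the number of latent variables by leave-one-out cross-validation
#'
#' For each candidate LV count the model is refitted `n` times leaving one
#' observation out, and the root-mean-square error of cross-validation
#' (RMSECV) is accumulated. Rather than taking the raw minimiser, the
#' smallest LV count whose RMSECV lies within 5% of the global minimum is
#' returned — the usual parsimony guard against fitting noise with an extra
#' component. The procedure is fully deterministic.
#'
#' @inheritParams fit_pls
#' @param max_lv Largest LV count to consider; capped at `min(n - 1, p)`.
#' @return The selected LV count (integer), with the RMSECV curve attached
#'   as attribute `"rmsecv"` (a tibble with columns `n_lv`, `rmsecv`).
#' @export
select_n_lv <- function(data, conc = conc,
                        features = c(refl_r, refl_g, refl_b),
                        max_lv = NULL, scale = FALSE) {
  X <- as.matrix(dplyr::select(dplyr::as_tibble(data), {{ features }}))
  y <- dplyr::pull(data, {{ conc }})
  max_lv <- max_lv %||% min(nrow(X) - 1L, ncol(X))
  sel <- select_n_lv_matrix(X, y, max_lv = max_lv, scale = scale)
  structure(sel$n_lv, rmsecv = sel$rmsecv)
}

select_n_lv_matrix <- function(X, y, max_lv, scale = FALSE) {
  n <- nrow(X)
  max_lv <- min(max_lv, n - 2L, ncol(X))  # n-2: each LOO fit sees n-1 rows
  if (max_lv < 1L) {
    abort("Too few observations for cross-validated LV selection.",
          class = "chromaquant_dimension_error")
  }
  # rank-deficient data may not support every candidate count: when any
  # leave-one-out fold cannot extract LV `a`, the candidate list stops at a-1
  press <- numeric(0)
  for (a in seq_len(max_lv)) {
    acc <- 0
    ok <- TRUE
    for (i in seq_len(n)) {
      m <- tryCatch(
        pls1_nipals(X[-i, , drop = FALSE], y[-i], n_lv = a, scale = scale),
        chromaquant_degenerate_error = function(e) NULL)
      if (is.null(m)) { ok <- FALSE; break }
      acc <- acc + (pls_predict_core(m, X[i, , drop = FALSE]) - y[i])^2
    }
    if (!ok) break
    press[a] <- acc
  }
  if (!length(press)) {
    abort("No latent variable could be cross-validated on these data.",
          class = "chromaquant_degenerate_error")
  }
  rmsecv <- sqrt(press / n)
  pick <- which(rmsecv <= 1.05 * min(rmsecv))[1]
  list(n_lv = as.integer(pick),
       rmsecv = tibble(n_lv = seq_along(rmsecv), rmsecv = rmsecv))
}

#' Predict concentrations from a PLS calibration
#'
#' @param object A `pls_cal` model.
#' @param newdata A data frame containing the model's feature columns, or a
#'   numeric matrix with `p` columns.
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (mg/mL). Negative
#'   predictions (below-blank signal) are returned unclipped, with a warning.
#' @export
predict.pls_cal <- function(object, newdata, ...) {
  Xn <- if (is.data.frame(newdata)) {
    miss <- setdiff(object$feature_cols, names(newdata))
    if (length(miss)) {
      abort(sprintf("`newdata` lacks feature column(s): %s.",
                    paste(miss, collapse = ", ")),
            class = "chromaquant_dimension_error")
    }
    as.matrix(newdata[object$feature_cols])
  } else {
    m <- as.matrix(newdata)
    if (ncol(m) != object$p) {
      abort(sprintf("Feature dimension mismatch: model has %d, data has %d.",
                    object$p, ncol(m)),
            class = "chromaquant_dimension_error")
    }
    m
  }
  pred <- pls_predict_core(object, Xn)
  if (any(pred < 0, na.rm = TRUE)) {
    warn("Some predicted concentrations are negative (signal below the blank); returned unclipped.")
  }
  pred
}

#' @export
tidy.pls_cal <- function(x, ...) {
  tibble(term = x$feature_cols,
         estimate = unname(x$regression_vector))
}

#' @export
glance.pls_cal <- function(x, ...) {
  tibble(n_lv = x$n_lv, n = x$n, p = x$p,
         rmsec = sqrt(mean((x$fitted - x$y)^2)),
         r.squared = stats::cor(x$fitted, x$y)^2)
}
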