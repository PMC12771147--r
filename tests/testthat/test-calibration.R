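test_that("univariate calibration recovers exact linear data and rejects degenerate designs", {
  d <- tibble::tibble(conc = c(1, 2, 3, 4), resp = 2 * c(1, 2, 3, 4) + 1)
  fit <- fit_linear(d, resp, conc)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  expect_error(fit_linear(tibble::tibble(conc = rep(2, 4), resp = 1:4),
                          resp, conc),
               class = "chromaquant_singular_error")
  expect_error(fit_linear(tibble::tibble(conc = 1:4, resp = rep(3, 4)),
                          resp, conc),
               class = "chromaquant_degenerate_error")
})

test_that("least-squares estimates match the closed-form normal equations on a noisy curve", {
  levels <- calibration_levels()
  d <- withr::with_seed(21, tibble::tibble(
    conc = rep(levels, each = 3),
    resp = 12.5 * rep(levels, each = 3) + 0.03 + rnorm(18, 0, 0.005)))
  fit <- fit_linear(d, resp, conc)
  # direct sum formulas
  x <- d$conc; y <- d$resp; n <- length(x)
  m <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  b <- mean(y) - m * mean(x)
  expect_equal(fit$slope, m, tolerance = 1e-12)
  expect_equal(fit$intercept, b, tolerance = 1e-12)

  # prediction inverts the curve
  expect_equal(predict(fit, m * 0.005 + b), 0.005, tolerance = 1e-12)
  expect_warning(predict(fit, b - 1), "negative")
})

test_that("PLS1 with a single predictor collapses to OLS", {
  d <- withr::with_seed(31, tibble::tibble(
    x = rnorm(8), conc = 3 * rnorm(8)))
  d$conc <- 2 * d$x + withr::with_seed(32, rnorm(8, 0, 0.1))
  m <- fit_pls(d, conc, features = x, n_lv = 1)
  expect_equal(m$fitted, ols_predictions(matrix(d$x), d$conc),
               tolerance = 1e-10)
})

test_that("full-LV PLS reproduces least-squares predictions on full-rank data", {
  xy <- full_rank_xy(n = 7, seed = 11, noise = 0.2)
  d <- tibble::tibble(as.data.frame(xy$X), conc = xy$y)
  names(d)[1:3] <- c("f1", "f2", "f3")
  m <- fit_pls(d, conc, features = c(f1, f2, f3), n_lv = 3)
  expect_equal(m$fitted, ols_predictions(xy$X, xy$y), tolerance = 1e-8)
})

test_that("the first NIPALS weight vector is proportional to X'y after centering", {
  xy <- full_rank_xy(n = 9, seed = 41, noise = 0.3)
  m <- pls1_nipals(xy$X, xy$y, n_lv = 2)
  xc <- scale(xy$X, scale = FALSE)
  yc <- xy$y - mean(xy$y)
  w_ref <- drop(crossprod(xc, yc))
  cosine <- sum(m$weights[, 1] * w_ref) /
    sqrt(sum(m$weights[, 1]^2) * sum(w_ref^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-12)
})

test_that("prediction via the regression vector equals sequential LV deflation", {
  xy <- full_rank_xy(n = 8, seed = 51, noise = 0.5)
  m <- pls1_nipals(xy$X, xy$y, n_lv = 3)
  # sequential route: rebuild scores by deflating the centred data with W, P
  Xc <- sweep(xy$X, 2, m$x_mean)
  yhat <- rep(m$y_mean, nrow(Xc))
  for (a in seq_len(m$n_lv)) {
    t_a <- drop(Xc %*% m$weights[, a])
    yhat <- yhat + m$y_loadings[a] * t_a
    Xc <- Xc - tcrossprod(t_a, m$x_loadings[, a])
  }
  expect_equal(m$fitted, yhat, tolerance = 1e-9)
})

test_that("calibration is invariant to feature reordering", {
  xy <- full_rank_xy(n = 7, seed = 61, noise = 0.2)
  d <- tibble::tibble(as.data.frame(xy$X), conc = xy$y)
  names(d)[1:3] <- c("f1", "f2", "f3")
  m1 <- fit_pls(d, conc, features = c(f1, f2, f3), n_lv = 2)
  m2 <- fit_pls(d, conc, features = c(f3, f1, f2), n_lv = 2)
  expect_equal(m1$fitted, m2$fitted, tolerance = 1e-10)
  # centred random data straddle zero, so negative predictions are expected
  expect_equal(suppressWarnings(predict(m1, d)),
               suppressWarnings(predict(m2, d)), tolerance = 1e-10)
})

test_that("PLS guards its dimensional preconditions", {
  xy <- full_rank_xy(n = 6, seed = 71)
  expect_error(pls1_nipals(xy$X, xy$y, n_lv = 4),
               class = "chromaquant_dimension_error")
  expect_error(pls1_nipals(matrix(1, 6, 2), xy$y, n_lv = 1),
               class = "chromaquant_degenerate_error")
  m <- pls1_nipals(xy$X, xy$y, n_lv = 2)
  expect_error(predict(m, matrix(0, 2, 2)),
               class = "chromaquant_dimension_error")
})

test_that("LV selection finds the true dimensionality and is parsimonious under noise", {
  # a single latent direction drives y: one score vector spread over the
  # three channels (plus a trace of channel noise) -> selects 1
  withr::with_seed(81, {
    t1 <- rnorm(10)
    X <- outer(t1, c(1, 0.5, -0.8)) + matrix(rnorm(30, 0, 0.01), 10, 3)
    y <- 2 * t1
  })
  expect_equal(as.integer(select_n_lv(
    tibble::tibble(a = X[, 1], b = X[, 2], c = X[, 3], conc = y),
    conc, features = c(a, b, c))), 1L)

  # three independent concentration-linked factors at low noise -> 3;
  # the six measured channels mix the factors exactly (rank 3), so LV
  # counts beyond 3 are unreachable and the candidate list truncates
  withr::with_seed(82, {
    n <- 12
    F3 <- matrix(rnorm(n * 3), n, 3)
    M <- matrix(rnorm(18), 3, 6)
    X6 <- F3 %*% M
    y3 <- drop(F3 %*% c(1, -2, 1.5)) + rnorm(n, 0, 0.02)
  })
  d6 <- tibble::as_tibble(as.data.frame(X6))
  d6$conc <- y3
  sel3 <- select_n_lv(d6, conc, features = dplyr::starts_with("V"),
                      max_lv = 5)
  expect_equal(as.integer(sel3), 3L)
  expect_lte(nrow(attr(sel3, "rmsecv")), 3L)

  # pure-noise response: cross-validation cannot improve, pick the minimum
  withr::with_seed(83, {
    Xn <- matrix(rnorm(12 * 3), 12, 3)
    yn <- rnorm(12)
  })
  dn <- tibble::tibble(a = Xn[, 1], b = Xn[, 2], c = Xn[, 3], conc = yn)
  expect_equal(as.integer(select_n_lv(dn, conc, features = c(a, b, c))), 1L)

  # deterministic: same data, same curve
  s1 <- select_n_lv(dn, conc, features = c(a, b, c))
  s2 <- select_n_lv(dn, conc, features = c(a, b, c))
  expect_identical(attr(s1, "rmsecv"), attr(s2, "rmsecv"))
})

test_that("calibration metrics reduce to closed forms and match a brute-force loop", {
  # identity model: predictions equal the response column
  d <- tibble::tibble(conc = c(1, 2, 3, 4, 5), resp = c(1, 2, 3, 4, 5))
  ident <- fit_linear(d, resp, conc)
  perfect <- calibration_metrics(ident, d, d)
  expect_equal(perfect$rmse, c(0, 0))
  expect_equal(perfect$bias, c(0, 0))
  expect_equal(perfect$relative_error_pct, c(0, 0))
  expect_equal(perfect$r_squared, c(1, 1))

  # constant offset c: bias = c, RMSEP = |c|
  offset <- ident
  offset$intercept <- -0.25   # predict() returns resp + 0.25
  shifted <- calibration_metrics(offset, d, d)
  expect_equal(shifted$bias[2], 0.25)
  expect_equal(shifted$rmse[2], 0.25)

  # brute-force oracle on a noisy validation set
  val <- withr::with_seed(91, tibble::tibble(
    conc = c(0.5, 1.5, 2.5, 3.5), resp = c(0.5, 1.5, 2.5, 3.5) + rnorm(4, 0, 0.1)))
  got <- calibration_metrics(ident, d, val)[2, ]
  pred <- val$resp
  se <- 0; bias <- 0; re <- 0
  for (i in seq_len(4)) {
    se <- se + (pred[i] - val$conc[i])^2
    bias <- bias + (pred[i] - val$conc[i])
    re <- re + abs(pred[i] - val$conc[i]) / val$conc[i]
  }
  expect_equal(got$rmse, sqrt(se / 4))
  expect_equal(got$bias, bias / 4)
  expect_equal(got$relative_error_pct, re / 4 * 100)

  # zero reference concentrations are excluded with a warning
  withzero <- tibble::tibble(conc = c(0, 1, 2), resp = c(0.1, 1, 2))
  expect_warning(mz <- calibration_metrics(ident, withzero),
                 "concentration 0")
  expect_equal(mz$relative_error_pct, mean(c(0, 0)) * 100)
})
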