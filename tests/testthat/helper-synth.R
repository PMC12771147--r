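# shared fixture builders, all deterministic under explicit seeds

random_patch <- function(h, w, seed) {
  withr::with_seed(seed,
    rgb_image(array(sample(0:255, h * w * 3, replace = TRUE),
                    dim = c(h, w, 3))))
}

# a full-rank multivariate calibration set: 3 latent factors, p = 3
full_rank_xy <- function(n = 7, seed = 11, noise = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * 3), n, 3)
    beta <- c(0.7, -1.3, 2.1)
    y <- drop(X %*% beta) + rnorm(n, 0, noise)
    list(X = X, y = y)
  })
}

# independent least-squares oracle (explicit normal equations)
ols_predictions <- function(X, y, X_new = X) {
  Xa <- cbind(1, X)
  beta <- solve(crossprod(Xa), crossprod(Xa, y))
  drop(cbind(1, X_new) %*% beta)
}
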