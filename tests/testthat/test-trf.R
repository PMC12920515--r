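test_that("lag specification follows the floor/ceil sample convention", {
  ls <- lag_spec(-100, 600, 256)
  expect_equal(range(ls$lag_idx), c(-26, 154))
  expect_equal(length(ls$lag_idx), 181)
  expect_equal(ls$times_ms[1], -26 / 256 * 1000)
  ls64 <- lag_spec(-100, 600, 64)
  expect_equal(range(ls64$lag_idx), c(-7, 39))
})

test_that("lag matrix delays the stimulus with zero padding", {
  ls <- structure(list(t_min = 0, t_max = 1000 / 256, sample_rate = 256,
                       lag_idx = c(0L, 1L), times_ms = c(0, 1000 / 256)),
                  class = "lag_spec")
  X <- lag_matrix(c(1, 0, 0), ls)
  expect_equal(X, rbind(c(1, 0), c(0, 1), c(0, 0)))
  expect_equal(lag_matrix(numeric(5), lag_spec(-100, 600, 256)),
               matrix(0, 5, 181))
  # negative lags look into the future
  lsn <- lag_spec(-2000 / 256, 0, 256)
  Xn <- lag_matrix(c(1, 2, 3), lsn)
  expect_equal(Xn[, 1], c(3, 0, 0))  # lag -2
})

test_that("ridge solution matches the dense normal-equation oracle", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 12), 40, 12)
    Y <- matrix(rnorm(40 * 3), 40, 3)
    lambda <- 10^runif(1, -3, 3)
    B <- fit_ridge(X, Y, lambda)
    # oracle: direct solve of the penalized normal equations
    Xa <- cbind(1, X)
    m <- mean(diag(crossprod(Xa))[-1])
    R <- diag(c(0, rep(1, 12)))
    B_or <- solve(crossprod(Xa) + lambda * m * R, crossprod(Xa, Y))
    expect_lt(max(abs(B - B_or)) / max(abs(B_or)), 1e-8)
  }
})

test_that("ridge limits: exact interpolation at 0, total shrinkage at Inf", {
  set.seed(2)
  X <- matrix(rnorm(60 * 8), 60, 8)
  W_true <- matrix(rnorm(8 * 2), 8, 2)
  Y <- X %*% W_true
  B0 <- fit_ridge(X, Y, 0)
  expect_lt(max(abs(B0[-1, ] - W_true)), 1e-8)
  Binf <- fit_ridge(X, Y, 1e12)
  expect_lt(max(abs(Binf[-1, ])), 1e-6)
  # rank-deficient design at lambda = 0 advises regularization
  Xd <- cbind(X, X[, 1])
  expect_error(fit_ridge(Xd, Y, 0), "lambda > 0")
  expect_error(fit_ridge(X, Y, -1), "nonnegative")
})

test_that("shrinkage of the penalized block is monotone in lambda", {
  set.seed(4)
  X <- matrix(rnorm(100 * 10), 100, 10)
  Y <- matrix(rnorm(100 * 2), 100, 2)
  norms <- vapply(10^seq(-4, 4), function(l) {
    norm(fit_ridge(X, Y, l)[-1, , drop = FALSE], "F")
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("LOO lambda search prefers minimal penalty on noiseless data", {
  d <- tiny_sim(seed = 5, snr_db = Inf, n_subjects = 1, n_items = 5)
  lags <- lag_spec(-100, 600, 64)
  sr <- loo_lambda_search(d$envelopes, d$responses$natural[[1]], lags,
                          grid = 10^seq(-4, 4), zscore = FALSE, tol = 0)
  # cv-mse nondecreasing above the minimizer; minimizer at the small end
  i0 <- which.min(sr$curve$cv_mse)
  expect_lte(sr$curve$lambda[i0], 1e-2)
  upper <- sr$curve$cv_mse[i0:nrow(sr$curve)]
  expect_true(all(diff(upper) >= -1e-10))
  expect_error(loo_lambda_search(d$envelopes, d$responses$natural[[1]], lags,
                                 grid = c(-1, 1)), "nonnegative")
  expect_error(loo_lambda_search(d$envelopes[1], d$responses$natural[[1]],
                                 lags), "one envelope per item")
})

test_that("joint selection averages condition curves over a shared grid", {
  grid <- 10^(-2:2)
  mk <- function(mse) {
    structure(list(curve = tibble::tibble(lambda = grid, cv_mse = mse,
                                          cv_r = rep(0.1, 5)),
                   best_lambda = grid[which.min(mse)], grid = grid,
                   n_items = 5, tol = 0),
              class = "lambda_search")
  }
  a <- mk(c(5, 1, 2, 3, 4)); b <- mk(c(5, 4, 1, 3, 4))
  j <- select_lambda_joint(list(a, b))
  expect_equal(j$curve$cv_mse, c(5, 2.5, 1.5, 3, 4))
  expect_equal(j$best_lambda, grid[3])
  b2 <- mk(c(5, 4, 1, 3, 4)); b2$grid <- 10^(-1:3); b2$curve$lambda <- b2$grid
  expect_error(select_lambda_joint(list(a, b2)), "grids differ")
})

test_that("prediction metrics behave at the exact and degenerate limits", {
  set.seed(6)
  a <- matrix(rnorm(50 * 3), 50, 3)
  m <- score_prediction(a, a)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$mse, 0)
  m2 <- score_prediction(-a, a)
  expect_equal(m2$pearson_r, -1)
  # constant prediction: r is NA, not 0
  m3 <- score_prediction(matrix(2, 50, 1), a[, 1, drop = FALSE])
  expect_true(is.na(m3$per_channel$r[1]))
})

test_that("grand averaging is the element-wise mean with axis checks", {
  d <- tiny_sim(seed = 9, n_subjects = 2)
  lags <- lag_spec(-100, 600, 64)
  m1 <- fit_trf(d$envelopes, d$responses$natural[[1]], lags, 1)
  m2 <- fit_trf(d$envelopes, d$responses$natural[[2]], lags, 1)
  expect_equal(grand_average(list(m1))$weights, m1$weights)
  ga <- grand_average(list(m1, m2))
  expect_equal(ga$weights, (m1$weights + m2$weights) / 2)
  m_neg <- m1; m_neg$weights <- -m1$weights
  expect_equal(max(abs(grand_average(list(m1, m_neg))$weights)), 0)
  m3 <- m2; m3$channels <- rev(m3$channels)
  expect_error(grand_average(list(m1, m3)), "mismatched")
})

test_that("a fitted TRF predicts held-out responses above a shuffled one", {
  d <- tiny_sim(seed = 13, n_subjects = 1, n_items = 6, snr_db = 0,
                n_reps = 50)
  lags <- lag_spec(-100, 600, 64)
  ep <- baseline_normalize(d$responses$natural[[1]])
  valid <- loo_metrics(d$envelopes, ep, lags, lambda = 0.1)
  shuf <- loo_metrics(d$envelopes, ep, lags, lambda = 0.1,
                      mapping = shuffle_pairing(6, seed = 3))
  expect_gt(valid$pearson_r, shuf$pearson_r)
  expect_lt(valid$mse, shuf$mse)
})
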