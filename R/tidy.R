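# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a TRF model into a long tibble
#'
#' @param x a `trf`.
#' @param ... unused.
#' @return tibble: `channel`, `lag_ms`, `weight`, `subject`, `condition`.
#' @export
tidy.trf <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channels, times = ncol(x$weights)),
    lag_ms = rep(x$lags$times_ms, each = nrow(x$weights)),
    weight = as.numeric(x$weights),
    subject = x$subject %||% NA,
    condition = x$condition %||% NA)
}

#' One-row summary of a TRF model
#'
#' @inheritParams tidy.trf
#' @return tibble: `n_channels`, `n_lags`, `t_min`, `t_max`, `lambda`,
#'   `subject`, `condition`.
#' @export
glance.trf <- function(x, ...) {
  tibble::tibble(n_channels = nrow(x$weights), n_lags = ncol(x$weights),
                 t_min = x$lags$t_min, t_max = x$lags$t_max,
                 lambda = x$lambda, subject = x$subject %||% NA,
                 condition = x$condition %||% NA)
}

#' Tidy a lambda search into its cross-validation curve
#'
#' @param x a `lambda_search`.
#' @param ... unused.
#' @return tibble: `lambda`, `cv_mse`, `cv_r`.
#' @export
tidy.lambda_search <- function(x, ...) x$curve

#' One-row summary of a lambda search
#'
#' @inheritParams tidy.lambda_search
#' @return tibble: `best_lambda`, `min_cv_mse`, `n_grid`, `n_items`.
#' @export
glance.lambda_search <- function(x, ...) {
  tibble::tibble(best_lambda = x$best_lambda,
                 min_cv_mse = min(x$curve$cv_mse),
                 n_grid = length(x$grid), n_items = x$n_items)
}

#' Tidy a permutation result into its per-window tests
#'
#' @param x a `perm_result`.
#' @param ... unused.
#' @return the valid-vs-shuffled amplitude test tibble.
#' @export
tidy.perm_result <- function(x, ...) x$amp_tests

#' One-row summary of a permutation result
#'
#' @inheritParams tidy.perm_result
#' @return tibble: `n_windows`, `n_shuffles`, `all_sig`.
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(n_windows = nrow(x$windows), n_shuffles = x$n_shuffles,
                 all_sig = all(x$amp_tests$sig))
}
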