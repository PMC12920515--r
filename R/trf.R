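# Forward (encoding) TRF estimation: lagged design matrices, ridge
# regression with scale-invariant regularization, leave-one-out lambda
# search, prediction metrics, grand averaging.

#' Lag specification for TRF estimation
#'
#' Lag indices run from `floor(t_min/1000 * fs)` to `ceiling(t_max/1000 *
#' fs)` inclusive (mTRF convention). The standard window of -100 to 600 ms at
#' 256 Hz gives indices -26..154, i.e. 181 lags.
#'
#' @param t_min,t_max lag window in milliseconds (defaults -100, 600).
#' @param sample_rate sampling rate in Hz (default 256).
#' @return object of class `lag_spec` with `lag_idx` (integer samples) and
#'   `times_ms`.
#' @export
lag_spec <- function(t_min = -100, t_max = 600, sample_rate = 256) {
  stopifnot(t_min < t_max)
  idx <- seq.int(floor(t_min / 1000 * sample_rate),
                 ceiling(t_max / 1000 * sample_rate))
  structure(list(t_min = t_min, t_max = t_max, sample_rate = sample_rate,
                 lag_idx = idx, times_ms = idx / sample_rate * 1000),
            class = "lag_spec")
}

#' @export
print.lag_spec <- function(x, ...) {
  cat(sprintf("<lag_spec> %g..%g ms @ %g Hz: %d lags (indices %d..%d)\n",
              x$t_min, x$t_max, x$sample_rate, length(x$lag_idx),
              min(x$lag_idx), max(x$lag_idx)))
  invisible(x)
}

#' Lagged (time-delayed) design matrix
#'
#' Column j holds the stimulus delayed by `lags$lag_idx[j]` samples,
#' zero-padded outside the epoch, so the response at time t is modeled
#' from the stimulus at t - tau.
#'
#' @param envelope numeric stimulus vector (or [envelope_signal()]).
#' @param lags a [lag_spec()]; when `envelope` is an [envelope_signal()]
#'   its rate must match.
#' @return matrix `[n_times x n_lags]`.
#' @export
lag_matrix <- function(envelope, lags) {
  stopifnot(inherits(lags, "lag_spec"))
  if (inherits(envelope, "envelope")) {
    if (envelope$sample_rate != lags$sample_rate) {
      stop("envelope rate (", envelope$sample_rate,
           ") does not match lag_spec rate (", lags$sample_rate, ")")
    }
    envelope <- envelope$values
  }
  s <- as.numeric(envelope)
  n <- length(s)
  X <- matrix(0, n, length(lags$lag_idx))
  for (j in seq_along(lags$lag_idx)) {
    k <- lags$lag_idx[j]
    lo <- max(1L, 1L + k); hi <- min(n, n + k)
    if (lo > hi) next
    t_dst <- lo:hi
    X[t_dst, j] <- s[t_dst - k]
  }
  X
}

# Ridge normal-equation solve with scale-invariant regularization:
# A = XtX + lambda * m * R, m = mean diagonal of the penalized block,
# R = identity on penalized rows (intercept unpenalized).
ridge_solve <- function(XtX, XtY, lambda, pen = seq_len(nrow(XtX))) {
  if (lambda < 0) stop("lambda must be nonnegative")
  m <- mean(diag(XtX)[pen])
  A <- XtX
  diag(A)[pen] <- diag(A)[pen] + lambda * m
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    stop("normal equations are singular (rank-deficient design at lambda = ",
         lambda, "); use lambda > 0")
  }
  chol2inv(ch) %*% XtY
}

#' Ridge-regression TRF fit for one design/response pair
#'
#' Solves `W = (X'X + lambda * m * I)^-1 X'Y` where `m` is the mean
#' diagonal of the penalized block of `X'X`, making the lambda grid
#' invariant to stimulus scale. An unpenalized intercept column is
#' prepended when `intercept = TRUE`.
#'
#' @param X design matrix `[n_times x n_lags]` (see [lag_matrix()]).
#' @param Y response matrix `[n_times x n_channels]`.
#' @param lambda ridge parameter (>= 0).
#' @param intercept include an unpenalized intercept (default TRUE).
#' @return coefficient matrix `[(n_lags + intercept) x n_channels]`; with
#'   an intercept its first row holds the intercepts.
#' @export
fit_ridge <- function(X, Y, lambda, intercept = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  Xa <- if (intercept) cbind(1, X) else X
  pen <- if (intercept) 1L + seq_len(ncol(X)) else seq_len(ncol(X))
  ridge_solve(crossprod(Xa), crossprod(Xa, Y), lambda, pen)
}

new_trf <- function(weights, intercept, lags, lambda, channels,
                    condition = NULL, subject = NULL, zscale = NULL) {
  stopifnot(is.matrix(weights), ncol(weights) == length(lags$lag_idx),
            nrow(weights) == length(channels), all(is.finite(weights)))
  structure(list(weights = weights, intercept = intercept, lags = lags,
                 lambda = lambda, channels = channels, condition = condition,
                 subject = subject, zscale = zscale),
            class = "trf")
}

#' @export
print.trf <- function(x, ...) {
  cat(sprintf("<trf%s%s> %d channels x %d lags (%g..%g ms), lambda = %g\n",
              if (!is.null(x$condition)) paste0(": ", x$condition) else "",
              if (!is.null(x$subject)) paste0(" / ", x$subject) else "",
              nrow(x$weights), ncol(x$weights), x$lags$t_min, x$lags$t_max,
              x$lambda))
  invisible(x)
}

# Per-item z-scored design/response blocks plus their crossproducts.
# Envelopes shorter than the epoch are placed on the epoch timeline
# (zeros before stimulus onset).
prepare_trf_blocks <- function(envelopes, responses, lags, zscore = TRUE) {
  stopifnot(inherits(responses, "eeg_epochs"))
  if (responses$sample_rate != lags$sample_rate) {
    stop("response rate does not match lag_spec rate")
  }
  d <- dim(responses$data)
  if (!is.list(envelopes)) envelopes <- list(envelopes)
  if (length(envelopes) != d[1]) {
    stop("need one envelope per item: got ", length(envelopes),
         " envelopes for ", d[1], " items")
  }
  items <- lapply(seq_len(d[1]), function(i) {
    s <- envelope_on_epoch(envelopes[[i]], responses)
    y <- t(responses$data[i, , ])               # time x channels
    zs <- list(env_mean = 0, env_sd = 1, resp_mean = 0, resp_sd = 1)
    if (zscore) {
      zs$env_mean <- mean(s); zs$env_sd <- stats::sd(s)
      if (zs$env_sd > 0) s <- (s - zs$env_mean) / zs$env_sd
      zs$resp_mean <- mean(y); zs$resp_sd <- stats::sd(as.numeric(y))
      if (zs$resp_sd > 0) y <- (y - zs$resp_mean) / zs$resp_sd
    }
    Xa <- cbind(1, lag_matrix(s, lags))
    list(Xa = Xa, Y = y, XtX = crossprod(Xa), XtY = crossprod(Xa, y),
         zscale = zs)
  })
  items
}

#' Place an envelope on the epoch timeline
#'
#' Returns a vector of the epoch's length with zeros before stimulus onset
#' and the envelope values from t = 0 onward (truncated or zero-padded to
#' the post-onset span).
#'
#' @param envelope numeric vector or [envelope_signal()].
#' @param epochs an [eeg_epochs()] defining the timeline.
#' @return numeric vector of length `n_times`.
#' @export
envelope_on_epoch <- function(envelope, epochs) {
  v <- if (inherits(envelope, "envelope")) envelope$values else as.numeric(envelope)
  n <- dim(epochs$data)[3]
  if (length(v) == n) return(v)
  pre <- round(-epochs$window[1] * epochs$sample_rate)
  out <- numeric(n)
  k <- min(length(v), n - pre)
  if (k > 0) out[pre + seq_len(k)] <- v[seq_len(k)]
  out
}

#' Fit a subject/condition TRF from per-item envelopes and responses
#'
#' Envelope and response are z-scored per item before fitting (the
#' constants are recorded in the model), per-item lagged designs are
#' stacked, and the ridge solution is computed with an unpenalized
#' intercept.
#'
#' @param envelopes list of per-item envelopes ([envelope_signal()] or
#'   numeric vectors), in the same order as the response items.
#' @param responses an [eeg_epochs()] (typically `averaged = TRUE`) with
#'   one entry per item.
#' @param lags a [lag_spec()].
#' @param lambda ridge parameter.
#' @param zscore z-score stimulus and response per item (default TRUE).
#' @return a `trf` model: weights `[n_channels x n_lags]` plus intercept,
#'   lambda and z-scoring record.
#' @export
fit_trf <- function(envelopes, responses, lags = lag_spec(), lambda,
                    zscore = TRUE) {
  blocks <- prepare_trf_blocks(envelopes, responses, lags, zscore)
  XtX <- Reduce(`+`, lapply(blocks, `[[`, "XtX"))
  XtY <- Reduce(`+`, lapply(blocks, `[[`, "XtY"))
  B <- ridge_solve(XtX, XtY, lambda, pen = 1L + seq_len(ncol(XtX) - 1L))
  zs <- do.call(rbind, lapply(blocks, function(b) as.data.frame(b$zscale)))
  zs <- tibble::as_tibble(cbind(item = seq_along(blocks), zs))
  new_trf(t(B[-1, , drop = FALSE]), intercept = B[1, ], lags = lags,
          lambda = lambda, channels = responses$channels,
          condition = responses$condition, subject = responses$subject,
          zscale = zs)
}

#' Default ridge-parameter grid
#'
#' Powers of ten spanning 1e-6..1e6 (13 values); `per_decade` refines the
#' grid within the same range.
#'
#' @param from,to grid bounds (defaults 1e-6 and 1e6).
#' @param per_decade grid points per decade (default 1).
#' @return numeric vector of lambda values.
#' @export
lambda_grid <- function(from = 1e-6, to = 1e6, per_decade = 1) {
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

#' Leave-one-out cross-validated lambda search
#'
#' For every lambda in the grid, each item is held out in turn: the TRF is
#' fitted on the remaining items and used to predict the held-out EEG from
#' its envelope. Performance is the mean squared error averaged across
#' channels (and the mean per-channel Pearson correlation), averaged over
#' folds. The best lambda minimizes the cross-validated MSE.
#'
#' Among lambdas whose cross-validated MSE is within `tol` (relative) of
#' the minimum, the largest is selected: prediction-equivalent solutions
#' resolve to the most regularized (smoothest) model, a one-standard-
#' error-style parsimony rule that matters when held-out noise is too
#' small to penalize unidentified high-frequency weight components.
#'
#' @inheritParams fit_trf
#' @param grid nonnegative lambda values (default [lambda_grid()]).
#' @param tol relative MSE tolerance for the parsimony tie-break
#'   (default 0.01).
#' @return object of class `lambda_search`: list with `curve` (tibble:
#'   lambda, cv_mse, cv_r), `best_lambda` and `grid`.
#' @export
loo_lambda_search <- function(envelopes, responses, lags = lag_spec(),
                              grid = lambda_grid(), zscore = TRUE,
                              tol = 0.01) {
  if (length(grid) == 0) stop("lambda grid is empty")
  if (any(grid < 0)) stop("lambda grid values must be nonnegative")
  blocks <- prepare_trf_blocks(envelopes, responses, lags, zscore)
  n_items <- length(blocks)
  if (n_items < 2) stop("leave-one-out search needs at least 2 items")
  XtX_all <- Reduce(`+`, lapply(blocks, `[[`, "XtX"))
  XtY_all <- Reduce(`+`, lapply(blocks, `[[`, "XtY"))
  pen <- 1L + seq_len(ncol(XtX_all) - 1L)
  mse <- matrix(NA_real_, length(grid), n_items)
  rr <- matrix(NA_real_, length(grid), n_items)
  for (i in seq_len(n_items)) {
    XtX_tr <- XtX_all - blocks[[i]]$XtX
    XtY_tr <- XtY_all - blocks[[i]]$XtY
    for (g in seq_along(grid)) {
      B <- ridge_solve(XtX_tr, XtY_tr, grid[g], pen)
      pred <- blocks[[i]]$Xa %*% B
      met <- score_prediction(pred, blocks[[i]]$Y)
      mse[g, i] <- met$mse
      rr[g, i] <- met$pearson_r
    }
  }
  curve <- tibble::tibble(lambda = grid,
                          cv_mse = rowMeans(mse),
                          cv_r = rowMeans(rr, na.rm = TRUE))
  structure(list(curve = curve,
                 best_lambda = pick_lambda(grid, curve$cv_mse, tol),
                 grid = grid, n_items = n_items, tol = tol),
            class = "lambda_search")
}

# largest lambda with cv_mse within (1 + tol) of the minimum
pick_lambda <- function(grid, cv_mse, tol) {
  max(grid[cv_mse <= min(cv_mse) * (1 + tol)])
}

#' @export
print.lambda_search <- function(x, ...) {
  cat(sprintf("<lambda_search> %d grid points, best lambda = %g (cv MSE %.4f)\n",
              length(x$grid), x$best_lambda,
              min(x$curve$cv_mse)))
  invisible(x)
}

#' Joint lambda selection across conditions
#'
#' Averages the cross-validated MSE curves of several searches (e.g. the
#' natural and vocoded conditions, each already averaged over subjects)
#' and picks the lambda minimizing the joint curve — one regularization
#' strength shared by all conditions.
#'
#' @param searches list of `lambda_search` objects over identical grids.
#' @return a `lambda_search` whose curve is the across-search mean.
#' @export
select_lambda_joint <- function(searches) {
  stopifnot(length(searches) >= 1)
  grids <- lapply(searches, `[[`, "grid")
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])), logical(1)))) {
    stop("lambda grids differ across searches")
  }
  mse <- rowMeans(vapply(searches, function(s) s$curve$cv_mse,
                         numeric(length(grids[[1]]))))
  rr <- rowMeans(vapply(searches, function(s) s$curve$cv_r,
                        numeric(length(grids[[1]]))))
  tol <- searches[[1]]$tol %||% 0.01
  curve <- tibble::tibble(lambda = grids[[1]], cv_mse = mse, cv_r = rr)
  structure(list(curve = curve,
                 best_lambda = pick_lambda(grids[[1]], mse, tol),
                 grid = grids[[1]],
                 n_items = searches[[1]]$n_items, tol = tol),
            class = "lambda_search")
}

#' Predict EEG from an envelope with a fitted TRF
#'
#' @param object a `trf` model.
#' @param envelope stimulus envelope (numeric or [envelope_signal()]); it
#'   is z-scored with its own mean/sd when the model was fitted with
#'   z-scoring.
#' @param ... unused.
#' @return predicted response matrix `[n_times x n_channels]` in the
#'   model's (normalized) response units.
#' @export
predict.trf <- function(object, envelope, ...) {
  s <- if (inherits(envelope, "envelope")) envelope$values else as.numeric(envelope)
  if (!is.null(object$zscale)) {
    mu <- mean(s); sdv <- stats::sd(s)
    if (is.finite(sdv) && sdv > 0) s <- (s - mu) / sdv
  }
  X <- lag_matrix(s, object$lags)
  pred <- X %*% t(object$weights)
  pred <- sweep(pred, 2, object$intercept, `+`)
  colnames(pred) <- object$channels
  pred
}

#' Prediction performance metrics
#'
#' Mean squared error and Pearson correlation per channel, then averaged
#' across channels. A constant prediction or constant actual signal makes
#' the correlation undefined; such channels are reported as `NA` (never
#' coerced to 0) and dropped from the channel average.
#'
#' @param pred,actual matrices `[n_times x n_channels]`.
#' @return list of class `pred_metrics`: `mse`, `pearson_r` (channel
#'   means) and `per_channel` tibble.
#' @export
score_prediction <- function(pred, actual) {
  pred <- as.matrix(pred); actual <- as.matrix(actual)
  stopifnot(all(dim(pred) == dim(actual)))
  mse_ch <- colMeans((pred - actual)^2)
  r_ch <- vapply(seq_len(ncol(pred)), function(j) {
    sp <- stats::sd(pred[, j]); sa <- stats::sd(actual[, j])
    if (!is.finite(sp) || !is.finite(sa) || sp == 0 || sa == 0) return(NA_real_)
    stats::cor(pred[, j], actual[, j])
  }, numeric(1))
  structure(list(mse = mean(mse_ch),
                 pearson_r = if (all(is.na(r_ch))) NA_real_ else mean(r_ch, na.rm = TRUE),
                 per_channel = tibble::tibble(channel = seq_len(ncol(pred)),
                                              mse = mse_ch, r = r_ch)),
            class = "pred_metrics")
}

#' Grand-average TRF across models
#'
#' Element-wise mean of the weights (and intercepts) of models sharing the
#' same lag specification and channel set.
#'
#' @param models list of `trf` objects.
#' @return a `trf` with `subject = "grand_average"`.
#' @export
grand_average <- function(models) {
  stopifnot(length(models) >= 1, all(vapply(models, inherits, logical(1), "trf")))
  ref <- models[[1]]
  for (m in models[-1]) {
    if (!identical(m$lags$lag_idx, ref$lags$lag_idx) ||
        !identical(m$channels, ref$channels)) {
      stop("models have mismatched lag or channel axes")
    }
  }
  W <- Reduce(`+`, lapply(models, `[[`, "weights")) / length(models)
  ic <- Reduce(`+`, lapply(models, `[[`, "intercept")) / length(models)
  new_trf(W, ic, ref$lags, ref$lambda, ref$channels,
          condition = ref$condition, subject = "grand_average")
}
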