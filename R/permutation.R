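# Stimulus-shuffling permutation validation: derangement pairing, a
# shuffled-pipeline null, and valid-vs-shuffled comparisons of component
# amplitudes and prediction metrics.

#' Uniformly sampled derangement of item indices
#'
#' A permutation with no fixed points, so no envelope stays paired with
#' its own EEG ("shuffled" pairing that cannot leak true coupling).
#' Sampled by rejection from uniform permutations, which is uniform over
#' derangements.
#'
#' @param n_items number of items (>= 2).
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @return integer permutation vector with `mapping[i] != i` for all i.
#' @export
shuffle_pairing <- function(n_items, seed = NULL) {
  if (n_items < 2) stop("need at least 2 items to shuffle")
  with_seed(seed, {
    repeat {
      p <- sample.int(n_items)
      if (!any(p == seq_len(n_items))) return(p)
    }
  })
}

# The one pipeline used for both arms: fit a TRF with an explicit
# envelope-to-item mapping. The identity mapping reproduces the valid fit
# bit for bit; a derangement gives the shuffled fit.
fit_trf_mapped <- function(envelopes, responses, lags, lambda,
                           mapping = seq_along(envelopes), zscore = TRUE) {
  stopifnot(length(mapping) == length(envelopes),
            all(sort(mapping) == seq_along(envelopes)))
  fit_trf(envelopes[mapping], responses, lags, lambda, zscore = zscore)
}

#' Leave-one-out prediction metrics at a fixed lambda
#'
#' Fits on all-but-one item, predicts the held-out EEG from its envelope,
#' and averages MSE and Pearson r over folds (and channels).
#'
#' @inheritParams fit_trf
#' @param mapping optional envelope-to-item permutation (the shuffled arm
#'   uses a derangement; default identity).
#' @return one-row tibble: `mse`, `pearson_r`.
#' @export
loo_metrics <- function(envelopes, responses, lags = lag_spec(), lambda,
                        mapping = seq_along(envelopes), zscore = TRUE) {
  stopifnot(all(sort(mapping) == seq_along(envelopes)))
  blocks <- prepare_trf_blocks(envelopes[mapping], responses, lags, zscore)
  n_items <- length(blocks)
  if (n_items < 2) stop("leave-one-out metrics need at least 2 items")
  XtX_all <- Reduce(`+`, lapply(blocks, `[[`, "XtX"))
  XtY_all <- Reduce(`+`, lapply(blocks, `[[`, "XtY"))
  pen <- 1L + seq_len(ncol(XtX_all) - 1L)
  mse <- numeric(n_items); rr <- numeric(n_items)
  for (i in seq_len(n_items)) {
    B <- ridge_solve(XtX_all - blocks[[i]]$XtX, XtY_all - blocks[[i]]$XtY,
                     lambda, pen)
    met <- score_prediction(blocks[[i]]$Xa %*% B, blocks[[i]]$Y)
    mse[i] <- met$mse; rr[i] <- met$pearson_r
  }
  tibble::tibble(mse = mean(mse), pearson_r = mean(rr, na.rm = TRUE))
}

#' Permutation validation of TRF components
#'
#' For every subject and condition, a valid TRF (true envelope-EEG
#' pairing) and a shuffled TRF (derangement pairing, averaged over
#' `n_shuffles` draws) are fitted with the identical pipeline and the
#' same lambda. Component amplitudes (peak GFP within each window) and
#' leave-one-out prediction metrics of the two arms are compared by
#' two-tailed paired t-tests with BH-FDR correction (one family across
#' windows x conditions; one across metrics x conditions).
#'
#' @param envelopes list of per-item envelopes (shared across subjects).
#' @param responses named list `(natural, vocoded)`, each a list of
#'   [eeg_epochs()] per subject (conditions may be any subset, but must
#'   contain the same subjects).
#' @param lags a [lag_spec()].
#' @param lambda ridge parameter (reused for the shuffled fits: identical
#'   pipeline, only the pairing differs).
#' @param windows component windows tibble (default [component_windows()]).
#' @param n_shuffles shuffled TRFs averaged per subject (default 1).
#' @param seed integer seed for the derangements.
#' @param alpha FDR level.
#' @param zscore passed to the fits.
#' @param compute_metrics also compute LOO prediction metrics (default
#'   TRUE; the fits are the slow part).
#' @return list of class `perm_result`: `amplitudes`, `amp_tests`,
#'   `metrics`, `metric_tests`, `windows`, `n_shuffles`.
#' @export
run_permutation <- function(envelopes, responses, lags = lag_spec(), lambda,
                            windows = component_windows(), n_shuffles = 1,
                            seed = 1L, alpha = 0.05, zscore = TRUE,
                            compute_metrics = TRUE) {
  stopifnot(n_shuffles >= 1, is.list(responses), length(responses) >= 1)
  n_items <- length(envelopes)
  amp <- list(); met <- list()
  draw <- 0L
  for (cond in names(responses)) {
    subs <- responses[[cond]]
    for (s in seq_along(subs)) {
      valid <- fit_trf_mapped(envelopes, subs[[s]], lags, lambda,
                              zscore = zscore)
      gv <- gfp(valid)
      sh_w <- 0; sh_maps <- vector("list", n_shuffles)
      for (k in seq_len(n_shuffles)) {
        draw <- draw + 1L
        sh_maps[[k]] <- shuffle_pairing(n_items, seed = seed + 7919L * draw)
        sh <- fit_trf_mapped(envelopes, subs[[s]], lags, lambda,
                             mapping = sh_maps[[k]], zscore = zscore)
        sh_w <- sh_w + sh$weights / n_shuffles
      }
      shuffled <- valid; shuffled$weights <- sh_w
      gs <- gfp(shuffled)
      for (w in seq_len(nrow(windows))) {
        sel <- gv$lag_ms >= windows$t_start[w] & gv$lag_ms <= windows$t_end[w]
        if (!any(sel)) stop("window ", windows$name[w],
                            " contains no lag samples")
        amp[[length(amp) + 1L]] <- tibble::tibble(
          subject = subs[[s]]$subject %||% paste0("sub", s),
          condition = cond, window = windows$name[w],
          valid_amp = max(gv$gfp[sel]), shuffled_amp = max(gs$gfp[sel]))
      }
      if (compute_metrics) {
        mv <- loo_metrics(envelopes, subs[[s]], lags, lambda, zscore = zscore)
        ms <- loo_metrics(envelopes, subs[[s]], lags, lambda,
                          mapping = sh_maps[[1]], zscore = zscore)
        met[[length(met) + 1L]] <- tibble::tibble(
          subject = subs[[s]]$subject %||% paste0("sub", s),
          condition = cond,
          valid_r = mv$pearson_r, shuffled_r = ms$pearson_r,
          valid_mse = mv$mse, shuffled_mse = ms$mse)
      }
    }
  }
  amplitudes <- dplyr::bind_rows(amp)
  amp_tests <- amplitudes |>
    dplyr::group_by(.data$condition, .data$window) |>
    dplyr::summarise(paired_t(.data$valid_amp, .data$shuffled_amp),
                     .groups = "drop")
  fdr <- fdr_bh(amp_tests$p, alpha)
  amp_tests$q <- fdr$q; amp_tests$sig <- fdr$sig
  metrics <- if (compute_metrics) dplyr::bind_rows(met) else NULL
  metric_tests <- NULL
  if (compute_metrics) {
    metric_tests <- metrics |>
      dplyr::group_by(.data$condition) |>
      dplyr::reframe(
        dplyr::bind_rows(
          cbind(metric = "pearson_r",
                paired_t(.data$valid_r, .data$shuffled_r)),
          cbind(metric = "mse",
                paired_t(.data$valid_mse, .data$shuffled_mse))))
    fdr2 <- fdr_bh(metric_tests$p, alpha)
    metric_tests$q <- fdr2$q; metric_tests$sig <- fdr2$sig
  }
  structure(list(amplitudes = amplitudes, amp_tests = amp_tests,
                 metrics = metrics, metric_tests = metric_tests,
                 windows = windows, n_shuffles = n_shuffles),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("<perm_result> valid vs shuffled component amplitudes\n")
  print(x$amp_tests)
  if (!is.null(x$metric_tests)) {
    cat("prediction metrics:\n")
    print(x$metric_tests)
  }
  invisible(x)
}
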