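# EEG conditioning: FIR band-pass, resampling, epoching, repetition
# averaging, pooled baseline normalization, alpha-power control metric.

#' Epoched EEG container
#'
#' @param data numeric array `[n_epochs x n_channels x n_times]`.
#' @param sample_rate sampling rate in Hz.
#' @param window epoch window `c(t_min, t_max)` in seconds relative to
#'   stimulus onset; the standard window is `c(-0.5, 2.5)` (3 s). The
#'   sample at t = 0 belongs to the epoch; windows are half-open
#'   `[t_min, t_max)`, so `n_times = round((t_max - t_min) * sample_rate)`.
#' @param channels unique channel labels, length `n_channels`.
#' @param condition condition tag, e.g. `"natural"` or `"vocoded"`.
#' @param subject subject identifier.
#' @param items per-epoch item (sentence) labels, length `n_epochs`, or
#'   `NULL`.
#' @param averaged logical: `TRUE` when each "epoch" is a per-item average
#'   of repetitions.
#' @return object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, sample_rate, window = c(-0.5, 2.5),
                       channels = NULL, condition = NULL, subject = NULL,
                       items = NULL, averaged = FALSE) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_times_expect <- round(diff(window) * sample_rate)
  if (dim(data)[3] != n_times_expect) {
    stop("n_times (", dim(data)[3], ") does not match window: expected ",
         n_times_expect)
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (length(channels) != dim(data)[2]) stop("channel labels do not match data")
  if (!is.null(items) && length(items) != dim(data)[1]) {
    stop("items must have one label per epoch")
  }
  structure(list(data = data, sample_rate = sample_rate, window = window,
                 channels = channels, condition = condition,
                 subject = subject, items = items, averaged = averaged),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs%s> %d %s x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              if (!is.null(x$condition)) paste0(": ", x$condition) else "",
              d[1], if (isTRUE(x$averaged)) "item averages" else "epochs",
              d[2], d[3], x$sample_rate, x$window[1], x$window[2]))
  invisible(x)
}

#' Epoch sample times
#'
#' @param epochs an [eeg_epochs()].
#' @return numeric vector of sample times in seconds (length `n_times`).
#' @export
epoch_times <- function(epochs) {
  n <- dim(epochs$data)[3]
  epochs$window[1] + (seq_len(n) - 1) / epochs$sample_rate
}

#' Zero-phase FIR band-pass filter
#'
#' Linear-phase windowed-sinc (Hamming) band-pass with compensated group
#' delay, as used for continuous EEG (default band 1-57 Hz). Stop-band
#' attenuation is ~53 dB; `trans_hz` sets the transition width and hence
#' the filter length (~3.3 fs / trans_hz taps), so the input must be
#' longer than the filter.
#'
#' @param x numeric vector, or matrix with time in rows.
#' @param sample_rate sampling rate in Hz.
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @param trans_hz transition bandwidth in Hz (default 1).
#' @return filtered data, same shape as `x`.
#' @export
bandpass_fir <- function(x, sample_rate, low = 1, high = 57, trans_hz = 1) {
  b <- design_fir_bandpass(sample_rate, low, high, trans_hz)
  apply_fir_zerophase(x, b)
}

#' Anti-aliased resampling
#'
#' Rational (polyphase) resampling; output length is
#' `round(n * to_rate / from_rate)`. A typical use is taking a 2048 Hz
#' recording down to 256 Hz (an exact factor of 8).
#'
#' @param x numeric vector, or matrix with time in rows.
#' @param from_rate,to_rate rates in Hz.
#' @return resampled data.
#' @export
resample_signal <- function(x, from_rate, to_rate) {
  filt_time(x, function(v) resample_vec(v, from_rate, to_rate))
}

#' Cut continuous EEG into stimulus-locked epochs
#'
#' The sample at t = 0 is the onset sample; the epoch covers the half-open
#' window `[t_min, t_max)`, i.e. `round((t_max - t_min) * fs)` samples
#' starting `round(-t_min * fs)` samples before the onset.
#'
#' @param x continuous data, matrix `[n_times x n_channels]`.
#' @param onsets stimulus onset sample indices (1-based).
#' @param sample_rate sampling rate in Hz.
#' @param window epoch window in seconds, default `c(-0.5, 2.5)`.
#' @inheritParams eeg_epochs
#' @return an [eeg_epochs()]; zero onsets give an empty epoch set.
#' @export
epoch_data <- function(x, onsets, sample_rate, window = c(-0.5, 2.5),
                       channels = NULL, condition = NULL, subject = NULL,
                       items = NULL) {
  stopifnot(is.matrix(x))
  n_times <- round(diff(window) * sample_rate)
  pre <- round(-window[1] * sample_rate)
  starts <- as.integer(onsets) - pre
  bad <- starts < 1L | (starts + n_times - 1L) > nrow(x)
  if (any(bad)) {
    stop("epoch window exceeds recording bounds for onset(s): ",
         paste(onsets[bad], collapse = ", "))
  }
  dat <- array(0, dim = c(length(onsets), ncol(x), n_times))
  for (i in seq_along(onsets)) {
    dat[i, , ] <- t(x[starts[i]:(starts[i] + n_times - 1L), , drop = FALSE])
  }
  eeg_epochs(dat, sample_rate, window, channels, condition, subject, items)
}

#' Average repetitions into per-item responses
#'
#' Averages all epochs sharing an item label, then band-pass filters the
#' averages (default band 1-15 Hz, zero-phase). On a 3 s epoch a
#' narrow-transition FIR does not fit, so the post-average filter is a
#' 4th-order zero-phase Butterworth.
#'
#' @param epochs an [eeg_epochs()] with item labels (or `item_labels`
#'   supplied here).
#' @param item_labels optional per-epoch item labels overriding
#'   `epochs$items`.
#' @param band post-average band-pass edges in Hz; `NULL` skips filtering.
#' @return an [eeg_epochs()] with `averaged = TRUE`, one "epoch" per
#'   distinct item (in order of first appearance).
#' @export
average_repetitions <- function(epochs, item_labels = NULL, band = c(1, 15)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  labels <- if (is.null(item_labels)) epochs$items else item_labels
  if (is.null(labels) || anyNA(labels)) {
    stop("every epoch must carry an item label")
  }
  if (length(labels) != dim(epochs$data)[1]) {
    stop("item labels must match the number of epochs")
  }
  uniq <- unique(labels)
  d <- dim(epochs$data)
  out <- array(0, dim = c(length(uniq), d[2], d[3]))
  for (i in seq_along(uniq)) {
    idx <- which(labels == uniq[i])
    sub <- epochs$data[idx, , , drop = FALSE]
    out[i, , ] <- apply(sub, c(2, 3), mean)
    if (!is.null(band)) {
      out[i, , ] <- t(butter_bandpass_zp(t(out[i, , ]), epochs$sample_rate,
                                         band[1], band[2]))
    }
  }
  eeg_epochs(out, epochs$sample_rate, epochs$window, epochs$channels,
             epochs$condition, epochs$subject, items = uniq, averaged = TRUE)
}

#' Pooled baseline normalization
#'
#' One scalar mean and one scalar standard deviation are computed from all
#' pre-onset (t < 0) samples pooled across epochs and channels, then the
#' whole data set is shifted and scaled by them. Pooling (rather than
#' per-channel z-scoring) preserves the relative power differences across
#' channels. Idempotent up to numerical tolerance.
#'
#' @param epochs an [eeg_epochs()] whose window includes pre-onset time.
#' @return the normalized [eeg_epochs()].
#' @export
baseline_normalize <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  tt <- epoch_times(epochs)
  base_idx <- which(tt < 0)
  if (length(base_idx) == 0) stop("epoch window contains no baseline samples")
  base <- epochs$data[, , base_idx, drop = FALSE]
  mu <- mean(base)
  sigma <- stats::sd(as.numeric(base))
  if (!is.finite(sigma) || sigma < .Machine$double.eps^0.5 * max(1, abs(mu))) {
    stop("degenerate input: pooled baseline standard deviation is zero")
  }
  epochs$data <- (epochs$data - mu) / sigma
  epochs
}

#' Alpha-band power at parietal sites
#'
#' Welch power spectral density (1 s Hann segments, 50% overlap) per epoch
#' per site; the PSD is averaged within the alpha band and then over
#' epochs and sites. Used as an alertness control: condition effects on
#' the TRF should not be accompanied by alpha-power differences.
#'
#' @param epochs an [eeg_epochs()].
#' @param sites channel labels to average over (default Pz, POz).
#' @param band frequency band in Hz (default `c(8, 12)`).
#' @return scalar mean band power (input units^2/Hz).
#' @export
alpha_power <- function(epochs, sites = c("Pz", "POz"), band = c(8, 12)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  missing <- setdiff(sites, epochs$channels)
  if (length(missing) > 0) {
    stop("site(s) not present in channel labels: ",
         paste(missing, collapse = ", "))
  }
  fs <- epochs$sample_rate
  idx <- match(sites, epochs$channels)
  vals <- numeric(0)
  for (e in seq_len(dim(epochs$data)[1])) {
    for (ch in idx) {
      w <- welch_psd(epochs$data[e, ch, ], fs, seg_len = fs, overlap = 0.5)
      sel <- w$freq >= band[1] & w$freq <= band[2]
      vals <- c(vals, mean(w$psd[sel]))
    }
  }
  mean(vals)
}
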