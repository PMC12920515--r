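# Broadband speech-envelope front end: 128-band log-spaced auditory
# filterbank, sub-band envelopes, band average, resampling to the EEG rate.

#' Envelope signal container
#'
#' The broadband temporal envelope used as the TRF stimulus regressor s(t).
#'
#' @param values nonnegative numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @param source_id optional stimulus identifier.
#' @return object of class `envelope`.
#' @export
envelope_signal <- function(values, sample_rate, source_id = NULL) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("envelope values must be finite")
  if (any(values < 0)) stop("envelope values must be nonnegative")
  structure(list(values = values, sample_rate = sample_rate,
                 source_id = source_id),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %d samples @ %g Hz%s\n", length(x$values),
              x$sample_rate,
              if (is.null(x$source_id)) "" else paste0(" [", x$source_id, "]")))
  invisible(x)
}

#' Auditory spectrogram (linear filterbank approximation)
#'
#' Decomposes audio into `n_bands` logarithmically spaced sub-band
#' envelopes between `f_low` and `f_high` Hz: per band, 4th-order
#' zero-phase Butterworth band-pass, half-wave rectification, and a
#' `smooth_hz` low-pass. This is a linear approximation of a cochlear
#' model front end: no compressive nonlinearity is applied, which leaves
#' the band-averaged temporal envelope (the only quantity used downstream)
#' essentially unchanged.
#'
#' @param audio an [audio_wave()] with sample rate >= 8000 Hz.
#' @param n_bands number of sub-bands (default 128).
#' @param f_low,f_high filterbank span in Hz (defaults 90 and 4000).
#' @param smooth_hz envelope smoothing low-pass cutoff (default 30 Hz).
#' @return object of class `aud_spec`: list with `sub_band_envelopes`
#'   (`[n_bands x n_times]`, nonnegative), `band_centers` (Hz, increasing)
#'   and `sample_rate`.
#' @export
auditory_spectrogram <- function(audio, n_bands = 128, f_low = 90,
                                 f_high = 4000, smooth_hz = 30) {
  stopifnot(inherits(audio, "audio_wave"))
  fs <- audio$sample_rate
  if (fs < 8000) stop("audio sample rate must be >= 8000 Hz, got ", fs)
  if (fs < 2 * f_high) stop("sample rate too low for f_high = ", f_high, " Hz")
  n <- length(audio$samples)
  if (n < fs / smooth_hz) {
    stop("input too short: ", n, " samples is less than one smoothing window")
  }
  # keep the top filter edge strictly below Nyquist (f_high = fs/2 allowed)
  f_top <- min(f_high, 0.499 * fs)
  edges <- f_low * (f_top / f_low)^(seq(0, n_bands) / n_bands)
  centers <- sqrt(edges[-1] * edges[-(n_bands + 1)])
  env <- matrix(0, n_bands, n)
  for (b in seq_len(n_bands)) {
    band <- butter_bandpass_zp(audio$samples, fs, edges[b], edges[b + 1])
    env[b, ] <- pmax(butter_lowpass_zp(pmax(band, 0), fs, smooth_hz), 0)
  }
  structure(list(sub_band_envelopes = env, band_centers = centers,
                 sample_rate = fs),
            class = "aud_spec")
}

#' @export
print.aud_spec <- function(x, ...) {
  cat(sprintf("<aud_spec> %d bands (%.0f-%.0f Hz) x %d samples @ %g Hz\n",
              nrow(x$sub_band_envelopes), min(x$band_centers),
              max(x$band_centers), ncol(x$sub_band_envelopes),
              x$sample_rate))
  invisible(x)
}

#' Broadband envelope from an auditory spectrogram
#'
#' Unweighted mean across all sub-band envelopes, anti-alias resampled to
#' `target_rate` (polyphase rational resampling) and clipped at zero to
#' preserve nonnegativity.
#'
#' @param spec an [auditory_spectrogram()] result.
#' @param target_rate output rate in Hz (default 256, the EEG rate).
#' @param source_id optional stimulus identifier carried on the output.
#' @return an [envelope_signal()] at `target_rate`.
#' @export
broadband_envelope <- function(spec, target_rate = 256, source_id = NULL) {
  stopifnot(inherits(spec, "aud_spec"))
  mean_env <- colMeans(spec$sub_band_envelopes)
  v <- resample_vec(mean_env, spec$sample_rate, target_rate)
  envelope_signal(pmax(v, 0), target_rate, source_id)
}

#' Speech envelope straight from audio
#'
#' Convenience chain: [auditory_spectrogram()] then [broadband_envelope()].
#'
#' @inheritParams auditory_spectrogram
#' @inheritParams broadband_envelope
#' @return an [envelope_signal()].
#' @export
speech_envelope <- function(audio, target_rate = 256, n_bands = 128,
                            f_low = 90, f_high = 4000, source_id = NULL) {
  broadband_envelope(
    auditory_spectrogram(audio, n_bands = n_bands, f_low = f_low,
                         f_high = f_high),
    target_rate = target_rate, source_id = source_id
  )
}
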