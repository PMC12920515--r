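# N-channel noise vocoder: band-pass analysis, envelope extraction,
# noise-carrier modulation, RMS matching, band summation.

#' Logarithmically spaced analysis filter bank
#'
#' Builds `n_channels + 1` geometrically spaced band edges from `f_low` to
#' `f_high`, so every band spans the same frequency ratio. The 4-channel
#' 200-5000 Hz bank is the standard cochlear-implant-simulation
#' configuration used throughout this package.
#'
#' @param n_channels number of analysis bands (>= 1).
#' @param f_low,f_high lower and upper edge of the full bank, Hz.
#' @return an object of class `filter_bank`: list with `n_channels`,
#'   `f_low`, `f_high`, `edges` (length `n_channels + 1`) and `spacing`.
#' @examples
#' make_log_bank(4, 200, 5000)$edges
#' @export
make_log_bank <- function(n_channels, f_low, f_high) {
  if (length(n_channels) != 1L || n_channels < 1 || n_channels != round(n_channels)) {
    stop("n_channels must be a positive integer")
  }
  if (!(is.finite(f_low) && is.finite(f_high) && 0 < f_low && f_low < f_high)) {
    stop("need 0 < f_low < f_high, got [", f_low, ", ", f_high, "]")
  }
  edges <- f_low * (f_high / f_low)^(seq(0, n_channels) / n_channels)
  edges[1] <- f_low; edges[n_channels + 1] <- f_high
  structure(list(n_channels = as.integer(n_channels), f_low = f_low,
                 f_high = f_high, edges = edges, spacing = "logarithmic"),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d log-spaced bands, %.0f-%.0f Hz\n",
              x$n_channels, x$f_low, x$f_high))
  cat("edges:", paste(sprintf("%.1f", x$edges), collapse = ", "), "\n")
  invisible(x)
}

#' Noise-vocode an audio waveform
#'
#' Degrades speech while preserving band envelopes: the input is split into
#' the bank's analysis bands (4th-order zero-phase Butterworth), each band's
#' envelope is extracted by half-wave rectification followed by an
#' `env_lowpass_hz` low-pass, the envelope modulates a Gaussian white-noise
#' carrier band-limited to the same band, the modulated product is confined
#' by repeated zero-phase band filtering (so modulation sidebands do not
#' leak into neighboring bands), each band is RMS-matched to its analysis
#' band as seen by the analysis filter, and the bands are summed. Spectral
#' fine structure is destroyed; temporal envelope cues survive.
#'
#' @param audio an [audio_wave()]; its sample rate must be at least twice
#'   the bank's upper edge.
#' @param bank a [make_log_bank()] filter bank (default: the 4-channel
#'   200-5000 Hz bank).
#' @param env_lowpass_hz envelope-smoothing low-pass cutoff, Hz (default 200).
#' @param seed integer seed for the noise carriers; identical seeds give
#'   bit-identical output.
#' @param confine_passes zero-phase band-filter passes applied to the
#'   modulated carrier (default 3; more passes confine sidebands harder).
#' @return an [audio_wave()] of the same length and rate as the input.
#' @export
vocode <- function(audio, bank = make_log_bank(4, 200, 5000),
                   env_lowpass_hz = 200, seed = 1L, confine_passes = 3) {
  stopifnot(inherits(audio, "audio_wave"), inherits(bank, "filter_bank"))
  if (env_lowpass_hz <= 0) stop("env_lowpass_hz must be positive")
  fs <- audio$sample_rate
  if (fs < 2 * bank$f_high) {
    stop("sample rate ", fs, " Hz too low for upper band edge ",
         bank$f_high, " Hz (need >= ", 2 * bank$f_high, " Hz)")
  }
  x <- audio$samples
  n <- length(x)
  out <- numeric(n)
  with_seed(seed, {
    for (b in seq_len(bank$n_channels)) {
      lo <- bank$edges[b]; hi <- bank$edges[b + 1]
      band <- butter_bandpass_zp(x, fs, lo, hi)
      r_in <- rms(band)
      if (r_in == 0) next
      env <- band_envelope(band, fs, env_lowpass_hz)
      carrier <- butter_bandpass_zp(stats::rnorm(n), fs, lo, hi)
      mod <- env * carrier
      for (k in seq_len(confine_passes)) {
        mod <- butter_bandpass_zp(mod, fs, lo, hi)
      }
      # match so a re-analysis of the output recovers the input band RMS
      r_reana <- rms(butter_bandpass_zp(mod, fs, lo, hi))
      if (r_reana > 0) out <- out + mod * (r_in / r_reana)
    }
  })
  audio_wave(out, fs)
}

#' Per-band envelope of an audio waveform
#'
#' The vocoder's analysis chain for one or all bands: band-pass, half-wave
#' rectify, low-pass smooth. Exposed so envelope preservation of a vocoded
#' signal can be quantified with the identical chain.
#'
#' @inheritParams vocode
#' @return a matrix `[n_bands x n_samples]` of nonnegative band envelopes.
#' @export
band_envelopes <- function(audio, bank = make_log_bank(4, 200, 5000),
                           env_lowpass_hz = 200) {
  stopifnot(inherits(audio, "audio_wave"), inherits(bank, "filter_bank"))
  fs <- audio$sample_rate
  t(vapply(seq_len(bank$n_channels), function(b) {
    band <- butter_bandpass_zp(audio$samples, fs, bank$edges[b], bank$edges[b + 1])
    band_envelope(band, fs, env_lowpass_hz)
  }, numeric(length(audio$samples))))
}

band_envelope <- function(band, fs, lowpass_hz) {
  butter_lowpass_zp(pmax(band, 0), fs, lowpass_hz)
}
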