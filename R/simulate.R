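# Synthetic multi-subject EEG generator: condition-dependent ground-truth
# TRF kernels convolved with speech-like envelopes plus spatially
# correlated 1/f noise.

#' Standard 64-channel montage labels
#'
#' The 10-20-style labels of a 64-channel cap (includes FCz, Cz, CPz, Pz,
#' POz used as analysis sites).
#'
#' @return character vector of length 64.
#' @export
montage64_labels <- function() {
  c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2")
}

#' Approximate 2-d scalp positions for 10-20-style labels
#'
#' Idealized top-view coordinates (x: left -1 .. right +1, y: posterior
#' -1 .. anterior +1) parsed from the label's row letters and hemisphere
#' digit; used only to shape smooth topographic gain fields.
#'
#' @param labels channel labels.
#' @return tibble: `channel`, `x`, `y`.
#' @export
montage_positions <- function(labels) {
  row_y <- c(Fp = 0.88, AF = 0.72, F = 0.54, FT = 0.3, FC = 0.27,
             T = 0, C = 0, TP = -0.3, CP = -0.27, P = -0.54,
             PO = -0.72, O = -0.88, I = -1)
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    if (length(m) != 3) stop("cannot parse channel label: ", lab)
    row <- m[2]; pos <- m[3]
    if (!row %in% names(row_y)) stop("unknown montage row in label: ", lab)
    y <- row_y[[row]]
    if (pos == "z") return(c(0, y))
    d <- as.integer(pos)
    side <- if (d %% 2 == 1) -1 else 1
    x <- side * min(1, 0.22 * ceiling(d / 2))
    c(x, y)
  }
  xy <- t(vapply(labels, parse_one, numeric(2)))
  tibble::tibble(channel = labels, x = unname(xy[, 1]), y = unname(xy[, 2]))
}

#' Default two-condition ground-truth kernel specifications
#'
#' Three Gaussian-shaped lag components per condition — N1 (negative,
#' 90 ms, width 15 ms), P2 (positive, 160 ms, width 25 ms), P400
#' (positive, 390 ms, width 30 ms) — with smooth fronto-central
#' topographies peaking near Cz. The natural condition carries 1.5x the
#' vocoded N1/P2 amplitudes; the vocoded condition carries 1.5x the
#' natural P400 amplitude (clean speech boosts the early components,
#' degraded speech the late one).
#'
#' @return named list of two tibbles (`natural`, `vocoded`) with columns
#'   `name`, `latency_ms`, `width_ms`, `amplitude`, `polarity`, `topo_x`,
#'   `topo_y`, `topo_spread`.
#' @export
make_default_kernels <- function() {
  base <- tibble::tibble(
    name = c("N1", "P2", "P400"),
    latency_ms = c(90, 160, 390),
    width_ms = c(15, 25, 30),
    polarity = c(-1, 1, 1),
    topo_x = c(0, 0, 0),
    topo_y = c(0.15, 0.05, 0),
    topo_spread = c(0.5, 0.5, 0.5))
  natural <- base; natural$amplitude <- c(1.5, 1.5, 1.0)
  vocoded <- base; vocoded$amplitude <- c(1.0, 1.0, 1.5)
  list(natural = natural[, c("name", "latency_ms", "width_ms", "amplitude",
                             "polarity", "topo_x", "topo_y", "topo_spread")],
       vocoded = vocoded[, c("name", "latency_ms", "width_ms", "amplitude",
                             "polarity", "topo_x", "topo_y", "topo_spread")])
}

#' Realize a kernel specification as a channel-by-lag weight matrix
#'
#' @param kspec one kernel tibble from [make_default_kernels()].
#' @param channels channel labels (positions derived via
#'   [montage_positions()]).
#' @param lags a [lag_spec()].
#' @param amp_scale per-component amplitude multipliers (subject
#'   variability), default 1.
#' @param latency_shift_ms per-component latency shifts in ms, default 0.
#' @return matrix `[n_channels x n_lags]`.
#' @export
kernel_matrix <- function(kspec, channels, lags,
                          amp_scale = rep(1, nrow(kspec)),
                          latency_shift_ms = rep(0, nrow(kspec))) {
  pos <- montage_positions(channels)
  K <- matrix(0, length(channels), length(lags$lag_idx))
  for (c_i in seq_len(nrow(kspec))) {
    gain <- exp(-((pos$x - kspec$topo_x[c_i])^2 +
                  (pos$y - kspec$topo_y[c_i])^2) /
                (2 * kspec$topo_spread[c_i]^2))
    lat <- kspec$latency_ms[c_i] + latency_shift_ms[c_i]
    shape <- exp(-(lags$times_ms - lat)^2 / (2 * kspec$width_ms[c_i]^2))
    K <- K + (kspec$amplitude[c_i] * amp_scale[c_i] * kspec$polarity[c_i]) *
      outer(gain, shape)
  }
  K
}

#' Speech-like synthetic envelope
#'
#' Nonnegative envelope built from low-pass-filtered rectified noise with
#' a dominant ~4 Hz sinusoidal syllabic modulation, plus a small
#' broadband rectified-noise floor (a stand-in for the sharp transients
#' of real speech, and what keeps the lagged design numerically
#' identifiable). Zero before stimulus onset by construction (the signal
#' starts at t = 0).
#'
#' @param duration_s duration in seconds (default 2.5, the stimulus
#'   length).
#' @param fs sampling rate in Hz (default 256).
#' @param seed integer seed; `NULL` draws from the current RNG stream.
#' @param am_freq syllabic modulation frequency, Hz (default 4).
#' @param am_depth modulation depth in \[0, 1) (default 0.9).
#' @param base_cutoff_hz low-pass cutoff of the slow base envelope
#'   (default 3.5 Hz, 4th-order zero-phase, so that envelope power stays
#'   below the 8-12 Hz alpha band even after modulation sidebands).
#' @param floor_frac RMS of the broadband floor relative to the base
#'   envelope (default 0.05, emulating the fast transient content of
#'   syllable onsets that keeps the lagged design identifiable).
#' @return an [envelope_signal()].
#' @export
synth_envelope <- function(duration_s = 2.5, fs = 256, seed = NULL,
                           am_freq = 4, am_depth = 0.9,
                           base_cutoff_hz = 3.5, floor_frac = 0.05) {
  n <- round(duration_s * fs)
  with_seed(seed, {
    base <- butter_lowpass_zp(pmax(stats::rnorm(n), 0), fs,
                              base_cutoff_hz, order = 4)
    base <- pmax(base, 0)
    tt <- (seq_len(n) - 1) / fs
    am <- 1 + am_depth * sin(2 * pi * am_freq * tt + stats::runif(1, 0, 2 * pi))
    v <- base * am
    fl <- pmax(stats::rnorm(n), 0)
    if (rms(fl) > 0 && rms(v) > 0) v <- v + fl * (floor_frac * rms(v) / rms(fl))
    envelope_signal(pmax(v, 0), fs)
  })
}

# Unit-variance 1/f^exponent noise via spectral shaping.
pink_noise <- function(n, exponent = 1) {
  pink_noise_mat(n, 1L, exponent)[, 1]
}

# [n x m] matrix of independent unit-variance 1/f^exponent noise columns,
# shaped in one batched FFT.
pink_noise_mat <- function(n, m, exponent = 1) {
  if (n < 2) return(matrix(stats::rnorm(n * m), n, m))
  spec <- stats::mvfft(matrix(stats::rnorm(n * m), n, m))
  f <- c(1, seq_len(n - 1))            # index frequencies; DC reuses f = 1
  w <- (pmin(f, n - f + 1))^(-exponent / 2)
  w[1] <- 0
  x <- Re(stats::mvfft(spec * w, inverse = TRUE)) / n
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  sweep(x, 2, s, `/`)
}

# Row-normalized smooth random mixing matrix for spatially correlated
# noise: identity plus a channel-smoothed random field.
mixing_matrix <- function(n_ch) {
  P <- matrix(stats::rnorm(n_ch * n_ch), n_ch, n_ch)
  if (n_ch >= 3) {
    k <- stats::dnorm(-2:2, sd = 1.2); k <- k / sum(k)
    P <- apply(P, 2, function(col) stats::filter(c(col[1], col[1], col,
                                                   col[n_ch], col[n_ch]),
                                                 k, sides = 2)[3:(n_ch + 2)])
  }
  M <- diag(n_ch) + 0.6 * P
  M / sqrt(rowSums(M^2))
}

#' Simulation configuration
#'
#' The defaults encode the reference experimental design: 50 subjects, 10 sentences per
#' condition repeated 100 times, 64 channels, 256 Hz, 3 s epochs
#' (-0.5..2.5 s), two conditions with the [make_default_kernels()]
#' ground-truth kernels, per-epoch SNR of 0 dB against spatially
#' correlated 1/f noise, and between-subject variability of 20% in
#' component amplitude and 10 ms in latency.
#'
#' @param n_subjects,n_items,n_reps design counts (defaults 50, 10, 100).
#' @param fs sampling rate, Hz (default 256).
#' @param channels channel labels (default [montage64_labels()]).
#' @param snr_db per-epoch signal-to-noise ratio in dB, computed over
#'   post-onset samples (`Inf` disables noise).
#' @param kernels named list `(natural, vocoded)` of kernel tibbles.
#' @param amp_sd between-subject amplitude multiplier SD (default 0.2).
#' @param latency_jitter_ms between-subject latency jitter SD (default 10).
#' @param noise_exponent 1/f spectral exponent (default 1).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param return `"averaged"` generates the per-item averages of `n_reps`
#'   repetitions directly (noise SD scaled by `1/sqrt(n_reps)`,
#'   distributionally equivalent for Gaussian noise); `"epochs"` generates
#'   every repetition.
#' @param epoch_window epoch window in seconds (default `c(-0.5, 2.5)`).
#' @param stim_duration_s maximum stimulus duration (default 2.5 s);
#'   per-item durations are drawn uniformly from 60-100% of it and the
#'   per-item syllabic rate from 3-4.5 Hz, mimicking sentences of varying
#'   length and tempo.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 50, n_items = 10, n_reps = 100,
                       fs = 256, channels = montage64_labels(),
                       snr_db = 0, kernels = make_default_kernels(),
                       amp_sd = 0.2, latency_jitter_ms = 10,
                       noise_exponent = 1, seed = 1L,
                       return = c("averaged", "epochs"),
                       epoch_window = c(-0.5, 2.5), stim_duration_s = 2.5) {
  return <- match.arg(return)
  stopifnot(n_subjects >= 1, n_items >= 1, n_reps >= 1, fs > 0,
            length(channels) >= 2, amp_sd >= 0, latency_jitter_ms >= 0,
            is.list(kernels), all(c("natural", "vocoded") %in% names(kernels)))
  structure(list(n_subjects = n_subjects, n_items = n_items, n_reps = n_reps,
                 fs = fs, channels = channels, snr_db = snr_db,
                 kernels = kernels, amp_sd = amp_sd,
                 latency_jitter_ms = latency_jitter_ms,
                 noise_exponent = noise_exponent, seed = as.integer(seed),
                 return = return, epoch_window = epoch_window,
                 stim_duration_s = stim_duration_s),
            class = "sim_config")
}

#' Simulate a two-condition multi-subject TRF dataset
#'
#' Each epoch is the convolution of a per-item speech-like envelope with
#' the subject's condition-dependent ground-truth kernel plus spatially
#' correlated 1/f noise scaled to the configured per-epoch SNR
#' (repetitions share the signal; noise is independent). The realized
#' per-subject kernels are stored alongside the data.
#'
#' @param cfg a [sim_config()].
#' @return list of class `trf_sim`: `responses` (per condition, a list of
#'   [eeg_epochs()] per subject), `envelopes` (per item), `ground_truth`
#'   (`nominal` and per-subject realized kernels plus the [lag_spec()]),
#'   and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$fs
    lags <- lag_spec(-100, 600, fs)
    n_t <- round(diff(cfg$epoch_window) * fs)
    pre <- round(-cfg$epoch_window[1] * fs)
    n_ch <- length(cfg$channels)
    conds <- c("natural", "vocoded")
    n_comp <- nrow(cfg$kernels$natural)

    # items differ in duration (up to stim_duration_s, as sentences do)
    # and syllabic rate, so no two stimuli share gross temporal structure
    # syllabic rates capped at 4.5 Hz so that AM sidebands of the slow
    # base (cutoff 3.5 Hz) stay below the 8-12 Hz alpha band
    envelopes <- lapply(seq_len(cfg$n_items), function(i) {
      dur <- stats::runif(1, 0.6, 1) * cfg$stim_duration_s
      e <- synth_envelope(dur, fs, am_freq = stats::runif(1, 3, 4.5))
      e$source_id <- paste0("item", i)
      e
    })
    X_items <- lapply(envelopes, function(e) {
      full <- numeric(n_t)
      k <- min(length(e$values), n_t - pre)
      full[pre + seq_len(k)] <- e$values[seq_len(k)]
      lag_matrix(full, lags)
    })
    M <- mixing_matrix(n_ch)
    post <- (pre + 1):n_t

    nominal <- lapply(cfg$kernels, function(k) kernel_matrix(k, cfg$channels, lags))
    responses <- list(natural = vector("list", cfg$n_subjects),
                      vocoded = vector("list", cfg$n_subjects))
    realized <- vector("list", cfg$n_subjects)

    noise_block <- function(scale) {
      if (scale == 0) return(matrix(0, n_ch, n_t))
      raw <- t(pink_noise_mat(n_t, n_ch, cfg$noise_exponent))
      (M %*% raw) * scale
    }

    for (s in seq_len(cfg$n_subjects)) {
      amp_scale <- stats::rnorm(n_comp, 1, cfg$amp_sd)
      lat_shift <- stats::rnorm(n_comp, 0, cfg$latency_jitter_ms)
      realized[[s]] <- list()
      cond_signals <- list()
      for (cond in conds) {
        K <- kernel_matrix(cfg$kernels[[cond]], cfg$channels, lags,
                           amp_scale, lat_shift)
        realized[[s]][[cond]] <- K
        cond_signals[[cond]] <- lapply(X_items, function(X) X %*% t(K))
      }
      # one condition-independent noise scale per subject: SNR is defined
      # against the across-condition mean post-onset signal power, so the
      # noise process is identical in distribution for both conditions
      p_sig <- mean(vapply(conds, function(cond) {
        mean(vapply(cond_signals[[cond]], function(sg) mean(sg[post, ]^2),
                    numeric(1)))
      }, numeric(1)))
      # zero-amplitude kernels (pure-noise data): unit noise
      scale <- if (is.infinite(cfg$snr_db)) 0 else
        if (p_sig == 0) 1 else sqrt(p_sig / 10^(cfg$snr_db / 10))
      for (cond in conds) {
        signals <- cond_signals[[cond]]
        if (cfg$return == "averaged") {
          dat <- array(0, dim = c(cfg$n_items, n_ch, n_t))
          for (i in seq_len(cfg$n_items)) {
            dat[i, , ] <- t(signals[[i]]) +
              noise_block(scale / sqrt(cfg$n_reps))
          }
          items <- paste0("item", seq_len(cfg$n_items))
          averaged <- TRUE
        } else {
          dat <- array(0, dim = c(cfg$n_items * cfg$n_reps, n_ch, n_t))
          items <- character(cfg$n_items * cfg$n_reps)
          e_idx <- 0L
          for (i in seq_len(cfg$n_items)) {
            for (r in seq_len(cfg$n_reps)) {
              e_idx <- e_idx + 1L
              dat[e_idx, , ] <- t(signals[[i]]) + noise_block(scale)
              items[e_idx] <- paste0("item", i)
            }
          }
          averaged <- FALSE
        }
        responses[[cond]][[s]] <- eeg_epochs(
          dat, fs, cfg$epoch_window, cfg$channels, condition = cond,
          subject = paste0("sub", s), items = items, averaged = averaged)
      }
    }
    structure(list(responses = responses, envelopes = envelopes,
                   ground_truth = list(nominal = nominal,
                                       subjects = realized, lags = lags),
                   config = cfg),
              class = "trf_sim")
  })
}

#' @export
print.trf_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<trf_sim> %d subjects x 2 conditions, %d items",
                     " (%s), %d channels @ %g Hz, SNR %g dB, seed %d\n"),
              cfg$n_subjects, cfg$n_items, cfg$return,
              length(cfg$channels), cfg$fs, cfg$snr_db, cfg$seed))
  invisible(x)
}
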