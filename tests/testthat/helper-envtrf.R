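# Shared fixtures: reduced montages and small simulation configs used
# across test files. Everything is generated in code at test time.

ch16 <- c("Fz", "F3", "F4", "FCz", "FC3", "FC4", "Cz", "C3", "C4",
          "CPz", "CP3", "CP4", "Pz", "P3", "P4", "POz")
ch8 <- c("Fz", "FCz", "FC3", "Cz", "C3", "CPz", "Pz", "POz")

# tiny two-condition dataset for fast structural tests
tiny_sim <- function(seed = 1, fs = 64, n_subjects = 2, n_items = 4,
                     snr_db = 10, channels = ch8, return = "averaged",
                     n_reps = 10, kernels = make_default_kernels()) {
  simulate_dataset(sim_config(
    n_subjects = n_subjects, n_items = n_items, n_reps = n_reps, fs = fs,
    channels = channels, snr_db = snr_db, kernels = kernels, seed = seed,
    return = return))
}

# speech-like amplitude-modulated broadband noise at audio rate: a bump
# train of varying rate/amplitude multiplying white noise
am_noise_audio <- function(fs, duration = 3, seed = 2) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  set.seed(seed)
  ons <- cumsum(abs(rnorm(ceiling(duration * 5), 0.25, 0.04)))
  ons <- ons[ons < duration - 0.1]
  m <- rowSums(vapply(ons, function(o) {
    exp(-(t - o)^2 / (2 * 0.045^2)) * runif(1, 0.5, 1.5)
  }, numeric(length(t)))) + 0.02
  audio_wave(rnorm(length(t)) * m, fs)
}

# independent step-up Benjamini-Hochberg enumeration (test oracle)
bh_oracle <- function(p, alpha = 0.05) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  q_sorted <- rev(cummin(rev(ranked * n / seq_len(n))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  k <- which(ranked <= seq_len(n) / n * alpha)
  sig <- rep(FALSE, n)
  if (length(k) > 0) sig[o[seq_len(max(k))]] <- TRUE
  list(q = q, sig = sig)
}
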