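# Internal filtering / spectral helpers shared across modules.

#' @importFrom signal butter filtfilt fir1 fftfilt resample hanning
NULL

# Zero-phase Butterworth band-pass of total order `order` (forward-backward,
# so the effective magnitude response is squared). `order` must be even for
# a band-pass (signal::butter doubles the prototype order).
butter_bandpass_zp <- function(x, fs, low, high, order = 4) {
  stopifnot(order %% 2 == 0, low > 0, high > low)
  if (high >= fs / 2) {
    stop("band edge ", high, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  }
  flt <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  filt_time(x, function(v) signal::filtfilt(flt, v))
}

butter_lowpass_zp <- function(x, fs, cutoff, order = 4) {
  if (cutoff >= fs / 2) {
    stop("cutoff ", cutoff, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  }
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filt_time(x, function(v) signal::filtfilt(flt, v))
}

# Apply a 1-d filter function along time. Vectors are filtered directly;
# matrices are filtered column-wise (time in rows).
filt_time <- function(x, f) {
  if (is.matrix(x)) {
    out <- apply(x, 2, f)
    dim(out) <- dim(x)
    dimnames(out) <- dimnames(x)
    out
  } else {
    f(as.numeric(x))
  }
}

# Linear-phase windowed-sinc (Hamming) band-pass, applied with delay
# compensation so the net filter is zero-phase. Transition width `trans_hz`
# sets the length: ~3.3 * fs / trans_hz taps (Hamming rule of thumb,
# stop-band attenuation ~53 dB).
design_fir_bandpass <- function(fs, low, high, trans_hz = 1) {
  stopifnot(trans_hz > 0)
  if (!(0 < low && low < high)) {
    stop("invalid band: need 0 < low < high, got [", low, ", ", high, "]")
  }
  if (high >= fs / 2) {
    stop("high edge ", high, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  }
  n_taps <- ceiling(3.3 * fs / trans_hz)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  signal::fir1(n_taps - 1, c(low, high) / (fs / 2), type = "pass")
}

apply_fir_zerophase <- function(x, b) {
  m <- (length(b) - 1L) / 2L
  one <- function(v) {
    n <- length(v)
    if (n <= length(b)) {
      stop("signal (", n, " samples) is shorter than the FIR filter (",
           length(b), " taps); use a shorter filter or a longer signal")
    }
    y <- signal::fftfilt(b, c(v, numeric(m)))
    y[(m + 1L):(m + n)]
  }
  filt_time(x, one)
}

# Welch power spectral density: Hann segments, one-sided density in
# units^2/Hz. Returns list(freq, psd).
welch_psd <- function(x, fs, seg_len = fs, overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  seg_len <- as.integer(seg_len)
  if (seg_len < 8) stop("segment length too short for Welch estimate")
  if (n < seg_len) stop("signal shorter than one Welch segment")
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- signal::hanning(seg_len)
  scale <- 1 / (fs * sum(w^2))
  n_freq <- floor(seg_len / 2) + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    p <- abs(stats::fft(seg))^2 * scale
    acc <- acc + p[seq_len(n_freq)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when seg_len even)
  dbl <- rep(2, n_freq)
  dbl[1] <- 1
  if (seg_len %% 2 == 0) dbl[n_freq] <- 1
  list(freq = (seq_len(n_freq) - 1) * fs / seg_len, psd = psd * dbl)
}

rms <- function(x) sqrt(mean(x^2))

# Rational (polyphase-equivalent) resampling: zero-stuff by p, windowed-sinc
# anti-alias filter with gain p and cutoff at the tighter Nyquist, pick every
# q-th sample with compensated delay. Output length = round(n * to / from).
resample_vec <- function(x, from, to) {
  stopifnot(from > 0, to > 0)
  x <- as.numeric(x)
  if (from == to) return(x)
  fr <- rational_approx(to / from)
  p <- fr[1]; q <- fr[2]
  n <- length(x)
  n_out <- round(n * to / from)
  up <- numeric(n * p)
  up[seq(1, n * p, by = p)] <- x
  # windowed-sinc low-pass, 10 zero-crossings per side, Hamming window
  half <- 10L * max(p, q)
  k <- seq(-half, half)
  fc <- 1 / max(p, q)             # cutoff as a fraction of upsampled Nyquist
  h <- fc * sinc_fn(fc * k) * (0.54 + 0.46 * cos(pi * k / half))
  h <- p * h / sum(h) * 1         # unit DC gain after upsampling by p
  y <- signal::fftfilt(h, c(up, numeric(half)))
  y <- y[(half + 1):(half + n * p)]
  idx <- 1 + q * (seq_len(n_out) - 1)
  idx[idx > n * p] <- n * p
  y[idx]
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

rational_approx <- function(r, max_den = 4096) {
  # continued-fraction expansion
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(as.integer(p1), as.integer(q1))
}

# Run `expr` with a private RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
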