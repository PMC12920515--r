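test_that("FIR band-pass keeps in-band sinusoids and kills DC", {
  fs <- 512
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x30 <- sin(2 * pi * 30 * t)
  y30 <- bandpass_fir(x30, fs, 1, 57)
  mid <- seq(2 * fs, length(t) - 2 * fs)  # away from edges
  expect_lt(abs(envtrf:::rms(y30[mid]) / envtrf:::rms(x30[mid]) - 1), 0.05)
  ydc <- bandpass_fir(rep(1, length(t)), fs, 1, 57)
  expect_lt(20 * log10(max(abs(mean(ydc[mid])), 1e-12)), -20)
  expect_error(bandpass_fir(x30, fs, 1, 300), "Nyquist")
})

test_that("resampling preserves a sinusoid's frequency and amplitude", {
  from <- 2048; to <- 256
  t <- seq(0, 4 - 1 / from, by = 1 / from)
  x <- sin(2 * pi * 10 * t)
  y <- resample_signal(x, from, to)
  expect_equal(length(y), round(length(x) * to / from))
  tt <- seq_along(y) / to
  fit <- stats::lm(y ~ sin(2 * pi * 10 * tt) + cos(2 * pi * 10 * tt) - 1)
  amp <- sqrt(sum(stats::coef(fit)^2))
  expect_lt(abs(amp - 1), 0.02)
  expect_gt(summary(fit)$r.squared, 0.98)
  expect_identical(resample_signal(x, 256, 256), x)
})

test_that("epoching uses the half-open onset convention and checks bounds", {
  fs <- 256
  x <- matrix(rnorm(2000 * 3), 2000, 3)
  # onset at sample 129 (1-based): epoch covers rows 1..768, onset at index 129
  ep <- epoch_data(x, onsets = 129, sample_rate = fs)
  expect_equal(dim(ep$data), c(1, 3, 768))
  expect_equal(ep$data[1, 2, ], x[1:768, 2])
  expect_equal(ep$data[1, 1, 129], x[129, 1])  # t = 0 sample is the onset
  tt <- epoch_times(ep)
  expect_equal(tt[129], 0)
  expect_equal(tt[1], -0.5)
  # empty and out-of-bounds
  ep0 <- epoch_data(x, onsets = integer(0), sample_rate = fs)
  expect_equal(dim(ep0$data)[1], 0)
  expect_error(epoch_data(x, onsets = c(50, 500), sample_rate = fs), "50")
})

test_that("epoching then averaging commutes with channel reordering", {
  fs <- 64
  x <- matrix(rnorm(1500 * 4), 1500, 4)
  on <- c(100, 400, 700, 1000)
  items <- c("a", "b", "a", "b")
  ep1 <- epoch_data(x, on, fs, channels = c("c1", "c2", "c3", "c4"),
                    items = items)
  ep2 <- epoch_data(x[, c(3, 1, 4, 2)], on, fs,
                    channels = c("c3", "c1", "c4", "c2"), items = items)
  a1 <- average_repetitions(ep1)
  a2 <- average_repetitions(ep2)
  expect_equal(a1$data[, 1, ], a2$data[, 2, ])
  expect_equal(a1$data[, 4, ], a2$data[, 3, ])
})

test_that("repetition averaging reduces noise ~sqrt(n) and is per-item", {
  fs <- 64
  n_t <- round(3 * fs)
  sig <- sin(2 * pi * 3 * (0:(n_t - 1)) / fs)
  n_rep <- 100
  set.seed(5)
  dat <- array(0, dim = c(n_rep, 1, n_t))
  for (r in seq_len(n_rep)) dat[r, 1, ] <- sig + rnorm(n_t)
  ep <- eeg_epochs(dat, fs, channels = "Cz", items = rep("s1", n_rep))
  avg <- average_repetitions(ep, band = NULL)
  expect_equal(dim(avg$data)[1], 1)
  resid_sd <- sd(avg$data[1, 1, ] - sig)
  expect_lt(resid_sd, 3 / sqrt(n_rep))  # ~10x noise reduction
  expect_gt(resid_sd, 0.3 / sqrt(n_rep))
  # identical epochs average to themselves
  dat2 <- array(rep(sig, each = 2), dim = c(2, 1, n_t))
  dat2[1, 1, ] <- sig; dat2[2, 1, ] <- sig
  ep2 <- eeg_epochs(dat2, fs, channels = "Cz", items = c("s", "s"))
  expect_equal(average_repetitions(ep2, band = NULL)$data[1, 1, ], sig)
  no_items <- eeg_epochs(dat2, fs, channels = "Cz")
  expect_error(average_repetitions(no_items), "item label")
})

test_that("post-average band-pass confines the spectrum to 1-15 Hz", {
  fs <- 256
  set.seed(8)
  dat <- array(rnorm(20 * 2 * 768), dim = c(20, 2, 768))
  ep <- eeg_epochs(dat, fs, channels = c("a", "b"),
                   items = rep(c("s1", "s2"), 10))
  avg <- average_repetitions(ep)
  w <- envtrf:::welch_psd(avg$data[1, 1, ], fs, seg_len = 256)
  inband <- mean(w$psd[w$freq >= 2 & w$freq <= 14])
  outband <- mean(w$psd[w$freq >= 30 & w$freq <= 100])
  expect_gt(10 * log10(inband / outband), 20)
})

test_that("baseline normalization is pooled, exact, and idempotent", {
  fs <- 64
  set.seed(3)
  dat <- array(rnorm(6 * 4 * 192, mean = 3, sd = 2), dim = c(6, 4, 192))
  # different channel scales must be preserved relative to each other
  dat[, 2, ] <- dat[, 2, ] * 5
  ep <- eeg_epochs(dat, fs, channels = letters[1:4],
                   items = paste0("s", 1:6), averaged = TRUE)
  nor <- baseline_normalize(ep)
  tt <- epoch_times(nor)
  base <- nor$data[, , tt < 0]
  expect_lt(abs(mean(base)), 1e-10)
  expect_equal(sd(as.numeric(base)), 1, tolerance = 1e-10)
  # pooled: relative channel power unchanged
  r_before <- sd(as.numeric(dat[, 2, ])) / sd(as.numeric(dat[, 1, ]))
  r_after <- sd(as.numeric(nor$data[, 2, ])) / sd(as.numeric(nor$data[, 1, ]))
  expect_equal(r_after, r_before, tolerance = 1e-10)
  # idempotent
  nor2 <- baseline_normalize(nor)
  expect_equal(nor2$data, nor$data, tolerance = 1e-10)
  # degenerate: constant baseline
  flat <- dat; flat[, , tt < 0] <- 7
  epf <- eeg_epochs(flat, fs, channels = letters[1:4])
  expect_error(baseline_normalize(epf), "degenerate")
})

test_that("alpha power integrates a 10 Hz sinusoid to ~A^2/2 (Parseval)", {
  fs <- 256
  A <- 3
  n_t <- round(3 * fs)
  x <- A * sin(2 * pi * 10 * (0:(n_t - 1)) / fs)
  dat <- array(0, dim = c(2, 2, n_t))
  for (e in 1:2) for (ch in 1:2) dat[e, ch, ] <- x
  ep <- eeg_epochs(dat, fs, channels = c("Pz", "POz"))
  p <- alpha_power(ep)
  w <- envtrf:::welch_psd(x, fs, seg_len = fs)
  band_integral <- sum(w$psd[w$freq >= 8 & w$freq <= 12]) * 1  # df = 1 Hz
  expect_lt(abs(band_integral - A^2 / 2) / (A^2 / 2), 0.05)
  expect_equal(p, mean(w$psd[w$freq >= 8 & w$freq <= 12]))
  # DC-only input has essentially no alpha power
  dc <- ep; dc$data[] <- 5
  expect_lt(alpha_power(dc) / p, 1e-4)
  expect_error(alpha_power(ep, sites = c("Pz", "Oz")), "Oz")
})
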