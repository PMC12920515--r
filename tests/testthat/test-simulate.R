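test_that("default kernels encode the condition-specific amplitude ratios", {
  k <- make_default_kernels()
  expect_equal(k$natural$amplitude[k$natural$name == "N1"] /
                 k$vocoded$amplitude[k$vocoded$name == "N1"], 1.5)
  expect_equal(k$natural$amplitude[k$natural$name == "P2"] /
                 k$vocoded$amplitude[k$vocoded$name == "P2"], 1.5)
  expect_equal(k$vocoded$amplitude[k$vocoded$name == "P400"] /
                 k$natural$amplitude[k$natural$name == "P400"], 1.5)
  expect_true(all(k$natural$latency_ms > -100 & k$natural$latency_ms < 600))
  # component latencies fall inside the reported cluster windows
  expect_true(k$natural$latency_ms[1] >= 80 && k$natural$latency_ms[1] <= 103)
  expect_true(k$natural$latency_ms[2] >= 131 && k$natural$latency_ms[2] <= 185)
  expect_true(k$natural$latency_ms[3] >= 376 && k$natural$latency_ms[3] <= 408)
})

test_that("kernel matrices peak at the configured latency and topography", {
  lags <- lag_spec(-100, 600, 256)
  k <- make_default_kernels()
  K <- kernel_matrix(k$vocoded, montage64_labels(), lags)
  cz <- which(montage64_labels() == "Cz")
  p9 <- which(montage64_labels() == "P9")
  # P400 is the largest vocoded component; peak near 390 ms at Cz
  expect_equal(lags$times_ms[which.max(K[cz, ])], 390, tolerance = 6)
  # fronto-central topography decays toward the edge of the cap
  expect_gt(max(abs(K[cz, ])), 2 * max(abs(K[p9, ])))
})

test_that("synthetic envelopes are nonnegative with a syllabic spectral peak", {
  for (seed in c(2, 5, 9)) {
    e <- synth_envelope(2.5, 256, seed = seed)
    expect_true(all(e$values >= 0))
    expect_true(all(is.finite(e$values)))
    expect_equal(length(e$values), 640)
    sp <- envtrf:::welch_psd(e$values - mean(e$values), 256, seg_len = 256)
    pk <- sp$freq[which.max(sp$psd[sp$freq > 0.5]) +
                    sum(sp$freq <= 0.5)]
    expect_gte(pk, 2); expect_lte(pk, 8)
  }
})

test_that("pink noise has the configured spectral slope", {
  set.seed(12)
  for (expo in c(1, 1.5)) {
    x <- envtrf:::pink_noise(8192, exponent = expo)
    s <- envtrf:::welch_psd(x, 256, seg_len = 2048)
    sel <- s$freq > 1 & s$freq < 100
    slope <- stats::coef(stats::lm(log(s$psd[sel]) ~ log(s$freq[sel])))[2]
    expect_lt(abs(slope + expo), 0.2)
  }
})

test_that("simulation is bit-reproducible and obeys its declared shape", {
  cfg <- sim_config(n_subjects = 2, n_items = 3, n_reps = 4, fs = 64,
                    channels = ch8, snr_db = 5, seed = 41,
                    return = "epochs")
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$responses$vocoded[[2]]$data,
                   d2$responses$vocoded[[2]]$data)
  ep <- d1$responses$natural[[1]]
  expect_equal(dim(ep$data), c(3 * 4, 8, round(3 * 64)))
  expect_equal(unique(table(ep$items)), 4L)
  expect_length(d1$envelopes, 3)
  expect_length(d1$ground_truth$subjects, 2)
})

test_that("per-epoch SNR matches the configured value", {
  cfg <- sim_config(n_subjects = 1, n_items = 6, n_reps = 1, fs = 64,
                    channels = ch8, snr_db = 0, seed = 51,
                    return = "epochs")
  d <- simulate_dataset(cfg)
  ep <- d$responses$natural[[1]]
  lags <- d$ground_truth$lags
  K <- d$ground_truth$subjects[[1]]$natural
  pre <- round(0.5 * 64)
  post <- (pre + 1):dim(ep$data)[3]
  snr_est <- vapply(1:6, function(i) {
    full <- envelope_on_epoch(d$envelopes[[i]], ep)
    sig <- t(lag_matrix(full, lags) %*% t(K))
    noise <- ep$data[i, , ] - sig
    10 * log10(mean(sig[, post]^2) / mean(noise[, post]^2))
  }, numeric(1))
  # noise power is calibrated across conditions/items, so item SNRs
  # scatter around the configured value
  expect_lt(abs(mean(snr_est) - 0), 1.5)
})

test_that("noiseless epochs equal the convolution exactly", {
  cfg <- sim_config(n_subjects = 1, n_items = 2, n_reps = 1, fs = 64,
                    channels = ch8, snr_db = Inf, seed = 61)
  d <- simulate_dataset(cfg)
  ep <- d$responses$vocoded[[1]]
  K <- d$ground_truth$subjects[[1]]$vocoded
  full <- envelope_on_epoch(d$envelopes[[1]], ep)
  sig <- t(lag_matrix(full, d$ground_truth$lags) %*% t(K))
  expect_equal(ep$data[1, , ], unname(sig), tolerance = 1e-12)
})
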