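make_trf <- function(W, fs = 256, channels = paste0("ch", seq_len(nrow(W))),
                     subject = "s1", condition = "natural") {
  ls <- lag_spec(-100, 600, fs)
  stopifnot(ncol(W) == length(ls$lag_idx))
  envtrf:::new_trf(W, intercept = numeric(nrow(W)), lags = ls, lambda = 1,
                   channels = channels, condition = condition,
                   subject = subject)
}

test_that("GFP is the per-lag spatial standard deviation", {
  # spatially constant weights -> zero GFP
  W <- matrix(2, 4, 181)
  expect_equal(max(gfp(make_trf(W))$gfp), 0)
  # two channels +1/-1 -> GFP 1
  W2 <- matrix(c(1, -1), 2, 181)
  expect_equal(gfp(make_trf(W2))$gfp, rep(1, 181))
  # random matrix matches a brute-force oracle
  set.seed(3)
  W3 <- matrix(rnorm(64 * 181), 64, 181)
  g <- gfp(make_trf(W3))$gfp
  oracle <- apply(W3, 2, function(col) sqrt(mean((col - mean(col))^2)))
  expect_equal(g, oracle, tolerance = 1e-12)
  W1 <- matrix(1, 1, 181)
  expect_error(gfp(make_trf(W1)), "2 channels")
})

test_that("paired t matches hand computation and handles degeneracy", {
  r <- paired_t(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  r2 <- paired_t(1:5, 1:5)
  expect_equal(r2$t, 0); expect_equal(r2$p, 1)
  r3 <- paired_t(c(2, 3), c(1, 2))  # constant nonzero difference
  expect_true(is.infinite(r3$t)); expect_equal(r3$p, 0)
  # df = n - 1 at the reference sample size
  set.seed(1)
  expect_equal(paired_t(rnorm(50), rnorm(50))$df, 49L)
})

test_that("BH adjustment matches the step-up enumeration oracle exhaustively", {
  grid <- c(0.001, 0.011, 0.04, 0.051, 0.2, 1)
  for (len in 1:3) {
    combos <- as.matrix(do.call(expand.grid, rep(list(grid), len)))
    for (i in seq_len(nrow(combos))) {
      p <- as.numeric(combos[i, ])
      got <- fdr_bh(p, alpha = 0.05)
      want <- bh_oracle(p, alpha = 0.05)
      expect_equal(got$q, want$q, tolerance = 1e-12)
      expect_identical(got$sig, want$sig)
    }
  }
  set.seed(7)
  for (len in 4:6) {
    for (rep in 1:50) {
      p <- runif(len)^2
      got <- fdr_bh(p)
      want <- bh_oracle(p)
      expect_equal(got$q, want$q, tolerance = 1e-12)
      expect_identical(got$sig, want$sig)
    }
  }
  expect_true(fdr_bh(0.04)$sig)
  expect_false(any(fdr_bh(rep(1, 5))$sig))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH never declares more discoveries than raw alpha thresholding", {
  set.seed(9)
  for (rep in 1:50) {
    p <- runif(20)^runif(1, 0.5, 3)
    expect_lte(sum(fdr_bh(p)$sig), sum(p < 0.05))
  }
})

test_that("cluster finding partitions exactly the true mask entries", {
  lag_ms <- seq(0, 90, by = 10)
  cl <- find_clusters(c(F, T, T, F, T, F, F, T, T, T), lag_ms)
  expect_equal(cl$t_start, c(10, 40, 70))
  expect_equal(cl$t_end, c(20, 40, 90))
  expect_equal(nrow(find_clusters(rep(FALSE, 10), lag_ms)), 0)
  # reconstruction property on random masks
  set.seed(5)
  for (rep in 1:20) {
    mask <- runif(40) < 0.3
    lags <- seq_len(40) * 5
    cl <- find_clusters(mask, lags)
    rebuilt <- rep(FALSE, 40)
    for (i in seq_len(nrow(cl))) {
      rebuilt[lags >= cl$t_start[i] & lags <= cl$t_end[i]] <- TRUE
    }
    expect_identical(rebuilt, mask)
  }
  # minimum-length filter
  cl2 <- find_clusters(c(T, F, T, T), 1:4, min_len = 2)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$t_start, 3)
})

test_that("window amplitudes summarize the ROI trace by mean or signed peak", {
  W <- matrix(0, 3, 181)
  ls <- lag_spec(-100, 600, 256)
  sel <- ls$times_ms >= 80 & ls$times_ms <= 103
  W[, sel] <- 2
  m <- make_trf(W, channels = c("FCz", "Cz", "CPz"))
  expect_equal(window_amplitude(m, 80, 103), 2)
  # triangle peaking at 3
  W2 <- matrix(0, 2, 181)
  tri <- seq_len(sum(sel)); tri <- 3 * pmin(tri, rev(tri)) / max(pmin(tri, rev(tri)))
  W2[, sel] <- rep(tri, each = 2)
  m2 <- make_trf(W2, channels = c("a", "b"))
  expect_equal(window_amplitude(m2, 80, 103, mode = "peak", polarity = 1), 3)
  expect_equal(window_amplitude(m2, 80, 103, mode = "peak", polarity = -1),
               min(tri))
  expect_error(window_amplitude(m, 80.2, 80.3), "no lag samples")
  expect_error(window_amplitude(m, 80, 103, channels = "Oz"), "Oz")
})

test_that("topographic dominance flags only the truly different channel", {
  set.seed(21)
  n_sub <- 20
  n_ch <- 12
  chs <- paste0("C", seq_len(n_ch))
  mk <- function(shift10) {
    lapply(seq_len(n_sub), function(s) {
      W <- matrix(rnorm(n_ch * 181, sd = 1), n_ch, 181)
      if (shift10) W[10, ] <- W[10, ] + 2
      make_trf(W, channels = chs, subject = paste0("s", s))
    })
  }
  hits10 <- 0; false_pos <- 0
  n_sims <- 40
  for (sim in seq_len(n_sims)) {
    td <- topographic_dominance(mk(TRUE), mk(FALSE), 0, 500)
    hits10 <- hits10 + td$sig[10]
    false_pos <- false_pos + sum(td$sig[-10])
  }
  expect_gte(hits10 / n_sims, 0.95)
  expect_lte(false_pos / (n_sims * (n_ch - 1)), 0.05)
  a <- mk(TRUE); b <- mk(FALSE)
  expect_error(topographic_dominance(a[1:3], b, 0, 500), "paired")
})

test_that("identical conditions give a null dominance map", {
  set.seed(2)
  a <- lapply(1:6, function(s) make_trf(matrix(rnorm(4 * 181), 4, 181),
                                        subject = paste0("s", s)))
  td <- topographic_dominance(a, a, 0, 300)
  expect_equal(td$t, rep(0, 4))
  expect_false(any(td$sig))
})

test_that("GFP vs baseline detects a planted post-onset bump", {
  set.seed(31)
  lag_ms <- lag_spec(-100, 600, 64)$times_ms
  n_sub <- 50
  bump <- exp(-(lag_ms - 200)^2 / (2 * 20^2))
  gfps <- t(vapply(seq_len(n_sub), function(s) {
    abs(1 + 0.1 * rnorm(length(lag_ms))) + 3 * 0.1 * bump
  }, numeric(length(lag_ms))))
  res <- gfp_vs_baseline(gfps, lag_ms)
  expect_true(any(res$sig[lag_ms > 150 & lag_ms < 250]))
  # constant series -> all t = 0
  flat <- matrix(5, 10, length(lag_ms))
  res0 <- gfp_vs_baseline(flat, lag_ms)
  expect_equal(res0$t, rep(0, length(lag_ms)))
  expect_error(gfp_vs_baseline(gfps, lag_ms + 500), "baseline")
})
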