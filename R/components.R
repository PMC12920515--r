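# Component-level statistics: global field power, pointwise paired tests
# with BH-FDR, contiguous-cluster detection, window amplitudes and
# topographic dominance maps.

#' Global field power of a TRF
#'
#' The spatial standard deviation across channels at each lag
#' (Lehmann-Skrandies definition, population convention):
#' `GFP(tau) = sqrt(mean_ch (w(tau, ch) - mean_ch w(tau, .))^2)`.
#'
#' @param model a `trf` with at least 2 channels.
#' @return tibble with `lag_ms`, `gfp`, `subject`, `condition`.
#' @export
gfp <- function(model) {
  stopifnot(inherits(model, "trf"))
  if (nrow(model$weights) < 2) stop("GFP requires at least 2 channels")
  W <- model$weights
  mu <- colMeans(W)
  g <- sqrt(colMeans(sweep(W, 2, mu)^2))
  tibble::tibble(lag_ms = model$lags$times_ms, gfp = g,
                 subject = model$subject %||% NA,
                 condition = model$condition %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stack per-subject GFP series into a [subjects x lags] matrix.
gfp_matrix <- function(models) {
  do.call(rbind, lapply(models, function(m) gfp(m)$gfp))
}

#' Paired t-test (two-tailed)
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y` and `df = n - 1`.
#' Degenerate differences are handled explicitly: all-zero d gives t = 0,
#' p = 1; constant nonzero d gives infinite t, p = 0 (flagged, never
#' silently dropped).
#'
#' @param x,y paired numeric vectors of equal length n >= 2.
#' @return one-row tibble: `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) return(tibble::tibble(t = 0, df = n - 1L, p = 1))
    return(tibble::tibble(t = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  tval <- mean(d) / (sdd / sqrt(n))
  tibble::tibble(t = tval, df = n - 1L,
                 p = 2 * stats::pt(-abs(tval), df = n - 1))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (via `stats::p.adjust(method = "BH")`) and
#' the significance mask `q < alpha`.
#'
#' @param p raw p-values in \[0, 1\].
#' @param alpha significance level (default 0.05).
#' @return list with `q` (adjusted values, monotone) and `sig` (logical).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, sig = q < alpha)
}

#' Pointwise paired comparison along an axis
#'
#' Paired t-test at every point of a per-subject series (lags of a GFP
#' time course, or channels of a topography), with BH-FDR correction over
#' the whole axis — one FDR family per analysis surface.
#'
#' @param x,y matrices `[n_subjects x n_points]`, paired by row.
#' @param axis numeric axis values (e.g. lag times in ms), length
#'   `n_points`.
#' @param alpha FDR level (default 0.05).
#' @return tibble: `axis`, `t`, `df`, `p`, `q`, `sig`.
#' @export
pointwise_paired_test <- function(x, y, axis = seq_len(ncol(x)),
                                  alpha = 0.05) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            length(axis) == ncol(x))
  res <- purrr::map_dfr(seq_len(ncol(x)), function(j) paired_t(x[, j], y[, j]))
  fdr <- fdr_bh(res$p, alpha)
  tibble::tibble(axis = axis, t = res$t, df = res$df, p = res$p,
                 q = fdr$q, sig = fdr$sig)
}

#' Contiguous clusters of significant points
#'
#' Maximal runs of consecutive significant lags, reported as
#' `[first-lag ms, last-lag ms]` on the lag grid (endpoints are lag-sample
#' times, not interpolated).
#'
#' @param sig logical significance mask.
#' @param lag_ms lag times aligned to `sig`.
#' @param min_len minimum run length to report (default 1).
#' @return tibble: `cluster`, `t_start`, `t_end`, `n_lags`; empty mask
#'   gives a zero-row tibble.
#' @export
find_clusters <- function(sig, lag_ms, min_len = 1) {
  stopifnot(length(sig) == length(lag_ms))
  empty <- tibble::tibble(cluster = integer(), t_start = numeric(),
                          t_end = numeric(), n_lags = integer())
  if (!any(sig)) return(empty)
  r <- rle(as.logical(sig))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty)
  tibble::tibble(cluster = seq_len(sum(keep)),
                 t_start = lag_ms[starts[keep]],
                 t_end = lag_ms[ends[keep]],
                 n_lags = r$lengths[keep])
}

#' Canonical TRF component windows
#'
#' The three sensor-level component windows used throughout the package
#' (N1: 80-103 ms negative, P2: 131-185 ms positive, P400: 376-408 ms
#' positive) with their nominal peak polarities. Detected windows from
#' [find_clusters()] can be used instead.
#'
#' @return tibble: `name`, `t_start`, `t_end`, `polarity`.
#' @export
component_windows <- function() {
  tibble::tibble(name = c("N1_TRF", "P2_TRF", "P400_TRF"),
                 t_start = c(80, 131, 376),
                 t_end = c(103, 185, 408),
                 polarity = c(-1, 1, 1))
}

#' TRF amplitude within a component window
#'
#' Channel-averaged TRF weights within `[t_start, t_end]` ms, summarized
#' by the mean (default) or by the signed extremum of the given polarity
#' (`polarity = -1` takes the minimum, as for N1; `+1` the maximum).
#'
#' @param model a `trf`.
#' @param t_start,t_end window bounds in ms, inside the lag range.
#' @param channels channel labels to average over (default: all).
#' @param mode `"mean"` or `"peak"`.
#' @param polarity +1 or -1, used when `mode = "peak"`.
#' @return scalar amplitude.
#' @export
window_amplitude <- function(model, t_start, t_end, channels = NULL,
                             mode = c("mean", "peak"), polarity = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "trf"), t_start < t_end)
  sel_t <- model$lags$times_ms >= t_start & model$lags$times_ms <= t_end
  if (!any(sel_t)) stop("window [", t_start, ", ", t_end,
                        "] ms contains no lag samples")
  sel_ch <- if (is.null(channels)) seq_along(model$channels) else {
    miss <- setdiff(channels, model$channels)
    if (length(miss) > 0) stop("unknown channel(s): ", paste(miss, collapse = ", "))
    match(channels, model$channels)
  }
  trace <- colMeans(model$weights[sel_ch, sel_t, drop = FALSE])
  if (mode == "mean") mean(trace)
  else if (polarity < 0) min(trace) else max(trace)
}

#' Per-subject window amplitudes as a tidy table
#'
#' @param models list of `trf` models (one per subject).
#' @param windows tibble as from [component_windows()].
#' @inheritParams window_amplitude
#' @return tibble: `subject`, `condition`, `window`, `amplitude`.
#' @export
window_amplitudes <- function(models, windows = component_windows(),
                              channels = NULL, mode = "mean") {
  purrr::map_dfr(models, function(m) {
    purrr::map_dfr(seq_len(nrow(windows)), function(i) {
      tibble::tibble(
        subject = m$subject %||% NA,
        condition = m$condition %||% NA,
        window = windows$name[i],
        amplitude = window_amplitude(m, windows$t_start[i], windows$t_end[i],
                                     channels = channels, mode = mode,
                                     polarity = windows$polarity[i]))
    })
  })
}

#' Topographic dominance map between conditions
#'
#' Window-mean amplitude per channel per subject in each condition, a
#' paired t-test per channel, and BH-FDR across channels: a signed t map
#' with its significance mask (positive t = first condition dominant).
#'
#' @param models_a,models_b lists of `trf` models, paired by position
#'   (same subjects, two conditions).
#' @param t_start,t_end window bounds in ms.
#' @param alpha FDR level.
#' @return tibble: `channel`, `t`, `df`, `p`, `q`, `sig`.
#' @export
topographic_dominance <- function(models_a, models_b, t_start, t_end,
                                  alpha = 0.05) {
  if (length(models_a) != length(models_b)) {
    stop("conditions must contain the same (paired) subjects")
  }
  subj_a <- vapply(models_a, function(m) as.character(m$subject %||% NA), character(1))
  subj_b <- vapply(models_b, function(m) as.character(m$subject %||% NA), character(1))
  if (!all(is.na(subj_a)) && !identical(subj_a, subj_b)) {
    stop("conditions must contain the same (paired) subjects")
  }
  win_map <- function(m) {
    sel <- m$lags$times_ms >= t_start & m$lags$times_ms <= t_end
    if (!any(sel)) stop("window contains no lag samples")
    rowMeans(m$weights[, sel, drop = FALSE])
  }
  A <- do.call(rbind, lapply(models_a, win_map))
  B <- do.call(rbind, lapply(models_b, win_map))
  res <- pointwise_paired_test(A, B, axis = seq_len(ncol(A)), alpha = alpha)
  res$axis <- models_a[[1]]$channels
  names(res)[1] <- "channel"
  res
}

#' GFP versus its pre-onset baseline
#'
#' Per subject, the baseline is the mean GFP over the `baseline` lag
#' window (default -100..0 ms); GFP at every lag is compared with that
#' baseline by a pointwise paired t-test with FDR across lags, marking
#' the lags with a reliable response.
#'
#' @param gfps matrix `[n_subjects x n_lags]` of per-subject GFP series.
#' @param lag_ms lag axis in ms.
#' @param baseline baseline window in ms (default `c(-100, 0)`).
#' @param alpha FDR level.
#' @return tibble: `lag_ms`, `t`, `df`, `p`, `q`, `sig`.
#' @export
gfp_vs_baseline <- function(gfps, lag_ms, baseline = c(-100, 0),
                            alpha = 0.05) {
  stopifnot(is.matrix(gfps), length(lag_ms) == ncol(gfps))
  sel <- lag_ms >= baseline[1] & lag_ms <= baseline[2]
  if (!any(sel)) stop("lag axis contains no baseline samples")
  base <- rowMeans(gfps[, sel, drop = FALSE])
  res <- pointwise_paired_test(gfps, matrix(base, nrow(gfps), ncol(gfps)),
                               axis = lag_ms, alpha = alpha)
  names(res)[1] <- "lag_ms"
  res
}
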