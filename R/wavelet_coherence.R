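# Morlet continuous wavelet transform, wavelet transform coherence (WTC),
# band averaging, and ROI-pair coupling aggregation.

#' Continuous wavelet transform with an analytic Morlet wavelet
#'
#' FFT implementation of the CWT with the analytic Morlet mother wavelet
#' (nondimensional frequency omega0 = 6). Scales map to frequencies as
#' `f = omega0 / (2 pi s)`; the default grid is log-spaced at `dj = 1/12`
#' octaves covering `flo`-`fhi` Hz so the hemodynamic band is interior.
#' Edge effects are tracked by the e-folding time `sqrt(2) * s`: the cone
#' of influence is reported as the lowest edge-safe frequency per time
#' point.
#'
#' @param x Numeric series (finite values).
#' @param fs Sampling rate, Hz.
#' @param flo,fhi Frequency range of the scale grid, Hz.
#' @param dj Scale resolution, octaves (default 1/12).
#' @param omega0 Morlet parameter (default 6).
#' @return A `cwt_result`: `W` (complex, nscale x ntime), `freqs` (Hz,
#'   descending), `scales` (s), `times` (s), `coi_freq` (Hz per time point;
#'   cells with `freq >= coi_freq` are edge-safe), `fs`, `omega0`, `dj`.
#' @export
cwt_morlet <- function(x, fs, flo = 0.01, fhi = 0.5, dj = 1 / 12,
                       omega0 = hypersync_constants$omega0) {
  if (anyNA(x) || any(!is.finite(x))) stop("NaN or non-finite input")
  n <- length(x)
  dt <- 1 / fs
  noct <- log2(fhi / flo)
  freqs <- fhi * 2^(-seq(0, noct, by = dj))        # descending
  scales <- omega0 / (2 * pi * freqs)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  X <- stats::fft(xp)
  wk <- 2 * pi * fs * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / npad
  W <- matrix(0i, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * wk - omega0)^2 / 2) * (wk > 0)
    w <- stats::fft(X * psi, inverse = TRUE) / npad
    W[si, ] <- w[seq_len(n)]
  }
  tt <- (seq_len(n) - 1) * dt
  edge_dist <- pmax(pmin(tt, (n - 1) * dt - tt), dt)
  coi_freq <- sqrt(2) * omega0 / (2 * pi * edge_dist)
  structure(list(W = W, freqs = freqs, scales = scales, times = tt,
                 coi_freq = coi_freq, fs = fs, omega0 = omega0, dj = dj),
            class = "cwt_result")
}

# Smoothing operator of the Grinsted WTC definition: per scale, a Gaussian
# filter in time with sigma = s, then a boxcar across scales of width 0.6
# octaves (renormalized at the grid edges). `z` is nscale x ntime (complex
# allowed); rows correspond to `scales`.
wtc_smooth <- function(z, scales, fs, dj) {
  ns <- nrow(z)
  n <- ncol(z)
  npad <- 2^ceiling(log2(n))
  wk <- 2 * pi * fs * c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) / npad
  out <- z
  for (si in seq_len(ns)) {
    row <- c(z[si, ], rep(0, npad - n))
    filt <- exp(-0.5 * (scales[si] * wk)^2)
    sm <- stats::fft(stats::fft(row) * filt, inverse = TRUE) / npad
    out[si, ] <- sm[seq_len(n)]
  }
  # scale smoothing: boxcar over ~0.6 octaves
  nb <- max(1L, round(0.6 / dj))
  if (nb > 1L) {
    half <- nb %/% 2L
    cum <- rbind(0, apply(out, 2, cumsum))
    lo <- pmax(1L, seq_len(ns) - half)
    hi <- pmin(ns, seq_len(ns) + half)
    out <- (cum[hi + 1L, , drop = FALSE] - cum[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  out
}

#' Wavelet transform coherence between two series
#'
#' Squared coherence
#' `R2(t, s) = |S(W_xy / s)|^2 / (S(|W_x|^2 / s) * S(|W_y|^2 / s))`
#' with `S` the smoothing operator of the cited Matlab toolbox definition: a
#' Gaussian filter in time (sigma = s) followed by a boxcar across scales
#' (0.6 octaves). Without smoothing the ratio is identically 1, so the
#' smoothing operator is what gives coherence its meaning; `smooth = FALSE`
#' exists only to demonstrate that degeneracy in regression tests.
#'
#' @param x,y Numeric series of equal length.
#' @param fs Sampling rate, Hz.
#' @param flo,fhi,dj,omega0 Passed to [cwt_morlet()].
#' @param smooth Apply the smoothing operator (default TRUE).
#' @return A `wtc_result`: `R2` (nscale x ntime in \[0,1\]), `freqs`,
#'   `times`, `coi_freq`, `fs`, plus the grid metadata.
#' @export
wtc <- function(x, y, fs, flo = 0.01, fhi = 0.5, dj = 1 / 12,
                omega0 = hypersync_constants$omega0, smooth = TRUE) {
  if (length(x) != length(y)) stop("mismatched series lengths")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance series")
  cx <- cwt_morlet(x, fs, flo, fhi, dj, omega0)
  cy <- cwt_morlet(y, fs, flo, fhi, dj, omega0)
  wtc_from_cwt(cx, cy, smooth = smooth)
}

# WTC from two precomputed CWTs on the same grid (lets callers cache
# per-channel transforms when forming many channel pairs).
wtc_from_cwt <- function(cx, cy, smooth = TRUE) {
  stopifnot(identical(cx$scales, cy$scales), ncol(cx$W) == ncol(cy$W))
  sc <- cx$scales
  inv_s <- 1 / sc
  Wxy <- (cx$W * Conj(cy$W)) * inv_s
  Px <- (Mod(cx$W)^2) * inv_s
  Py <- (Mod(cy$W)^2) * inv_s
  if (smooth) {
    Wxy <- wtc_smooth(Wxy, sc, cx$fs, cx$dj)
    Px <- Re(wtc_smooth(Px, sc, cx$fs, cx$dj))
    Py <- Re(wtc_smooth(Py, sc, cx$fs, cx$dj))
  }
  R2 <- Mod(Wxy)^2 / (Px * Py)
  R2[R2 > 1] <- 1
  R2[R2 < 0] <- 0
  structure(list(R2 = R2, freqs = cx$freqs, scales = sc, times = cx$times,
                 coi_freq = cx$coi_freq, fs = cx$fs, dj = cx$dj,
                 omega0 = cx$omega0),
            class = "wtc_result")
}

#' Band-averaged coherence
#'
#' Unweighted mean of `R2` over all (time, frequency) cells with frequency
#' inside `[f_lo, f_hi]` and outside the cone of influence; cells
#' contaminated by edge effects never enter the average. Also reports the
#' effective band floor: the lowest band frequency with at least one
#' edge-safe cell (for 120 s recordings this sits above the nominal
#' 0.015 Hz edge, because a 67 s period cannot clear the e-folding
#' boundary).
#'
#' @param res A `wtc_result`.
#' @param f_lo,f_hi Band edges, Hz (inclusive; default 0.015-0.15).
#' @param time_range Optional `c(t0, t1)` in seconds restricting the cells
#'   to a condition block.
#' @return List: `band_mean` (mean R2), `band_mean_z`
#'   (`atanh(sqrt(band_mean))`), `effective_band_floor_hz`, `n_cells`.
#' @export
band_average <- function(res, f_lo = hypersync_constants$band_hz[1],
                         f_hi = hypersync_constants$band_hz[2],
                         time_range = NULL) {
  stopifnot(inherits(res, "wtc_result"))
  frows <- which(res$freqs >= f_lo & res$freqs <= f_hi)
  if (!length(frows)) stop("band outside the scale grid")
  tcols <- seq_along(res$times)
  if (!is.null(time_range))
    tcols <- which(res$times >= time_range[1] & res$times < time_range[2])
  valid <- outer(res$freqs[frows], res$coi_freq[tcols], `>=`)
  if (!any(valid))
    stop("no COI-valid cells in band; recording too short for f_lo")
  vals <- res$R2[frows, tcols, drop = FALSE][valid]
  band_mean <- mean(vals)
  floor_hz <- min(res$freqs[frows][rowSums(valid) > 0])
  list(band_mean = band_mean,
       band_mean_z = fisher_z(sqrt(band_mean)),
       effective_band_floor_hz = floor_hz,
       n_cells = length(vals))
}
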