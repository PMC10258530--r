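# Behavioral synchrony: velocity extraction, CVV, lagged windowed sync maps,
# thresholded sync moments, summaries, outlier exclusion, pseudo-dyad nulls.

#' Instantaneous 3D velocity from a motion trace
#'
#' First differences of consecutive positions scaled by the sampling rate:
#' `v[k] = (pos[k+1] - pos[k]) * fs`, units per second; length n - 1.
#'
#' @param trace A [motion_trace()].
#' @return A `velocity_series`: list with `v` ((n-1) x 3 matrix), `fs`,
#'   `participant_id`, `condition`, `smoothed`.
#' @export
compute_velocity <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- nrow(trace$pos)
  if (n < 2) stop("need at least 2 samples to compute velocity")
  v <- diff(trace$pos) * trace$fs
  structure(list(participant_id = trace$participant_id,
                 condition = trace$condition, fs = trace$fs,
                 v = v, smoothed = FALSE, window_ms = NA_real_),
            class = "velocity_series")
}

#' Gaussian smoothing of a velocity series
#'
#' Each axis is convolved with a Gaussian kernel of full width `window_ms`
#' (sigma = window_ms / 4, truncated at +-2 sigma), renormalized at the
#' edges so constants pass through unchanged; output length is preserved.
#' The default 100 ms window suppresses tracker jitter without smearing
#' hand-movement dynamics.
#'
#' @param vs A `velocity_series` (from [compute_velocity()]) or a numeric
#'   vector/matrix with rows as time (then `fs` must be given).
#' @param window_ms Kernel full width, ms (> 0; default 100).
#' @param fs Sampling rate, needed only for plain numeric input.
#' @return Smoothed object of the same type.
#' @export
gaussian_smooth <- function(vs, window_ms = 100, fs = NULL) {
  if (window_ms <= 0) stop("window_ms must be > 0")
  smooth_mat <- function(m, fs) {
    sigma <- window_ms / 4 / 1000 * fs          # sigma in samples
    half <- max(1L, ceiling(2 * sigma))
    w <- stats::dnorm(-half:half, sd = sigma)
    n <- nrow(m)
    out <- m
    # edge-renormalized convolution
    csum <- cumsum(w)
    for (col in seq_len(ncol(m))) {
      padded <- c(rep(0, half), m[, col], rep(0, half))
      num <- stats::filter(padded, w, sides = 2)[(half + 1):(half + n)]
      # denominator: kernel mass actually overlapping the series
      lo <- pmax(1L, half + 1L - (seq_len(n) - 1L))
      hi <- pmin(length(w), half + 1L + (n - seq_len(n)))
      denom <- csum[hi] - c(0, csum)[lo]
      out[, col] <- as.numeric(num) / denom
    }
    out
  }
  if (is.numeric(vs)) {
    if (is.null(fs)) stop("fs required for plain numeric input")
    m <- if (is.matrix(vs)) vs else matrix(vs, ncol = 1)
    res <- smooth_mat(m, fs)
    return(if (is.matrix(vs)) res else drop(res))
  }
  stopifnot(inherits(vs, "velocity_series"))
  vs$v <- smooth_mat(vs$v, vs$fs)
  vs$smoothed <- TRUE
  vs$window_ms <- window_ms
  vs
}

#' Cosine of the angle between two 3D velocity vectors (CVV)
#'
#' `cvv = <vi, vj> / (|vi| |vj|)`, in \[-1, 1\]: 1 for identical movement
#' direction, -1 for mirror-like (opposite) movement, 0 for orthogonal
#' movement. When either speed is below `eps` (stillness) the value is
#' defined as 0: no direction carries no alignment evidence.
#'
#' @param vi,vj Numeric 3-vectors, or n x 3 matrices (row-wise evaluation).
#' @param eps Stillness threshold on the speed, units/s.
#' @return Numeric scalar or vector in \[-1, 1\].
#' @export
cvv <- function(vi, vj, eps = 1e-9) {
  if (is.null(dim(vi))) vi <- matrix(vi, ncol = 3)
  if (is.null(dim(vj))) vj <- matrix(vj, ncol = 3)
  num <- rowSums(vi * vj)
  ni <- sqrt(rowSums(vi^2))
  nj <- sqrt(rowSums(vj^2))
  out <- ifelse(ni < eps | nj < eps, 0, num / (ni * nj))
  out <- pmin(1, pmax(-1, out))
  if (length(out) == 1) out[[1]] else out
}

#' Lag-resolved windowed synchrony map
#'
#' For each lag tau on a symmetric grid (default +-750 ms in 10 ms steps),
#' participant j's velocity is aligned at `t + tau` against participant i's
#' at `t` (positive lag = j trails i; fractional-sample shifts use linear
#' interpolation), the per-sample `|CVV|` is computed, and a centered moving
#' average of `window_s` (default 2 s) is applied. Only fully overlapping,
#' fully windowed time points are kept, so the map contains no partial
#' estimates. The sync mask marks cells above the `|CVV|` threshold
#' (default 0.35).
#'
#' @param vi,vj `velocity_series` of the two participants (equal `fs`).
#' @param max_lag_ms,step_ms Lag grid half-range and step, ms.
#' @param window_s Moving-average window, seconds.
#' @param threshold Sync threshold on windowed `|CVV|`.
#' @param dyad_id Dyad label carried into the result.
#' @return A `sync_map`: `lags_ms`, `times_s`, `C` (time x lag, in \[0,1\]),
#'   `sync_mask`, `threshold`, `window_s`, `fs`, `condition`, `dyad_id`.
#' @export
lagged_sync_map <- function(vi, vj, max_lag_ms = 750, step_ms = 10,
                            window_s = 2, threshold = 0.35,
                            dyad_id = NA_character_) {
  stopifnot(inherits(vi, "velocity_series"), inherits(vj, "velocity_series"))
  if (vi$fs != vj$fs) stop("mismatched sampling rates")
  fs <- vi$fs
  n <- min(nrow(vi$v), nrow(vj$v))
  need <- window_s + 2 * max_lag_ms / 1000
  if (n / fs < need)
    stop("traces too short: need at least ", need, " s of overlap")
  lags_ms <- seq(-max_lag_ms, max_lag_ms, by = step_ms)
  shift <- lags_ms / 1000 * fs                  # samples, possibly fractional
  mpad <- ceiling(max(abs(shift)))
  tidx <- (1 + mpad):(n - mpad)                 # fully overlapping samples
  A <- vi$v[tidx, , drop = FALSE]
  absC <- matrix(NA_real_, length(tidx), length(lags_ms))
  for (li in seq_along(lags_ms)) {
    s <- shift[li]
    f <- floor(s)
    fr <- s - f
    i0 <- tidx + f
    B <- if (fr == 0) {
      vj$v[i0, , drop = FALSE]
    } else {
      (1 - fr) * vj$v[i0, , drop = FALSE] + fr * vj$v[i0 + 1L, , drop = FALSE]
    }
    absC[, li] <- abs(cvv(A, B))
  }
  w <- max(1L, round(window_s * fs))
  Cm <- apply(absC, 2, function(x) stats::filter(x, rep(1 / w, w), sides = 2))
  keep <- which(!is.na(Cm[, 1]))
  Cm <- Cm[keep, , drop = FALSE]
  structure(
    list(dyad_id = dyad_id, condition = vi$condition,
         lags_ms = lags_ms, times_s = (tidx[keep] - 1) / fs,
         C = unname(Cm), sync_mask = unname(Cm > threshold),
         threshold = threshold, window_s = window_s, fs = fs),
    class = "sync_map")
}

#' Synchrony summary for one dyad and condition
#'
#' Sync moments are time points where windowed `|CVV|` exceeds the threshold.
#' `lag0_sync` is the proportion of time synchronized at lag 0;
#' `lagged_sync` at any lag with `|lag| > 30 ms`; `total_sync` combines the
#' two regimes with a per-time-point OR. `fisher_z_mean_cvv` is
#' `atanh` of the time-and-lag mean of `|CVV|` (clipped below 1).
#'
#' @param map A `sync_map`.
#' @param group `"real"` or `"pseudo"`.
#' @return A one-row data frame (class `sync_summary`): `dyad_id`,
#'   `condition`, `group`, `total_sync`, `lag0_sync`, `lagged_sync`,
#'   `fisher_z_mean_cvv`.
#' @export
total_sync <- function(map, group = "real") {
  stopifnot(inherits(map, "sync_map"))
  if (length(map$times_s) == 0) stop("empty sync map")
  lag0 <- which(map$lags_ms == 0)
  lagged <- which(abs(map$lags_ms) > 30)
  at_lag0 <- map$sync_mask[, lag0]
  at_lagged <- apply(map$sync_mask[, lagged, drop = FALSE], 1, any)
  out <- data.frame(
    dyad_id = map$dyad_id, condition = map$condition, group = group,
    total_sync = mean(at_lag0 | at_lagged),
    lag0_sync = mean(at_lag0),
    lagged_sync = mean(at_lagged),
    fisher_z_mean_cvv = fisher_z(mean(map$C)),
    stringsAsFactors = FALSE)
  class(out) <- c("sync_summary", "data.frame")
  out
}

#' Fisher z-transformation
#'
#' `atanh(r)`, with the argument clipped to `+-(1 - 1e-12)` so perfect
#' synthetic copies do not produce infinities.
#'
#' @param r Correlation-like values in \[-1, 1\].
#' @return `atanh` of the clipped values.
#' @export
fisher_z <- function(r) {
  atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, r)))
}

#' Single-pass standard-deviation outlier exclusion
#'
#' Removes values outside `mean +- k * SD`, both computed once on the full
#' set (no iteration). With zero SD (all values equal) nothing is removed.
#'
#' @param values Numeric vector (length >= 3).
#' @param k SD multiplier (default 2.5).
#' @return List: `kept` (values), `removed_idx` (indices into `values`),
#'   `removed_fraction`.
#' @export
exclude_outliers <- function(values, k = 2.5) {
  if (length(values) < 3) stop("need at least 3 values")
  m <- mean(values)
  s <- stats::sd(values)
  removed <- if (s == 0) integer(0) else
    which(values < m - k * s | values > m + k * s)
  list(kept = if (length(removed)) values[-removed] else values,
       removed_idx = removed,
       removed_fraction = length(removed) / length(values))
}

#' Pseudo-dyad pairing plan
#'
#' Builds the permutation-null pairing: each pseudo dyad takes participant 1
#' of dyad i and participant 2 of dyad sigma(i), with sigma a derangement
#' (sigma(i) != i), so no pseudo pair shares a real dyad. One pseudo dyad
#' per real dyad; deterministic given the seed.
#'
#' @param dyad_ids Character vector of real dyad ids (length >= 2).
#' @param seed Integer seed.
#' @return Data frame: `pseudo_id`, `dyad_a` (supplies participant 1),
#'   `dyad_b` (supplies participant 2).
#' @export
pseudo_pairings <- function(dyad_ids, seed = 1) {
  n <- length(dyad_ids)
  if (n < 2) stop("pseudo-dyad construction requires >= 2 real dyads")
  withr::with_seed(as.integer(seed), {
    repeat {
      sigma <- sample.int(n)
      if (all(sigma != seq_len(n))) break
    }
    data.frame(pseudo_id = paste0("pseudo", seq_len(n)),
               dyad_a = dyad_ids,
               dyad_b = dyad_ids[sigma],
               stringsAsFactors = FALSE)
  })
}

#' Construct pseudo dyads from real dyads' motion traces
#'
#' Applies the [pseudo_pairings()] scheme to a list of real dyad datasets,
#' condition-matched (BB traces are paired with BB traces, and so on).
#'
#' @param dyads List of real dyads; each element is a list with `dyad_id`
#'   and `traces`, a list of [motion_trace()] objects (two participants,
#'   any set of conditions).
#' @param seed Integer seed.
#' @return List of pseudo dyads in the same structure, with
#'   `group = "pseudo"`.
#' @export
make_pseudo_dyads <- function(dyads, seed = 1) {
  ids <- vapply(dyads, function(d) d$dyad_id, character(1))
  plan <- pseudo_pairings(ids, seed)
  by_id <- stats::setNames(dyads, ids)
  member_traces <- function(dyad, member, conds = NULL) {
    pids <- unique(vapply(dyad$traces, function(tr) tr$participant_id,
                          character(1)))
    pid <- pids[member]
    Filter(function(tr) tr$participant_id == pid, dyad$traces)
  }
  lapply(seq_len(nrow(plan)), function(i) {
    ta <- member_traces(by_id[[plan$dyad_a[i]]], 1)
    tb <- member_traces(by_id[[plan$dyad_b[i]]], 2)
    conds <- intersect(
      vapply(ta, function(tr) tr$condition, character(1)),
      vapply(tb, function(tr) tr$condition, character(1)))
    keep <- function(trs) Filter(function(tr) tr$condition %in% conds, trs)
    list(dyad_id = plan$pseudo_id[i], group = "pseudo",
         traces = c(keep(ta), keep(tb)))
  })
}

#' Movement synchrony for one dyad across conditions
#'
#' Convenience wrapper: velocity, 100 ms Gaussian smoothing, lagged sync
#' map and summary per condition.
#'
#' @param dyad List with `dyad_id`, optional `group`, and `traces` (two
#'   participants x conditions of [motion_trace()]).
#' @param ... Passed to [lagged_sync_map()].
#' @return Data frame of per-condition [total_sync()] summaries.
#' @export
dyad_sync_summary <- function(dyad, ...) {
  conds <- unique(vapply(dyad$traces, function(tr) tr$condition, character(1)))
  pids <- unique(vapply(dyad$traces, function(tr) tr$participant_id,
                        character(1)))
  stopifnot(length(pids) == 2)
  rows <- lapply(conds, function(cond) {
    trs <- Filter(function(tr) tr$condition == cond, dyad$traces)
    vi <- gaussian_smooth(compute_velocity(
      trs[[which(vapply(trs, function(x) x$participant_id, character(1)) == pids[1])]]))
    vj <- gaussian_smooth(compute_velocity(
      trs[[which(vapply(trs, function(x) x$participant_id, character(1)) == pids[2])]]))
    m <- lagged_sync_map(vi, vj, dyad_id = dyad$dyad_id, ...)
    total_sync(m, group = dyad$group %||% "real")
  })
  do.call(rbind, rows)
}
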