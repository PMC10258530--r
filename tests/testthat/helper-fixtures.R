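# Shared fixtures: small layouts, direct hemo-series construction, quick
# simulation wrappers, and the naive reference implementation of the lagged
# sync map used as an oracle.

# n-channel layout on a line, optionally with ROI labels.
tiny_layout <- function(n = 4, rois = NULL, spacing_cm = 3) {
  df <- data.frame(channel = sprintf("c%d", seq_len(n)),
                   source_x = (seq_len(n) - 1) * spacing_cm - 1.75,
                   source_y = 0, source_z = 0,
                   detector_x = (seq_len(n) - 1) * spacing_cm + 1.75,
                   detector_y = 0, detector_z = 0)
  if (!is.null(rois)) df$roi <- rois
  channel_layout(df)
}

# 2D grid layout (nx x ny patch, like a cap segment) with checkerboard
# parity returned alongside, for spatial-frequency filter tests.
grid_layout <- function(nx = 4, ny = 3, spacing_cm = 3) {
  g <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  df <- data.frame(channel = sprintf("g%d", seq_len(nrow(g))),
                   source_x = g$ix * spacing_cm - 1.75,
                   source_y = g$iy * spacing_cm, source_z = 0,
                   detector_x = g$ix * spacing_cm + 1.75,
                   detector_y = g$iy * spacing_cm, detector_z = 0)
  list(layout = channel_layout(df), parity = (-1)^(g$ix + g$iy))
}

# Direct hemo_series construction for filter tests.
make_hemo <- function(hbo, fs = 10, pid = "P1",
                      ids = sprintf("c%d", seq_len(nrow(hbo)))) {
  structure(list(hbo = hbo, hbr = hbo * 0, fs = fs,
                 channel_ids = ids, participant_id = pid,
                 qc = stats::setNames(rep("ok", nrow(hbo)), ids),
                 dpf = hypersync_constants$dpf_default,
                 extinction = hypersync_constants$extinction),
            class = "hemo_series")
}

# total_sync for a simulated dyad at given coupling, duration, seed.
sim_total_sync <- function(coupling, seed, duration_s = 15, lag_ms = 0,
                           move_frac = 0.55) {
  cfg <- motion_sim_config(coupling = coupling, lag_ms = lag_ms,
                           duration_s = duration_s, move_frac = move_frac,
                           seed = seed)
  tr <- simulate_dyad_motion(cfg)
  m <- lagged_sync_map(gaussian_smooth(compute_velocity(tr[[1]])),
                       gaussian_smooth(compute_velocity(tr[[2]])))
  total_sync(m)$total_sync
}

# Naive reference for lagged_sync_map: explicit loops over lag, time and
# window, sharing only the definition (per-lag linear interpolation of the
# shifted series, per-sample |cvv|, centered moving average, valid region).
naive_sync_map <- function(vi, vj, max_lag_ms = 750, step_ms = 10,
                           window_s = 2) {
  fs <- vi$fs
  n <- min(nrow(vi$v), nrow(vj$v))
  lags_ms <- seq(-max_lag_ms, max_lag_ms, by = step_ms)
  shift <- lags_ms / 1000 * fs
  mpad <- ceiling(max(abs(shift)))
  tidx <- (1 + mpad):(n - mpad)
  inst <- matrix(NA_real_, length(tidx), length(lags_ms))
  for (li in seq_along(lags_ms)) {
    for (ti in seq_along(tidx)) {
      t <- tidx[ti]
      s <- t + shift[li]
      f <- floor(s); fr <- s - f
      b <- if (fr == 0) vj$v[f, ] else (1 - fr) * vj$v[f, ] + fr * vj$v[f + 1, ]
      inst[ti, li] <- abs(cvv(vi$v[t, ], b))
    }
  }
  w <- round(window_s * fs)
  half_lo <- (w - 1) %/% 2
  half_hi <- w - 1 - half_lo
  keep <- (1 + half_lo):(length(tidx) - half_hi)
  C <- matrix(NA_real_, length(keep), length(lags_ms))
  for (li in seq_along(lags_ms)) {
    for (ki in seq_along(keep)) {
      idx <- (keep[ki] - half_lo):(keep[ki] + half_hi)
      C[ki, li] <- mean(inst[idx, li])
    }
  }
  C
}
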