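test_that("Morlet CWT localizes sinusoids and is linear in amplitude", {
  fs <- 10
  t <- seq(0, 204.7, by = 1 / fs)
  f0 <- 0.1
  x <- sin(2 * pi * f0 * t)
  cw <- cwt_morlet(x, fs)
  # power maximized at the scale nearest f0 (time-averaged, mid-recording)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  pw <- rowMeans(Mod(cw$W[, mid])^2)
  expect_lt(abs(cw$freqs[which.max(pw)] - f0), 0.05 * f0)
  # amplitude scaling
  cw3 <- cwt_morlet(3 * x, fs)
  expect_equal(Mod(cw3$W), 3 * Mod(cw$W), tolerance = 1e-8)
  expect_error(cwt_morlet(c(1, NA, 2), fs), "NaN")
})

test_that("CWT satisfies a Parseval-type energy identity", {
  fs <- 10
  set.seed(13)
  # in-grid band-limited signal so energy outside the scale range is negligible
  x <- hypersync:::band_limited_gp(2048, fs, c(0.03, 0.3))
  cw <- cwt_morlet(x, fs, flo = 0.005, fhi = 1)
  dj <- cw$dj; dt <- 1 / fs; Cdelta <- 0.776   # Morlet omega0 = 6
  est <- dj * dt / (Cdelta * length(x)) *
    sum(sweep(Mod(cw$W)^2, 1, cw$scales, `/`))
  expect_equal(est, stats::var(x) * (length(x) - 1) / length(x),
               tolerance = 0.05)
})

test_that("self-coherence is 1 and smoothing is what makes WTC informative", {
  fs <- 10
  set.seed(14)
  x <- hypersync:::band_limited_gp(1200, fs, c(0.015, 0.15)) +
    0.1 * rnorm(1200)
  y <- hypersync:::band_limited_gp(1200, fs, c(0.015, 0.15)) +
    0.1 * rnorm(1200)
  rs <- wtc(x, x, fs)
  valid <- outer(rs$freqs, rs$coi_freq, `>=`)
  expect_true(all(abs(rs$R2[valid] - 1) < 1e-6))
  # without smoothing the coherence ratio degenerates to 1 for ANY pair
  r0 <- wtc(x, y, fs, smooth = FALSE)
  expect_true(all(abs(r0$R2 - 1) < 1e-8))
  # with smoothing, independent signals fall well below 1
  r1 <- wtc(x, y, fs)
  expect_lt(mean(r1$R2[valid]), 0.9)
  expect_error(wtc(x, y[-1], fs), "mismatched")
  expect_error(wtc(x, rep(0, 1200), fs), "zero-variance")
})

test_that("WTC is symmetric and invariant to amplitude scaling", {
  fs <- 10
  set.seed(15)
  x <- hypersync:::band_limited_gp(600, fs, c(0.02, 0.2))
  y <- 0.5 * x + 0.5 * hypersync:::band_limited_gp(600, fs, c(0.02, 0.2))
  expect_equal(wtc(x, y, fs)$R2, wtc(y, x, fs)$R2, tolerance = 1e-12)
  expect_equal(wtc(5 * x, 0.2 * y, fs)$R2, wtc(x, y, fs)$R2,
               tolerance = 1e-10)
})

test_that("two phase-locked sinusoids cohere in their frequency band", {
  fs <- 10
  t <- seq(0, 239.9, by = 1 / fs)
  f0 <- 0.08
  set.seed(16)
  x <- sin(2 * pi * f0 * t) + 0.2 * rnorm(length(t))
  y <- sin(2 * pi * f0 * t + pi / 3) + 0.2 * rnorm(length(t))
  rs <- wtc(x, y, fs)
  ba <- band_average(rs, f_lo = 0.06, f_hi = 0.1)
  expect_gt(ba$band_mean, 0.9)
})

test_that("band averaging respects the COI and reports the effective floor", {
  fs <- 10
  set.seed(17)
  x <- hypersync:::band_limited_gp(1200, fs, c(0.015, 0.15)) + 0.05 * rnorm(1200)
  rs <- wtc(x, x, fs)
  # constant R2 -> band mean equals that constant
  rc <- rs; rc$R2[] <- 0.4
  expect_equal(band_average(rc)$band_mean, 0.4)
  # 120 s recording: COI pushes the usable floor above the nominal 0.015 Hz
  ba <- band_average(rs)
  expect_gt(ba$effective_band_floor_hz, 0.015)
  expect_lt(ba$effective_band_floor_hz, 0.15)
  # band outside the scale grid errors
  expect_error(band_average(rs, f_lo = 2, f_hi = 5), "outside")
  # no COI-valid cells: short recording at very low frequency
  xs <- x[1:200]
  expect_error(band_average(wtc(xs, xs, fs), f_lo = 0.012, f_hi = 0.015),
               "COI")
})

test_that("ROI-pair coupling counts channel pairs and never self-pairs", {
  lay <- tiny_layout(4, rois = c("L.IFG", "L.IFG", "dmPFC", "dmPFC"))
  design <- default_design("d1", c("a", "b"), conditions = "FM",
                           duration_s = 120)
  cfg <- nirs_sim_config(duration_s = 120, cardiac_amp = 0, resp_amp = 0,
                         mayer_amp = 0, global_amp = 0, spike_rate = 0,
                         seed = 18)
  pair <- simulate_dyad_nirs(cfg, lay, NULL, ids = c("a", "b"))
  hA <- beer_lambert(intensity_to_od(pair[[1]]), lay)
  hB <- beer_lambert(intensity_to_od(pair[[2]]), lay)
  recs <- roi_pair_coupling(hA, hB, lay, design, scope = "between")
  # 3 ROI pairs (L-L, d-d, L-d); homologous pairs have 2x2 = 4 channel pairs
  expect_equal(nrow(recs), 3)
  expect_equal(recs$n_channel_pairs[recs$roi_pair == "L.IFG-L.IFG"], 4)
  expect_equal(recs$n_channel_pairs[recs$roi_pair == "L.IFG-dmPFC"], 8)
  expect_true(all(recs$scope == "between"))
  expect_true(all(is.finite(recs$wtc_z)))
  # within-brain: distinct-ROI pairs only, no channel paired with itself
  recw <- roi_pair_coupling(hA, NULL, lay, design, scope = "within")
  expect_equal(unique(recw$roi_pair), "L.IFG-dmPFC")
  expect_equal(recw$n_channel_pairs, 4)      # 2 x 2 across the two ROIs
})

test_that("a selectively coupled ROI pair dominates the coupling table", {
  lay <- tiny_layout(4, rois = c("L.IFG", "L.IFG", "dmPFC", "dmPFC"))
  design <- default_design("d1", c("a", "b"), conditions = "FM",
                           duration_s = 120)
  cfg <- nirs_sim_config(duration_s = 120, cardiac_amp = 0, resp_amp = 0,
                         mayer_amp = 0, global_amp = 0, spike_rate = 0,
                         seed = 19)
  plan <- data.frame(channel_a = c("c1", "c2"), channel_b = c("c1", "c2"),
                     rho = 1)
  pair <- simulate_dyad_nirs(cfg, lay, plan, ids = c("a", "b"))
  hA <- beer_lambert(intensity_to_od(pair[[1]]), lay)
  hB <- beer_lambert(intensity_to_od(pair[[2]]), lay)
  recs <- roi_pair_coupling(hA, hB, lay, design, scope = "between")
  target <- recs$wtc_z[recs$roi_pair == "L.IFG-L.IFG"]
  others <- recs$wtc_z[recs$roi_pair != "L.IFG-L.IFG"]
  expect_true(all(target > others))
})

test_that("pseudo coupling mirrors real record counts and is seed-stable", {
  lay <- tiny_layout(2, rois = c("L.IFG", "dmPFC"))
  design <- default_design("dx", c("a", "b"), conditions = "FM",
                           duration_s = 60)
  mk <- function(seed, ids) {
    cfg <- nirs_sim_config(duration_s = 60, cardiac_amp = 0, resp_amp = 0,
                           mayer_amp = 0, global_amp = 0, spike_rate = 0,
                           seed = seed)
    pr <- simulate_dyad_nirs(cfg, lay, NULL, ids = ids)
    lapply(pr, function(p) beer_lambert(intensity_to_od(p), lay))
  }
  hemo_by_dyad <- list(d1 = mk(20, c("d1a", "d1b")),
                       d2 = mk(21, c("d2a", "d2b")))
  ps1 <- pseudo_coupling(hemo_by_dyad, lay, design, seed = 5)
  ps2 <- pseudo_coupling(hemo_by_dyad, lay, design, seed = 5)
  expect_identical(ps1, ps2)
  expect_true(all(ps1$group == "pseudo"))
  # per roi_pair x condition, pseudo record count equals real count
  real <- rbind(
    roi_pair_coupling(hemo_by_dyad$d1[[1]], hemo_by_dyad$d1[[2]], lay,
                      design, scope = "between", unit_id = "d1"),
    roi_pair_coupling(hemo_by_dyad$d2[[1]], hemo_by_dyad$d2[[2]], lay,
                      design, scope = "between", unit_id = "d2"))
  expect_equal(table(ps1$roi_pair, ps1$condition),
               table(real$roi_pair, real$condition))
})
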