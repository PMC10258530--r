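test_that("optical density is mean-referenced log attenuation", {
  # constant intensity -> OD identically 0
  arr <- array(5, c(2, 2, 40))
  nirs <- raw_nirs("p", arr, c("c1", "c2"))
  od <- intensity_to_od(nirs)
  expect_true(all(od$od == 0))
  # dip to a tenth of the mean -> OD = 1 at that sample (log10 arithmetic)
  x <- rep(1, 100)
  x[50] <- 0.1
  arr <- array(NA_real_, c(1, 2, 100))
  arr[1, 1, ] <- x; arr[1, 2, ] <- x
  od <- intensity_to_od(raw_nirs("p", arr, "c1"))
  expect_equal(od$od[1, 1, 50], -log10(x[50] / mean(x)), tolerance = 1e-12)
  # gain invariance: scaling intensities leaves OD unchanged
  od2 <- intensity_to_od(raw_nirs("p", arr * 7.3, "c1"))
  expect_equal(od2$od, od$od, tolerance = 1e-12)
})

test_that("Beer-Lambert inverts its forward operator and scales with DPF", {
  lay <- tiny_layout(3)
  set.seed(6)
  hbo <- matrix(rnorm(3 * 200, sd = 0.5), 3, 200)
  hbr <- matrix(rnorm(3 * 200, sd = 0.2), 3, 200)
  hbo <- hbo - rowMeans(hbo); hbr <- hbr - rowMeans(hbr)
  arr <- hypersync:::hemoglobin_to_intensity(hbo, hbr, lay)
  nirs <- raw_nirs("p", arr, lay$channel)
  hemo <- beer_lambert(intensity_to_od(nirs), lay)
  rec_hbo <- hemo$hbo - rowMeans(hemo$hbo)
  rec_hbr <- hemo$hbr - rowMeans(hemo$hbr)
  expect_lt(sqrt(mean((rec_hbo - hbo)^2)) / stats::sd(hbo), 1e-10)
  expect_lt(sqrt(mean((rec_hbr - hbr)^2)) / stats::sd(hbr), 1e-10)
  # OD = 0 -> concentrations identically 0
  z <- beer_lambert(intensity_to_od(raw_nirs("p", array(2, c(3, 2, 30)),
                                             lay$channel)), lay)
  expect_true(all(z$hbo == 0) && all(z$hbr == 0))
  # doubling DPF halves recovered concentrations (linearity)
  hemo2 <- beer_lambert(intensity_to_od(nirs), lay, dpf = c(12, 12))
  expect_equal(hemo2$hbo, hemo$hbo / 2, tolerance = 1e-10)
  # singular extinction matrix rejected
  expect_error(beer_lambert(intensity_to_od(nirs), lay,
                            extinction = matrix(1, 2, 2)), "singular")
})

test_that("wavelet motion correction removes spikes, spares smooth signal", {
  t <- seq(0, 119.9, by = 0.1)
  carrier <- sin(2 * pi * 0.05 * t)
  # artifact-free smooth signal passes through nearly unchanged
  out <- wavelet_motion_correct(carrier)
  expect_lt(max(abs(out - carrier)), 0.01)
  # all-zero series stays zero
  expect_true(all(wavelet_motion_correct(rep(0, 256)) == 0))
  # 10x-amplitude spike: peak suppressed >= 80%, carrier RMS within 5%
  spiked <- carrier; spiked[600] <- carrier[600] + 10
  corr <- wavelet_motion_correct(spiked)
  expect_lt(abs(corr[600] - carrier[600]), 0.2 * 10)
  away <- setdiff(seq_along(t), 580:620)
  rms_ratio <- sqrt(mean((corr[away] - carrier[away])^2)) /
    sqrt(mean(carrier^2))
  expect_lt(rms_ratio, 0.05)
  # idempotence: second pass changes almost nothing
  twice <- wavelet_motion_correct(corr)
  expect_lt(sqrt(mean((twice - corr)^2)) / sqrt(mean(corr^2)), 0.01)
  expect_error(wavelet_motion_correct(rep(0, 8)), "too short")
})

test_that("heartbeat detection finds cardiac peaks and rejects their absence", {
  fs <- 10
  t <- seq(0, 119.9, by = 1 / fs)
  set.seed(9)
  cardiac <- sin(2 * pi * 1.2 * t) + rnorm(length(t), sd = sqrt(1 / 5))
  expect_true(detect_heartbeat(cardiac, fs))
  # pure slow hemodynamics: no in-band peak
  slow <- sin(2 * pi * 0.05 * t)
  expect_false(detect_heartbeat(slow, fs))
  # white noise rarely passes
  fp <- vapply(1:200, function(s) {
    set.seed(s); detect_heartbeat(rnorm(length(t)), fs)
  }, logical(1))
  expect_lt(mean(fp), 0.05)
  expect_error(detect_heartbeat(rnorm(100), fs), "30 s")
})

test_that("channel QC masks channels without identifiable heartbeat", {
  lay <- tiny_layout(4)
  fs <- 10
  t <- seq(0, 119.9, by = 1 / fs)
  set.seed(10)
  hbo <- rbind(sin(2 * pi * 1.2 * t) + 0.3 * rnorm(length(t)),
               sin(2 * pi * 1.0 * t) + 0.3 * rnorm(length(t)),
               sin(2 * pi * 0.05 * t) + 0.05 * rnorm(length(t)),
               sin(2 * pi * 1.4 * t) + 0.3 * rnorm(length(t)))
  hemo <- make_hemo(hbo, fs = fs)
  out <- qc_channels(hemo)
  expect_equal(unname(out$qc), c("ok", "ok", "no_heartbeat", "ok"))
  expect_true(all(is.na(out$hbo[3, ])))      # excluded data carries no values
  expect_true(all(is.finite(out$hbo[c(1, 2, 4), ])))
})

test_that("PCA spatial filter removes global structure, keeps focal patterns", {
  gl <- grid_layout()
  lay <- gl$layout
  nch <- nrow(lay)
  n <- 1200
  set.seed(11)
  global <- hypersync:::band_limited_gp(n, 10, c(0.015, 0.15))
  focal <- hypersync:::band_limited_gp(n, 10, c(0.015, 0.15))
  noise <- matrix(rnorm(nch * n, sd = 0.05), nch, n)
  # spatially uniform global component: correlation drops by >= 50%
  hbo_g <- matrix(rep(global, each = nch), nch, n) + noise
  hg <- pca_spatial_filter(make_hemo(hbo_g, ids = lay$channel), lay,
                           smooth_sigma_cm = 3.5)
  pre <- mean(abs(apply(hbo_g, 1, stats::cor, y = global)))
  post <- mean(abs(apply(hg$hbo, 1, stats::cor, y = global)))
  expect_lt(post, 0.5 * pre)
  # checkerboard (high-spatial-frequency) focal signal: within 10% RMS
  hbo_f <- outer(gl$parity, focal) + noise
  hf <- pca_spatial_filter(make_hemo(hbo_f, ids = lay$channel), lay,
                           smooth_sigma_cm = 3.5)
  rel <- sqrt(mean((hf$hbo - hbo_f)^2)) / sqrt(mean(hbo_f^2))
  expect_lt(rel, 0.10)
  # sigma = 0 is the identity
  h0 <- pca_spatial_filter(make_hemo(hbo_g, ids = lay$channel), lay,
                           smooth_sigma_cm = 0)
  expect_equal(h0$hbo, hbo_g, tolerance = 1e-10)
  # shape preserved, too few channels rejected
  expect_equal(dim(hg$hbo), dim(hbo_g))
  hemo2 <- make_hemo(hbo_g[1:2, , drop = FALSE])
  expect_error(pca_spatial_filter(hemo2, tiny_layout(2), 3.5), ">= 3")
})

test_that("full synthetic round trip recovers noise-free concentrations", {
  lay <- tiny_layout(3)
  cfg <- nirs_sim_config(duration_s = 60, cardiac_amp = 0, resp_amp = 0,
                         mayer_amp = 0, global_amp = 0, spike_rate = 0,
                         seed = 12)
  pair <- simulate_dyad_nirs(cfg, lay, NULL)
  truth <- attr(pair[[1]], "truth")
  hemo <- beer_lambert(intensity_to_od(pair[[1]]), lay)
  rec <- hemo$hbo - rowMeans(hemo$hbo)
  expect_lt(sqrt(mean((rec - truth$hbo)^2)) / stats::sd(truth$hbo), 1e-8)
})
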