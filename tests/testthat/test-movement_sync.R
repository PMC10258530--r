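test_that("velocity is the scaled first difference of positions", {
  pos <- cbind(c(0, 0.02, 0.04), 0, 0)
  tr <- motion_trace("p1", "FM", pos, fs = 50)
  v <- compute_velocity(tr)
  expect_equal(v$v[, 1], c(1, 1))           # units per second
  expect_equal(nrow(v$v), nrow(pos) - 1)
  # constant position -> zero velocity
  vc <- compute_velocity(motion_trace("p1", "FM", matrix(1, 10, 3), fs = 50))
  expect_true(all(vc$v == 0))
  expect_error(compute_velocity(motion_trace("p1", "FM", matrix(0, 1, 3))),
               "at least 2")
})

test_that("gaussian smoothing preserves constants, spreads impulses, reduces variance", {
  # DC preservation (kernel renormalized, including at the edges)
  const <- matrix(2, 60, 3)
  sm <- gaussian_smooth(const, window_ms = 100, fs = 50)
  expect_equal(sm, const, tolerance = 1e-12)
  # unit impulse -> kernel-shaped output with peak < 1
  imp <- matrix(0, 61, 1); imp[31, 1] <- 1
  smi <- gaussian_smooth(imp, window_ms = 100, fs = 50)
  expect_lt(max(smi), 1)
  expect_equal(which.max(smi), 31)
  expect_equal(sum(smi), 1, tolerance = 0.05)  # interior mass conserved
  # variance reduction on white noise
  reduced <- vapply(1:100, function(s) {
    set.seed(s)
    x <- matrix(rnorm(200), ncol = 1)
    stats::var(drop(gaussian_smooth(x, 100, fs = 50))) < stats::var(drop(x))
  }, logical(1))
  expect_true(all(reduced))
  expect_error(gaussian_smooth(const, window_ms = 0, fs = 50), "window_ms")
})

test_that("cvv is symmetric, scale-invariant and bounded", {
  set.seed(4)
  for (i in 1:50) {
    a <- rnorm(3); b <- rnorm(3); k <- runif(1, 0.1, 10)
    expect_equal(cvv(a, b), cvv(b, a), tolerance = 1e-12)
    expect_equal(cvv(k * a, b), cvv(a, b), tolerance = 1e-12)
    expect_equal(cvv(-k * a, b), -cvv(a, b), tolerance = 1e-12)
    expect_lte(abs(cvv(a, b)), 1)
  }
  # stillness convention: no direction carries no alignment evidence
  expect_equal(cvv(c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(cvv(c(1e-12, 0, 0), c(1, 0, 0)), 0)
})

test_that("lagged sync map matches the naive triple-loop reference", {
  cfg <- motion_sim_config(coupling = 0.5, lag_ms = 150, duration_s = 5,
                           seed = 3)
  tr <- simulate_dyad_motion(cfg)
  vi <- gaussian_smooth(compute_velocity(tr[[1]]))
  vj <- gaussian_smooth(compute_velocity(tr[[2]]))
  m <- lagged_sync_map(vi, vj)
  expect_equal(dim(m$C), c(length(m$times_s), 151))
  expect_true(all(m$C >= 0 & m$C <= 1))
  expect_identical(m$sync_mask, m$C > m$threshold)
  expect_equal(m$lags_ms, -rev(m$lags_ms))   # symmetric grid
  Cref <- naive_sync_map(vi, vj)
  expect_lt(max(abs(m$C - Cref)), 1e-10)
})

test_that("an identical partner gives full-map synchrony at lag zero", {
  cfg <- motion_sim_config(coupling = 1, lag_ms = 0, duration_s = 6,
                           move_frac = 1, seed = 8)
  tr <- simulate_dyad_motion(cfg)
  vi <- gaussian_smooth(compute_velocity(tr[[1]]))
  m <- lagged_sync_map(vi, vi)
  lag0 <- which(m$lags_ms == 0)
  expect_true(all(m$C[, lag0] > 1 - 1e-6))
  expect_true(all(m$sync_mask[, lag0]))
})

test_that("traces too short or mismatched are rejected", {
  cfg <- motion_sim_config(duration_s = 3, seed = 1)
  tr <- simulate_dyad_motion(cfg)
  vi <- compute_velocity(tr[[1]]); vj <- compute_velocity(tr[[2]])
  expect_error(lagged_sync_map(vi, vj), "too short")
  vj2 <- vj; vj2$fs <- 25
  expect_error(lagged_sync_map(vi, vj2), "mismatched")
})

test_that("total sync combines the lag regimes with a per-time OR", {
  mk_map <- function(mask) {
    lags <- seq(-750, 750, 10)
    C <- matrix(0, nrow(mask), length(lags))
    C[mask] <- 0.9
    structure(list(dyad_id = "d", condition = "IS", lags_ms = lags,
                   times_s = seq_len(nrow(mask)), C = C,
                   sync_mask = C > 0.35, threshold = 0.35,
                   window_s = 2, fs = 50),
              class = "sync_map")
  }
  lags <- seq(-750, 750, 10)
  # all true -> 1
  m <- mk_map(matrix(TRUE, 10, length(lags)))
  expect_equal(total_sync(m)$total_sync, 1)
  # true only at +20 ms: neither lag 0 nor |lag| > 30 -> 0
  mask <- matrix(FALSE, 10, length(lags))
  mask[, which(lags == 20)] <- TRUE
  expect_equal(total_sync(mk_map(mask))$total_sync, 0)
  # lag-0 column true at half the time points -> 0.5
  mask <- matrix(FALSE, 10, length(lags))
  mask[1:5, which(lags == 0)] <- TRUE
  s <- total_sync(mk_map(mask))
  expect_equal(s$total_sync, 0.5)
  expect_equal(s$lag0_sync, 0.5)
  expect_equal(s$lagged_sync, 0)
})

test_that("fisher z is arctanh with clipping and monotonicity", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_true(is.finite(fisher_z(1)))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(r)) > 0))
})

test_that("outlier exclusion is single-pass around the full-set mean", {
  # all equal: SD = 0, nothing removed
  res <- exclude_outliers(rep(3, 10))
  expect_length(res$removed_idx, 0)
  expect_equal(res$removed_fraction, 0)
  # one extreme value among 100
  set.seed(5)
  x <- c(rnorm(99), 50)
  res <- exclude_outliers(x)
  expect_equal(res$removed_idx, 100L)
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
})

test_that("pseudo pairings never reuse a real dyad and are seed-stable", {
  ids <- sprintf("d%d", 1:6)
  p1 <- pseudo_pairings(ids, seed = 42)
  p2 <- pseudo_pairings(ids, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1$dyad_a != p1$dyad_b))
  expect_equal(nrow(p1), length(ids))
  expect_setequal(p1$dyad_b, ids)            # a permutation
  expect_error(pseudo_pairings("d1"), ">= 2")
})

test_that("pseudo dyads are condition-matched and break real coupling", {
  mk_dyad <- function(id, seed) {
    cfg <- motion_sim_config(coupling = 1, duration_s = 6, seed = seed)
    trs <- list()
    for (cond in c("BB", "FM")) {
      pr <- simulate_dyad_motion(
        motion_sim_config(coupling = 1, duration_s = 6, seed = seed + nchar(cond)),
        condition = cond, ids = paste0(id, c("_a", "_b")))
      trs <- c(trs, pr)
    }
    list(dyad_id = id, group = "real", traces = trs)
  }
  dyads <- list(mk_dyad("dA", 1), mk_dyad("dB", 100))
  pseudo <- make_pseudo_dyads(dyads, seed = 7)
  expect_length(pseudo, 2)
  for (pd in pseudo) {
    pids <- unique(vapply(pd$traces, function(tr) tr$participant_id,
                          character(1)))
    expect_length(pids, 2)
    # members come from different real dyads
    expect_false(substr(pids[1], 1, 2) == substr(pids[2], 1, 2))
    conds <- table(vapply(pd$traces, function(tr) tr$condition, character(1)))
    expect_true(all(conds == 2))             # both members in each condition
    expect_equal(pd$group, "pseudo")
  }
})
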