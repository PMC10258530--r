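# Synthetic dyadic 3D movement with known ground-truth coupling.

#' Configuration for simulated dyadic motion
#'
#' Movement is modeled as a 3D Ornstein-Uhlenbeck (OU) process in velocity
#' space, integrated to positions: smooth, non-repetitive and unpredictable,
#' like free hand movement. Participant B's velocity mixes a delayed copy of
#' A's velocity (weight `coupling`) with an independent OU process.
#'
#' @param fs Sampling rate, Hz (default 50, the motion-capture rate).
#' @param duration_s Block duration, seconds (default 120, one task block).
#' @param coupling Coupling strength kappa in \[0, 1\]: 0 = independent
#'   movement, 1 = perfect (possibly delayed) copy.
#' @param lag_ms Delay of B behind A, milliseconds (|lag| <= 750).
#' @param tau_s OU velocity time constant, seconds. Default 0.4 s: hand
#'   velocity decorrelates over a fraction of a second.
#' @param speed_scale Stationary standard deviation of each velocity
#'   component, device units per second.
#' @param move_frac Fraction of time each participant is moving (default
#'   0.55). Hand movement in this task is intermittent - strokes separated
#'   by holds - and the pauses are what keep chance-level synchrony low
#'   (still samples contribute CVV = 0). `move_frac = 1` gives continuous
#'   movement (pure OU velocities).
#' @param envelope_tau_s Time constant of the slow process gating movement
#'   on and off, seconds (default 3: movement bouts of a few seconds).
#' @param seed Integer seed; all randomness is derived from it.
#' @return A `motion_sim_config` list.
#' @export
motion_sim_config <- function(fs = 50, duration_s = 120, coupling = 0,
                              lag_ms = 0, tau_s = 0.4, speed_scale = 1,
                              move_frac = 0.55, envelope_tau_s = 3,
                              seed = 1) {
  stopifnot(fs > 0, duration_s > 0, tau_s > 0, speed_scale > 0,
            envelope_tau_s > 0)
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  if (abs(lag_ms) > 750) stop("|lag_ms| must be <= 750")
  if (move_frac <= 0 || move_frac > 1) stop("move_frac must be in (0, 1]")
  structure(list(fs = fs, duration_s = duration_s, coupling = coupling,
                 lag_ms = lag_ms, tau_s = tau_s, speed_scale = speed_scale,
                 move_frac = move_frac, envelope_tau_s = envelope_tau_s,
                 seed = as.integer(seed)),
            class = "motion_sim_config")
}

# Movement on/off envelope in [0, 1]: a slow OU process clamped through a
# linear ramp, exactly zero during holds (the hand is at rest, so the
# velocity - and hence CVV, by the stillness convention - is zero there),
# ramping smoothly into movement bouts. Calibrated so the expected moving
# fraction is move_frac. Returns all-ones when move_frac = 1.
movement_envelope <- function(n, dt, tau_env, move_frac) {
  if (move_frac >= 1) return(rep(1, n))
  s <- ou_velocity(n, dt, tau_env, 1)[, 1]
  thr <- stats::qnorm(1 - move_frac)
  pmin(1, pmax(0, (s - thr) / 0.2))
}

# Exact-discretization OU sample path, n x 3, stationary sd `sigma`.
ou_velocity <- function(n, dt, tau, sigma) {
  a <- exp(-dt / tau)
  innov_sd <- sigma * sqrt(1 - a^2)
  v <- matrix(0, n, 3)
  v[1, ] <- stats::rnorm(3, 0, sigma)
  eps <- matrix(stats::rnorm((n - 1) * 3, 0, innov_sd), n - 1, 3)
  for (k in 2:n) v[k, ] <- a * v[k - 1, ] + eps[k - 1, ]
  v
}

#' Simulate one dyad's coupled 3D movement
#'
#' Participant A's velocity is a 3D OU process gated by a smooth
#' intermittency envelope (movement bouts separated by holds); participant
#' B's velocity is `coupling * A(t - lag) + (1 - coupling) * U(t)` with U an
#' independent envelope-gated OU process. Velocities are integrated to
#' positions. Deterministic given the config seed.
#'
#' @param cfg A [motion_sim_config()].
#' @param condition Condition label attached to the traces.
#' @param ids Participant ids (length 2).
#' @return List of two [motion_trace()] objects (A, B).
#' @export
simulate_dyad_motion <- function(cfg, condition = "FM",
                                 ids = c("P1", "P2")) {
  stopifnot(inherits(cfg, "motion_sim_config"))
  withr::with_seed(cfg$seed, {
    dt <- 1 / cfg$fs
    n <- round(cfg$duration_s * cfg$fs)
    lag_n <- round(cfg$lag_ms / 1000 * cfg$fs)
    burn <- abs(lag_n)
    # simulate A with enough pre-samples that the delayed copy is defined
    vA_full <- ou_velocity(n + burn, dt, cfg$tau_s, cfg$speed_scale) *
      movement_envelope(n + burn, dt, cfg$envelope_tau_s, cfg$move_frac)
    vU <- ou_velocity(n + burn, dt, cfg$tau_s, cfg$speed_scale) *
      movement_envelope(n + burn, dt, cfg$envelope_tau_s, cfg$move_frac)
    iA <- seq_len(n) + burn                 # A's analyzed samples
    iDel <- iA - lag_n                      # A delayed by lag (B trails A)
    iDel <- pmin(pmax(iDel, 1L), n + burn)
    vA <- vA_full[iA, , drop = FALSE]
    vB <- cfg$coupling * vA_full[iDel, , drop = FALSE] +
      (1 - cfg$coupling) * vU[iA, , drop = FALSE]
    posA <- apply(vA * dt, 2, cumsum)
    posB <- apply(vB * dt, 2, cumsum)
    list(motion_trace(ids[1], condition, posA, fs = cfg$fs),
         motion_trace(ids[2], condition, posB, fs = cfg$fs))
  })
}
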