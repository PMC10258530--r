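# Synthetic dual-brain fNIRS with controllable shared-signal structure.

#' Configuration for simulated fNIRS recordings
#'
#' Each channel's oxyhemoglobin series is a sum of (i) a band-limited
#' (0.015-0.15 Hz) hemodynamic Gaussian process, split between a component
#' shared with the paired channel (weight `sqrt(rho)`) and an independent
#' component (`sqrt(1-rho)`); (ii) physiological sinusoids (cardiac,
#' respiration, Mayer waves) with random phases; (iii) a global scalp
#' process common to all channels of a participant; and (iv) transient spike
#' artifacts. Concentrations are converted to two-wavelength intensities by
#' inverting the same modified Beer-Lambert operator the preprocessing stage
#' applies, so recovery is exact in the noise-free configuration.
#'
#' @param fs Sampling rate, Hz (default 10).
#' @param duration_s Duration, seconds (default 120).
#' @param hemo_sd SD of the band-limited hemodynamic component, micromolar.
#' @param cardiac_hz,cardiac_amp Cardiac oscillation frequency (Hz) and
#'   amplitude (micromolar). Default 1.2 Hz, resolvable below the 5 Hz
#'   Nyquist frequency.
#' @param resp_hz,resp_amp Respiration (default 0.25 Hz).
#' @param mayer_hz,mayer_amp Mayer waves (default 0.1 Hz).
#' @param global_amp Amplitude of the spatially uniform scalp component,
#'   micromolar.
#' @param spike_rate Motion-artifact spikes per minute.
#' @param spike_amp Spike amplitude, micromolar.
#' @param hbr_ratio HbR is `-hbr_ratio` times the hemodynamic HbO component
#'   (typical task anti-correlation) plus a small independent term.
#' @param band_hz Hemodynamic band, Hz.
#' @param dpf Differential path-length factor per wavelength.
#' @param seed Integer seed.
#' @return An `nirs_sim_config` list.
#' @export
nirs_sim_config <- function(fs = 10, duration_s = 120, hemo_sd = 0.5,
                            cardiac_hz = 1.2, cardiac_amp = 0.2,
                            resp_hz = 0.25, resp_amp = 0.3,
                            mayer_hz = 0.1, mayer_amp = 0.3,
                            global_amp = 0.5, spike_rate = 2,
                            spike_amp = 5, hbr_ratio = 0.33,
                            band_hz = hypersync_constants$band_hz,
                            dpf = hypersync_constants$dpf_default,
                            seed = 1) {
  stopifnot(fs > 0, duration_s > 0, hemo_sd >= 0)
  amps <- c(cardiac_amp, resp_amp, mayer_amp, global_amp, spike_amp)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  structure(list(fs = fs, duration_s = duration_s, hemo_sd = hemo_sd,
                 cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
                 resp_hz = resp_hz, resp_amp = resp_amp,
                 mayer_hz = mayer_hz, mayer_amp = mayer_amp,
                 global_amp = global_amp, spike_rate = spike_rate,
                 spike_amp = spike_amp, hbr_ratio = hbr_ratio,
                 band_hz = band_hz, dpf = dpf, seed = as.integer(seed)),
            class = "nirs_sim_config")
}

# Unit-variance Gaussian process band-limited to [band[1], band[2]] Hz,
# synthesized by brick-wall filtering white noise in the frequency domain.
band_limited_gp <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                    # two-sided frequency magnitude
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# Random-phase sinusoid of amplitude a at frequency f0.
phase_sin <- function(n, fs, f0, a) {
  a * sin(2 * pi * f0 * (seq_len(n) - 1) / fs + stats::runif(1, 0, 2 * pi))
}

# Spike train: Poisson-count transients with exponential decay (~0.3 s).
spike_train <- function(n, fs, rate_per_min, amp) {
  out <- numeric(n)
  k <- stats::rpois(1, rate_per_min * n / fs / 60)
  if (k == 0) return(out)
  at <- sample.int(n, k, replace = TRUE)
  sgn <- sample(c(-1, 1), k, replace = TRUE)
  kern_n <- max(2L, round(0.3 * fs))
  kern <- exp(-(0:(kern_n - 1)) / (0.1 * fs))
  for (i in seq_len(k)) {
    j <- at[i]:min(n, at[i] + kern_n - 1L)
    out[j] <- out[j] + sgn[i] * amp * kern[seq_along(j)]
  }
  out
}

#' Simulate a dyad's paired fNIRS recordings
#'
#' @param cfg An [nirs_sim_config()].
#' @param layout A [channel_layout()] shared by both participants.
#' @param pair_plan Data frame with columns `channel_a`, `channel_b`, `rho`:
#'   the shared-signal weight between participant A's `channel_a` and
#'   participant B's `channel_b`. Channels not listed get rho = 0.
#' @param ids Participant ids (length 2).
#' @return List of two [raw_nirs()] objects. Each carries an attribute
#'   `truth`: the noise-and-artifact-decomposed ground-truth concentration
#'   series (`hbo`, `hbr` in micromolar, mean-centered; `scalp`; `shared`).
#' @export
simulate_dyad_nirs <- function(cfg, layout, pair_plan = NULL,
                               ids = c("P1", "P2")) {
  stopifnot(inherits(cfg, "nirs_sim_config"), inherits(layout, "channel_layout"))
  if (!is.null(pair_plan)) {
    if (any(pair_plan$rho < 0 | pair_plan$rho > 1))
      stop("rho must be in [0, 1]")
    bad <- setdiff(c(pair_plan$channel_a, pair_plan$channel_b), layout$channel)
    if (length(bad))
      stop("pair_plan references unknown channels: ", paste(bad, collapse = ", "))
  }
  withr::with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$fs)
    chans <- layout$channel
    nch <- length(chans)
    rhoA <- rhoB <- stats::setNames(numeric(nch), chans)
    pair_of <- stats::setNames(rep(NA_character_, nch), chans)
    shared <- list()
    if (!is.null(pair_plan) && nrow(pair_plan)) {
      for (i in seq_len(nrow(pair_plan))) {
        ca <- as.character(pair_plan$channel_a[i])
        cb <- as.character(pair_plan$channel_b[i])
        key <- paste(ca, cb, sep = "|")
        shared[[key]] <- band_limited_gp(n, cfg$fs, cfg$band_hz)
        rhoA[ca] <- pair_plan$rho[i]
        rhoB[cb] <- pair_plan$rho[i]
        pair_of[ca] <- key
        pair_of[cb] <- key
      }
    }
    build_participant <- function(pid, rho) {
      scalp <- band_limited_gp(n, cfg$fs, cfg$band_hz)
      hbo <- matrix(0, nch, n)
      hemo_part <- matrix(0, nch, n)
      for (ci in seq_len(nch)) {
        ch <- chans[ci]
        own <- band_limited_gp(n, cfg$fs, cfg$band_hz)
        base <- if (!is.na(pair_of[ch]) && rho[ch] > 0) {
          sqrt(rho[ch]) * shared[[pair_of[ch]]] + sqrt(1 - rho[ch]) * own
        } else own
        hemo <- cfg$hemo_sd * base
        hemo_part[ci, ] <- hemo
        physio <- phase_sin(n, cfg$fs, cfg$cardiac_hz, cfg$cardiac_amp) +
          phase_sin(n, cfg$fs, cfg$resp_hz, cfg$resp_amp) +
          phase_sin(n, cfg$fs, cfg$mayer_hz, cfg$mayer_amp)
        spikes <- if (cfg$spike_rate > 0 && cfg$spike_amp > 0)
          spike_train(n, cfg$fs, cfg$spike_rate, cfg$spike_amp) else numeric(n)
        hbo[ci, ] <- hemo + physio + cfg$global_amp * scalp + spikes
      }
      hbr <- -cfg$hbr_ratio * hemo_part +
        0.1 * cfg$hemo_sd * t(replicate(nch, band_limited_gp(n, cfg$fs, cfg$band_hz)))
      # center so the intensity baseline is the temporal mean
      hbo <- hbo - rowMeans(hbo)
      hbr <- hbr - rowMeans(hbr)
      intensity <- hemoglobin_to_intensity(hbo, hbr, layout, dpf = cfg$dpf)
      out <- raw_nirs(pid, intensity, chans, fs = cfg$fs)
      attr(out, "truth") <- list(hbo = hbo, hbr = hbr, scalp = scalp,
                                 shared = shared)
      out
    }
    list(build_participant(ids[1], rhoA), build_participant(ids[2], rhoB))
  })
}
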