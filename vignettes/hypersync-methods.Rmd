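---
title: "Methods: dual-brain fNIRS coupling and dyadic movement synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-brain fNIRS coupling and dyadic movement synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and numerical choices behind
`hypersync`. The package analyzes dyadic experiments in which two
participants move freely in 3D under three conditions — back-to-back rest
(BB), free movement (FM) and intentional synchrony (IS), each a 120 s
block — while hand position is tracked at 50 Hz and prefrontal cortical
hemodynamics are recorded with continuous-wave fNIRS at 10 Hz
(wavelengths 760/850 nm, 23 channels per participant, 3.5 cm optode
separation).

## Behavioral synchrony

### The CVV statistic

Instantaneous velocities are first differences of consecutive positions
scaled by the sampling rate. To suppress tracker jitter, each velocity
axis is convolved with a Gaussian kernel of 100 ms full width
(`sigma` = 25 ms, truncated at two sigma, renormalized at edges so
constants pass through).

Synchrony at a time point is the cosine of the angle between the two
participants' 3D velocity vectors,

$$C_{i,j}(t) = \frac{\langle v_i(t), v_j(t)\rangle}{\lVert v_i(t)\rVert\,\lVert v_j(t)\rVert},$$

which is 1 for identical movement direction, −1 for mirror-like movement
and 0 for orthogonal movement. Both same-direction and mirror movement
count as synchrony, so the analysis uses $|C_{i,j}|$.

**Stillness convention.** When either speed is below $10^{-9}$ units/s
the statistic is defined as 0: a vector with no direction carries no
alignment evidence, and this choice is conservative against inflating
synchrony while both hands rest. This matters: CVV is scale-invariant,
so any other convention would let measurement noise during rest
masquerade as chance-level alignment.

### Lagged windowed detection

The windowed, lag-resolved map is computed as per-lag instantaneous
$|C_{i,j}|$ followed by a centered 2 s (100-sample) moving average,
evaluated on a symmetric lag grid of ±750 ms in 10 ms steps. This
operationalization was chosen as the only reading consistent with a
100-sample smoothing window, a 10 ms lag step and a time × lag synchrony
surface; it is an interpretation, documented here rather than asserted
as the original implementation. Two numerical details:

* At 50 Hz a 10 ms lag is half a sample; fractional shifts use linear
  interpolation of the lagged participant's velocity.
* The absolute value is taken *before* windowing. Windowing signed CVV
  first would let mirror-movement episodes cancel against aligned ones.
* Only fully overlapping, fully windowed time points enter the map
  (valid-mode edges), so no cell is a partial estimate.
* Positive lag means the second participant trails the first; the
  convention is recorded in output headers.

Sync moments are cells with windowed $|C_{i,j}| > 0.35$ (the threshold
reported for this paradigm). `total_sync` is the proportion of time
points synchronized at lag 0 *or* at any lag beyond ±30 ms (per-time
OR); the two regimes are also reported separately, and
`fisher_z_mean_cvv` (arctanh of the map mean, clipped below 1 by
$10^{-12}$) is emitted alongside since "proportion of time above
threshold" and "mean synchrony level" are both defensible summaries.

### Pseudo-dyad null and outlier policy

Chance-level synchrony is estimated from pseudo dyads: a seeded
derangement pairs participant 1 of each dyad with participant 2 of a
*different* dyad, condition-matched, one pseudo dyad per real dyad.
Summary values feeding the statistical stage pass a single-pass
±2.5 SD exclusion computed once on the full set (expected removal
1.24% under normality; the removed fraction is reported).

## Synthetic movement

Participant A's velocity is a 3D Ornstein–Uhlenbeck process (time
constant 0.4 s — hand velocity decorrelates within a fraction of a
second; stationary SD 1 unit/s), multiplied by a smooth intermittency
envelope, and integrated to positions. Participant B's velocity is
$\kappa \cdot v_A(t - \text{lag}) + (1-\kappa) \cdot u(t)$ with $u$ an
independent envelope-gated OU process, so $\kappa = 1$ is a perfect
(possibly delayed) copy and coupling lives in velocity space, where the
statistic operates.

The envelope (a slow OU process, time constant 3 s, clamped through a
linear ramp; exactly zero during holds) models the stroke-and-hold
intermittency of natural hand movement, with a default moving fraction
of 0.55. It exists because chance-level synchrony is governed by it:
$E|\cos\theta| = 1/2$ for independent random 3D directions, so two
*continuously* moving independent participants produce windowed
$|CVV|$ concentrated near 0.5 — above the 0.35 threshold — and
chance-level total sync saturates near 1. With realistic pauses and the
stillness convention, chance total sync falls to a low baseline while
coupled dyads remain high, reproducing the qualitative real-versus-
pseudo structure of the paradigm. `move_frac = 1` recovers the pure OU
limit, which is the right regime for perfect-copy identities (there,
total sync reaches 1 by construction).

What the generator does *not* model: biomechanics, arm kinematic
constraints, leader–follower alternation, or deliberate mirroring.
Passing recovery tests on this generator shows the estimator chain is
correct, not that real dyads behave like OU processes.

## Synthetic fNIRS

Each channel's oxyhemoglobin series sums:

* a band-limited (0.015–0.15 Hz) Gaussian process, synthesized by
  brick-wall filtering white noise in the frequency domain, split
  $\sqrt{\rho}\,z_{\text{shared}} + \sqrt{1-\rho}\,z_{\text{own}}$
  against the paired channel (SD 0.5 µM);
* physiological sinusoids with seeded random phases: cardiac 1.2 Hz
  (0.2 µM), respiration 0.25 Hz (0.3 µM), Mayer waves 0.1 Hz (0.3 µM) —
  at 10 Hz sampling the cardiac band sits below the 5 Hz Nyquist, so
  heartbeat QC is meaningful;
* a spatially uniform scalp process per participant (0.5 µM), the
  target of the spatial filter;
* exponential-decay spike artifacts (2/min, 5 µM).

Deoxyhemoglobin is an anti-correlated copy (ratio 0.33) plus a small
independent term — enough to exercise the two-chromophore algebra, with
no claim of neurovascular realism. Concentrations are converted to
two-wavelength intensities by *inverting the same modified Beer–Lambert
operator the preprocessing applies*, which guarantees the round trip is
exact linear algebra in the noise-free configuration. Per-condition
shared-signal weights default to 0.05 (BB), 0.3 (FM), 0.5 (IS): a
small nonzero baseline under BB reflects shared environment, and the
ordering tracks the interaction demands of the conditions; no published
values exist to pin these, so they are generator conventions, stated
once here.

## fNIRS preprocessing

**Optical density.** $OD(t) = -\log_{10}(I(t)/\bar I)$ per channel and
wavelength; referencing to the mean intensity makes OD invariant to
detector gain, and concentrations are consequently deviations from the
block mean.

**Wavelet motion correction.** Per series, a 4-level periodized
Daubechies-5 discrete wavelet transform; at each detail level,
coefficients with magnitude above 1.5 × that level's interquartile
range are zeroed; the signal is reconstructed (reflective padding keeps
length). Spikes and baseline shifts concentrate into few large
coefficients, while sinusoidal physiology stays below the robust
threshold (an arcsine-distributed level has IQR ≈ 1.41 amplitude, so
1.5 × IQR clears its own peak). The transform is implemented in-package
with pinned filter coefficients because coefficient-level thresholding
with exact reconstruction is the core of the method. The cited method's
parameters are not published with the paradigm; db5 / 4 levels /
α = 1.5 are this package's pinned defaults.

**Modified Beer–Lambert law.** Per channel, the 2×2 system
$\Delta OD(\lambda) = [\varepsilon_{HbO}(\lambda)\Delta HbO +
\varepsilon_{HbR}(\lambda)\Delta HbR]\, d\, DPF(\lambda)$ is solved for
the chromophores, with $d$ the source–detector separation (cm),
extinction coefficients from a standard tabulation pinned in
`hypersync_constants` (1/(mM·cm)) and DPF defaulting to 6.0 at both
wavelengths (a conventional adult-forehead value; no study-specific
value exists to pin). Output is µM.

**Channel QC.** A channel passes if its Welch power spectrum (Hann
segments, 50% overlap) has a local peak in 0.8–2.0 Hz exceeding 3× the
median in-band power — an automated, reproducible stand-in for visual
heartbeat inspection. Failing channels are masked to `NA` and excluded
from every downstream coupling computation; they are never
interpolated. An optional variance-based noisy-channel rule is exposed
but off by default, since no published criterion exists to pin it.

**PCA spatial filtering.** On the channel-mean-removed time × channel
HbO matrix: SVD; each component's channel-loading vector is smoothed
with a row-normalized Gaussian kernel over channel-midpoint distances
(σ = 3.5 cm, one optode spacing); smoothed loadings are subtracted from
the originals; the signal is rebuilt from difference loadings with
unchanged temporal scores. Spatially uniform (scalp/systemic)
components cancel almost exactly; checkerboard-like focal patterns
survive (residual under 5% on a 4×3 grid patch). σ = 0 is defined as
the identity. Only HbO is filtered and only HbO proceeds to coherence
(its direction tracks regional blood flow more reliably); HbR is
retained for QC.

## Wavelet transform coherence

The CWT uses the analytic Morlet wavelet with $\omega_0 = 6$, the
standard compromise between time and frequency localization, on a scale
grid of 12 voices per octave spanning 0.01–0.5 Hz so the analysis band
is interior. The frequency–scale map is $f = \omega_0/(2\pi s)$.
Coherence follows the cited toolbox definition:

$$R^2(t,s) = \frac{|S(W_{xy}/s)|^2}{S(|W_x|^2/s)\, S(|W_y|^2/s)},$$

with smoothing $S$ = Gaussian in time (σ = s) then boxcar across scales
(0.6 octaves), both implemented spectrally. Without smoothing the ratio
is identically 1 for *any* pair — a regression test asserts this
degeneracy to prove the smoothing operator is active.

**Cone of influence.** Cells within the e-folding distance
$\sqrt{2}\,s$ of either edge are excluded from band averages. For a
120 s block the 0.015 Hz band edge (67 s period) can never clear the
boundary, so the effective band floor (reported per record, ≈ 0.023 Hz
at 120 s) sits above the nominal edge; including edge cells instead
would bias every block-level average.

**Band averaging and aggregation.** The coupling value is the
unweighted mean of $R^2$ over COI-valid cells with
$f \in [0.015, 0.15]$ Hz — below cardiac and respiratory noise — and is
reported with its Fisher z form $\mathrm{arctanh}(\sqrt{\bar R^2})$,
the variance-stabilized scale on which channel pairs are averaged to
ROI pairs and models operate. WTC is computed once on the full
recording and cells are assigned to condition blocks by time, avoiding
per-block COI loss; between-brain records use all channel pairs
spanning the ROI pair (homologous-only is a config choice), within-
brain records pair distinct ROIs of one participant and never pair a
channel with itself.

## Statistical stage

Models are linear mixed effects fits (REML) with a random intercept per
dyad (pseudo dyads enter as their own units). The model ladder — main
effects, + two-way, + three-way interactions — is compared by
likelihood-ratio χ² on ML refits with df equal to the parameter-count
difference, an asymptotically equivalent operationalization of Wald
model comparison; the choice is pinned in the report metadata. The
deepest significantly better model is selected. For the selected model
the package reports a Type II Wald χ² table, Satterthwaite-df F tests
with partial η², per-cell simple slopes of synchrony on coupling
(`emmeans::emtrends`), and real-versus-pseudo contrasts with Bonferroni
adjustment across cells. Singular fits are flagged, never silently
dropped; duplicated rows trigger a data-integrity warning.

Record granularity is ROI-averaged by default (one row per dyad ×
ROI pair × condition). Channel-level rows would multiply the df as in
some published analyses of this design; that switch is available but
not the default, and no claim is made of matching any particular
study's row granularity.

## Problem sizes and determinism

Every stochastic component takes one integer seed, and simulation
outputs are byte-identical across runs given the seed. The validation
suite runs at deliberately modest problem sizes chosen to exercise the
estimators, not to emulate a full study: 5 s fixtures for
oracle-equivalence checks against a naive triple-loop reference
(agreement to 1e−10), 15 s blocks × 200 simulations for null
calibration, 120 s single-channel recordings × 8 seeds per ρ for
coherence recovery, and 30 simulated dyads for slope recovery (±0.05
around an injected +0.2) and type-I calibration.

## Known limitations

* The channel→ROI map is configuration; the bundled 23-channel layout
  is schematic, not a reconstruction of any cap.
* No short-separation channels are modeled (the paradigm's hardware had
  none), so scalp correction rests entirely on the PCA filter.
* The heartbeat criterion replaces manual inspection; its default
  prominence (3×) was fixed from synthetic SNR considerations, not
  tuned to any dataset.
* `arctanh` of near-unit coherence is unbounded; perfect synthetic
  copies are meaningful only through the clipped z value.
* Epoch-level (as opposed to channel-level) noise exclusion is exposed
  as configuration but off by default, since no reproducible criterion
  is published for it.
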