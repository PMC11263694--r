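---
title: "Behavioral-state segmentation and state-conditioned LFP analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral-state segmentation and state-conditioned LFP analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, the tunable parameters, the synthetic
world the tests run in, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite and the
acceptance script do not themselves compute.

## 1. The segmentation model

Two movement signals are observed: the Euclidean norm of the high-passed
3-axis accelerometer (ACL, arbitrary units, native rate 400 Hz) and the
frame-to-frame nose speed from pose tracking (DLC, px/s, native rate
2 frames/s). Both are reduced to a common step (default 0.5 s; ACL by RMS,
because vibration energy rather than sign carries the behavioral
information) and binarized at the *session median* of each signal. A value
strictly above the median is `Hi`; ties map to `Lo`, so a flat, inactive
signal reads `Lo` throughout. The per-step pair of binary values forms one
of four symbols, written with the ACL letter first (`Lo/Hi` = low ACL, high
DLC).

The symbol stream drives a 3-state discrete-emission hidden Markov model.
Three states is a modeling commitment, not an inference: the three regimes
of interest are the sleep posture, quiet DMN-associated behaviors, and
locomotion/exploration. Estimation is scaled forward–backward EM
(Baum–Welch); decoding is log-space Viterbi with deterministic tie-breaks
toward the lower state index.

Parameters that matter:

* `step_duration` (default 0.5 s). One DLC frame at 2 fps and exactly one
  LFP epoch. The source recordings are ambiguous about the HMM timebase:
  a printed self-transition of 0.98 and a printed mean sleep dwell time of
  ~400 s are mutually consistent only for a step near 8 s, while the pose
  stream runs at 2 fps. We expose the step as configuration and default to
  0.5 s; dwell times in seconds therefore scale with this choice (geometric
  dwell = step/(1 − self-transition)).
* `n_restarts` (default 10), `tol` (1e-6), `max_iter` (500). EM is started
  from flat-Dirichlet random rows; restarts protect against local optima.
  At short session lengths (minutes) three restarts can all land in one
  basin — the tests use five or more.
* Emission floors: zeros are floored at 1e-12 during EM to keep the
  log-domain recursions finite; final matrices are renormalized.

Label switching is resolved by emission signatures (`canonicalize_states`):
sleep = largest `B[·, LoLo]`, then dmn = largest remaining `B[·, HiLo]`,
the rest is active. This mirrors the characteristic sensor signatures of
the three regimes: immobile sleep (both low), head movement without
locomotion (DMN), and locomotion (DLC high).

## 2. What the synthetic generator emulates — and what it cannot

`simulate_state_sequence` draws the latent chain; its default parameters
(`default_hmm_params`) are the printed example-session transition and
emission matrices of the study this package operationalizes: a very sticky
sleep state emitting `Lo/Lo` (0.98), a DMN state emitting `Hi/Lo` (0.78),
an active state mixing `Hi/Hi` (0.59) and `Lo/Hi` (0.29). The initial
distribution (0.60, 0.15, 0.25) is our choice — no initial distribution is
printed — and sits near both the chain's stationary distribution and the
reported time budget (54/15/30%).

`simulate_sensors` draws per-state log-normal ACL/DLC values (positive,
right-skewed, heavy tails like real locomotion bursts). One structural
limitation is worth stating precisely: a median split of any *continuous*
signal forces each sensor's marginal `Hi` rate to exactly 0.5, whereas the
printed emissions together with the time budget imply marginal `Hi` rates
near 0.33 (ACL) and 0.27 (DLC). Real data can do this because quantized
pose speeds have a point mass at the floor (the median lands on a tie and
ties read `Lo`). With continuous sensors the exact printed emission matrix
is therefore *not reachable* through the sensor route; the default profile
reproduces the qualitative signatures (sleep → `Lo/Lo`-dominant, DMN →
`Hi/Lo`-dominant, active → `Hi/Hi`-dominant), and exact-matrix tests drive
the symbol generator directly. A green sensor-route test establishes the
median/symbolization machinery, not the printed probabilities.

`simulate_lfp` builds each channel as a sum of:

1. a delta sinusoid (default 2 Hz) with per-state amplitude (default
   2.0/0.5/0.3 mV — slow waves near 2 mV during sleep) and phase continuous
   across state boundaries;
2. a band-limited Gaussian gamma carrier (40–60 Hz) whose envelope is
   `(1 + s·cos(φ_delta − θ_ch))/(1 + s)`, scaled by per-state gamma
   amplitude (0.05/0.30/0.15 mV) — coupling strength `s` defaults to
   0.1/0.8/0.4 (strongest in the DMN state) and the preferred angle
   `θ` advances across channels (VP −3π/4, MD −π/4, AC +π/4);
3. band-limited high-gamma noise (60–150 Hz, 0.03/0.15/0.08 mV);
4. a gamma-resonant VAR component: every channel has AR(2) poles at 50 Hz
   (radius 0.8 at 400 Hz sampling) and the directed structure MD→AC,
   MD→VP, VP→AC enters as lag-1 cross-coefficients (0.35/0.30/0.25,
   innovation SD 0.1 mV). Planting the interactions in a resonant system
   makes them gamma-band-specific, as in the recordings being emulated; a
   broadband lag-1 VAR does not produce band-specific Granger structure.
5. 1/f background noise (0.05 mV RMS).

The envelope normalization `(1+s)` is peak-normalizing, not
power-normalizing, so mean gamma power falls as `s` rises
(`E[env²] = (1+s²/2)/(1+s)²`); with the default per-state amplitudes the
intended power ordering (DMN > active > sleep) still holds on every
channel. Features of real LFPs the generator does not attempt: 1/f-embedded
oscillatory bursts (gamma here is stationary within state), line noise,
movement artifacts, volume-conduction mixing, non-sinusoidal delta.

Seeding: one global seed expands into named child seeds
(`child_seed(seed, stream)`, a documented hash), so the latent chain is
unchanged when, say, only the gamma carrier stream is re-drawn. All
generators are bit-reproducible given the seed.

## 3. Spectral analysis

Epochs are 0.5 s, non-overlapping, per-epoch demeaned; a trailing partial
epoch is dropped. Band power uses a Hann taper (the source text says only
"FFT"; an untapered periodogram leaks delta power into the gamma bands at
these epoch lengths) and one-sided density normalization (density vs total
power is unstated in the source; density is the convention here, units
mV²/Hz). Band edges are half-open `[f_lo, f_hi)` so that 60 Hz belongs to
high-gamma only. A 50 Hz notch is *not* applied by default (none is
described); note the gamma band spans 50 Hz, so recordings from 50 Hz-mains
environments should be notched upstream.

Delta amplitude is the mean Hilbert envelope of the 0.5–4 Hz band-passed
signal per epoch, with the filter run on the *continuous* signal before
epoch slicing to avoid per-epoch edge transients. Known artifact: the
reflection padding of the zero-phase filter excites delta-band ringing at
the very edges of a session, and the FFT-based Hilbert kernel leaks a small
(1/t) fraction of that into interior epochs; for in-band signals this is
negligible, and the tests bound it explicitly for the degenerate
out-of-band-tone case. High-delta epochs use the midrange rule
`threshold = min + (max − min)/2` over the session's per-epoch amplitudes,
with strict exceedance.

Filtering itself is 4th-order-prototype Butterworth (band-pass filters have
2×4 poles), designed by bilinear transform with pre-warping and applied
forward–backward. No DSP package is assumed; design and application are
implemented and verified in-package against closed-form gain targets
(passband ≥ 0.99, 2× upper edge ≤ 0.1, high-pass DC < 1e-6).

## 4. Granger causality

VAR models are estimated by OLS on the stacked lag regression after
demeaning — the Gaussian ML solution. (The source methods name "LWR"
estimation; the toolbox it cites uses LWR for a Levinson–Wiggins–Robinson
recursion, an algorithmic detail with the same asymptotic contract as OLS,
so OLS is declared rather than guessed.) The innovation covariance divides
by the number of regression rows. Order selection minimizes
`log det Σ̂ + 2pm²/n` over `p = 1..round(20 ms · fs)` on a common sample.

Data may be a list of contiguous segments; lag windows never straddle
segment boundaries. This is how state-conditioned GC works: epochs of one
decoded state form maximal contiguous runs (`state_segments`), and the
regression pools within-run rows only.

Time-domain conditional GC refits full and reduced VARs and takes
`F = ln(Σ_reduced[target]/Σ_full[target])`, floored at zero (negative
estimates are a finite-sample artifact and flagged). Spectral GC follows
Geweke: for a pair, the innovation-covariance-normalized transfer function
decomposes the target spectrum into intrinsic and source-borne parts; the
conditional version embeds the reduced model's transfer function alongside
an identity row for the source (`Q(f) = Ḡ(f)⁻¹H̃(f)`) — the standard
construction for conditional spectral GC. Band means average `GC(f)` over
the 0.5 Hz grid inside the half-open band.

One numerical subtlety is documented rather than hidden: the marginal
process of a VAR is generally VARMA, so fitting the reduced model at the
same order as the full model leaves a few-percent gap in the Geweke
integral identity `F ≈ (1/π)∫GC dω`. The `p_reduced` argument lets the
reduced model take a higher order when the spectral decomposition is the
goal; the default keeps `p_reduced = p` so the two models stay nested and
the parametric F-test (with Benjamini–Hochberg FDR across the tested
family, Q = 0.05) remains valid. Raising `p_reduced` far beyond need
re-introduces error of the opposite sign through overfitting bias in
`Σ̂_reduced`; the acceptance test uses `p_reduced = 12` at `p = 3`,
`n = 10⁴`.

Both conditional (on all remaining channels) and unconditional pairwise GC
are exposed; the all-pairs table uses the conditional form by default.
GC is invariant to per-channel rescaling, which the tests assert to 1e-6.

## 5. Cross-frequency coupling

Delta phase and gamma amplitude come from the analytic signals of the
band-passed data; 5% of samples at each edge are discarded against filter
transients. The coupling vector is the amplitude-weighted circular mean;
its closed forms anchor the tests (uniform phase → 0; envelope
`1 + cos(φ − φ₀)` → strength 1/2 at angle φ₀; point mass → 1).

Two conventions are explicit because the source text supports either
reading:

* **Phase convention**: angle 0 at the delta *peak*, ±π at the trough
  (cosine convention). The generator and estimator share it, so round-trip
  tests pin the sign.
* **Weighting**: amplitude by default; `weight = "power"` switches to
  squared amplitude (the source methods use both words in adjacent
  sentences).

Per-state coupling pools samples by state *after* continuous filtering.
With a broadband carrier the estimator's expected strength for generator
strength `s` is `s/2` (the carrier envelope is independent of delta phase),
so the round-trip tests compare ratios and angles, not raw strengths.
States with under 2 s of data are flagged unreliable rather than erroring.

## 6. Bespoke statistics

The Sarle bimodality coefficient uses bias-corrected (adjusted
Fisher–Pearson) skewness and excess kurtosis with the finite-sample term
`3(n−1)²/((n−2)(n−3))`; benchmarks: 1/3 for a Gaussian, 5/9 ≈ 0.555 for a
uniform. The decision threshold defaults to the uniform benchmark and is
configuration, not dogma — the source reports the coefficient, not a
threshold.

The multi-sample circular-median test is the common-median test: pooled
circular median, per-group counts on either side of the diameter through
it, and the χ²(k−1) statistic `N²/(M(N−M))·Σmᵢ²/nᵢ − NM/(N−M)`. The
circular median minimizes mean circular distance over observed angles with
ties to the smallest angle; the statistic is discrete, so its null
distribution is conservative at small n (the calibration test checks
coarse uniformity, not an exact KS).

## 7. Pipeline and scale choices

`run_pipeline` executes simulate → segment → spectral → granger → cfc →
report with all defaults equal to the analysis conventions above (0.5-s
epochs and step; delta/gamma/high-gamma bands; 20-ms max VAR order;
Q = 0.05; 3 states). The default session length is a full six hours
(43,200 steps); tests and the acceptance script run 10–50-minute sessions
purely for runtime — a scale change, never a parameter change. Outputs are
plain text (CSV/TSV/JSON) plus raw float32 LFP with a JSON sidecar; the
report carries the config hash and seed, and deterministic stages are
bit-identical under re-runs.

## 8. Known limitations

* Decoded-state quality on synthetic sessions shorter than ~20 minutes is
  variable: the DMN state occupies ~15% of steps, and EM restarts can merge
  it into the active state. This is a property of the stated world at small
  n, not a defect masked by the tests.
* The sensor route cannot reproduce the printed emission probabilities
  exactly (Section 2); dwell times in seconds depend on the configurable
  step (Section 1).
* Group-level results from the source recordings (mean dwell 398 ± 31 s,
  overlap percentages 95/86/84%, time budget 54/15/30%, a bimodality
  coefficient of 0.83, absolute power/GC/cfc magnitudes) are not
  reproducible at desk scale and are represented only by qualitative
  invariants on synthetic data: state-dependent gamma power ordering,
  the planted gamma-band direction ranking, and state-dependent coupling
  strength ordering.
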