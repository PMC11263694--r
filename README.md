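# lfpstates

Unsupervised segmentation of home-cage behavioral states from two movement
sensors, and state-conditioned analysis of multichannel local field
potentials (LFPs).

## The problem

Freely behaving animals carrying a head-mounted logger produce two cheap,
complementary movement signals: the magnitude of a 3-axis accelerometer
(ACL, sensitive to head vibration at hundreds of Hz) and the nose speed
derived from markerless pose tracking of home-cage video (DLC, 2 frames/s,
sensitive to locomotion). Long home-cage sessions cycle through three broad
behavioral regimes — curled-up sleep posture, quiet internally-focused
behaviors associated with the default mode network (DMN: quiet wakefulness,
eating/drinking, grooming, nest box), and externally-focused
locomotion/exploration. `lfpstates` classifies these regimes without manual
scoring and then asks how brain rhythms recorded simultaneously at four
sites — ventral pallidum (VP), mediodorsal thalamus (MD), anterior cingulate
cortex (AC), and primary visual cortex (V1, a non-DMN control) — depend on
the behavioral state.

## The model

**Segmentation.** Each sensor is reduced to a common 0.5-s step and
thresholded at its session median, giving one of four output symbols per
step, `o_t ∈ {Lo/Lo, Hi/Hi, Lo/Hi, Hi/Lo}` (ACL letter first). A 3-state
hidden Markov model with discrete emissions,

    P(s_1 = i) = π_i,   P(s_{t+1} = j | s_t = i) = A_ij,
    P(o_t = m | s_t = i) = B_im,

is estimated by Baum–Welch (scaled forward–backward EM, random restarts)
and decoded with the Viterbi algorithm. Label switching is resolved by
emission signatures: the state with the largest `B[·, LoLo]` is `sleep`,
the larger remaining `B[·, HiLo]` is `dmn`, the last is `active`.

**State-conditioned LFP analyses.**

* *Band power*: 0.5-s epochs, Hann periodogram, mean one-sided density over
  delta (0.5–4 Hz), gamma (40–60 Hz) and high-gamma (60–150 Hz).
* *Directed interactions*: VAR models fit by least squares on the lag
  regression (AIC order selection up to 20 ms), time-domain conditional
  Granger causality `F = ln(Σ_reduced/Σ_full)`, Geweke spectral GC with
  band averages, F-tests with Benjamini–Hochberg FDR at Q = 0.05.
* *Cross-frequency coupling*: delta phase and gamma amplitude from
  zero-phase Butterworth filtering + Hilbert transform; the coupling vector
  `v = Σ a_t e^{iφ_t} / Σ a_t` summarizes strength (|v| ∈ [0,1]) and
  preferred delta phase (arg v; 0 = delta peak).
* *Auxiliary statistics*: Sarle bimodality coefficient
  `(g₁²+1)/(g₂ + 3(n−1)²/((n−2)(n−3)))` for the delta-amplitude
  distribution, and a non-parametric multi-sample circular-median test for
  preferred-angle comparisons.

A first-class synthetic generator (`simulate_state_sequence`,
`simulate_symbols`, `simulate_sensors`, `simulate_lfp`) produces sessions
with known latent states, log-normal sensor emissions, state-dependent band
amplitudes, planted gamma-band VAR coupling (MD→AC, MD→VP, VP→AC) and
planted delta→gamma phase–amplitude coupling, so every stage is testable
without recordings.

## Worked example

A 50-minute synthetic session, segmented and analyzed end to end:

```r
library(lfpstates)
cfg <- validate_config(list(out_dir = "demo", seed = 1,
                            simulate = list(n_steps = 6000),
                            hmm = list(n_restarts = 5)))
rep <- run_pipeline(cfg)
round(rep$segment$hmm$A, 3)       # fitted transition matrix (canonical)
#>       [,1]  [,2]  [,3]
#> [1,] 0.980 0.011 0.009
#> [2,] 0.017 0.862 0.121
#> [3,] 0.035 0.065 0.901
round(rep$segment$overlap, 3)     # decoded state vs ground-truth set
#>         1     2     3
#>   1 0.999 0.000 0.001
#>   2 0.012 0.917 0.072
#>   3 0.003 0.080 0.917
```

The fitted transition matrix reproduces the generator (sticky sleep state,
self-transition 0.98); decoded states match the hidden truth on 92–99% of
steps per state. The gamma-band Granger table ranks the three planted
directions first:

```r
head(rep$granger[order(-rep$granger$gc_gamma),
                 c("source", "target", "gc_gamma")], 3)
#>  source target gc_gamma
#>      MD     AC    0.254
#>      VP     AC    0.205
#>      MD     VP    0.203
```

and the MD coupling vector is strongest in the DMN state with preferred
angle near the planted −π/4:

```r
rep$cfc[rep$cfc$channel == "MD", c("state", "strength", "angle")]
#>  state strength  angle
#>      1   0.0078 -0.985
#>      2   0.2155 -0.804
#>      3   0.0909 -0.851
```

(Strengths in states 1/3 are small/intermediate, matching the generator's
per-state coupling 0.1/0.8/0.4 after envelope normalization; the state-1
angle is meaningless at strength 0.008.)

## Command line

```sh
Rscript inst/cli/lfpstates --config cfg.json --out outdir --seed 7 --stage all
```

Stages: `simulate`, `segment`, `spectral`, `granger`, `cfc`, `report`,
`all`. Outputs are plain CSV/TSV/JSON plus raw little-endian float32 LFP
with a JSON sidecar; logs go to stderr.
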