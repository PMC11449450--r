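---
title: "Methods: models, conventions and numerical choices in mastloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and numerical choices in mastloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastloop)
```

`mastloop` quantifies the mechanical function of a jaw-opening muscle during
mastication. This vignette is the package's account of the models it
implements, the conventions and defaults it fixes, and the numerical choices
behind them. Nothing here states an empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The analysis chain

A trial runs through five stages (`run_trial()`):

1. **Kinematics.** Skull and mandible marker sets are registered to their
   templates frame by frame with the SVD (Kabsch) solution of the orthogonal
   Procrustes problem, reflections excluded. The mandible-in-skull rotation
   is expressed in a condylar joint coordinate system (z through the
   left/right most-medial condylar points, x parallel to the occlusal plane)
   and decomposed with a body-fixed z–y′–x″ sequence so that **pitch about
   the condylar axis is the gape proxy**. The decomposition sequence is a
   convention, not a measurement; it is configurable, and the neutral
   (occluded) posture in which the JCS is defined maps to (0, 0, 0).
2. **Cycle segmentation and phases.** Chew cycles run from one gape maximum
   to the next (prominence-gated peak detection, gate 0.25 of the trace
   range, plateau ties resolved to the earliest frame) and are resampled
   onto a 101-point 0–100% grid. Phases are classified from gape velocity:
   fast closing ends where closing speed drops below a threshold fraction
   (default 0.25) of its within-cycle peak, slow closing ends at the end of
   minimum gape (occlusion), and slow opening ends where opening speed rises
   above the same fraction of its peak. The threshold is exposed because the
   underlying studies report boundary positions as results, not the
   detection rule; 25% of peak speed is a conventional fast/slow split.
   Durations sum to exactly 100% by construction.
3. **Strain.** Fascicle strain is the inter-bead distance minus the resting
   length over the resting length, with the resting length taken as the mean
   distance over the longest EMG-silent occlusion window (envelope below the
   burst threshold, minimum 100 ms; the required "extended" duration is not
   standardized, so it is configurable). Whether published strain amplitudes
   are means of per-cycle peak-to-peak values or the peak-to-peak of a mean
   trajectory is ambiguous; the package computes per-cycle values and
   reports their mean ± sd.
4. **EMG.** The envelope is the full-wave rectified signal low-passed at
   30 Hz (zero phase, order 4). Burst onset/offset use a threshold of
   baseline mean + 2 sd, with the baseline defaulting to the quietest 200 ms
   window, and a 10 ms debounce that both rejects single-sample crossings
   and bridges sub-threshold dips. Because a 2-sd threshold on a smooth
   envelope inevitably marks brief low-amplitude excursions as well, timing
   and recruitment default to the *major* bursts (integrated envelope at
   least half the largest; `major_bursts()`) — one recruitment burst per
   chew cycle. Offsets that fall in the cycle after their onset are
   reported as percent of that later cycle and flagged `wrapped`, matching
   the convention of quoting offsets as small early-cycle percentages.
   Recruitment is the ratio of mean per-burst integrated envelopes between
   test and reference sides; per-cycle ratios are averaged rather than
   pooling the integrals, since a pooled grand ratio and a per-cycle mean
   need not agree.
5. **Work loops.** With shortening positive, the work increment between
   samples is the trapezoidal force times the length decrease
   (N·mm = mJ); positive work sums positive increments, negative work
   negative ones, and net work is their exact sum. Mass-specific units are
   mJ kg⁻¹ and W kg⁻¹ (net work over cycle duration). Each increment is
   attributed to the phase containing its midpoint. The pipeline analyses
   every segmented cycle because the synthesizer stimulates every cycle; for
   ergometer records that begin with a passive loop, pass explicit `cycle`
   ranges to `loop_work()` and average the active loops (conventionally
   loops 2–5 of a 5-loop set).

## The Hill-type surrogate

The synthesizer's muscle is the minimal standard Hill form able to
reproduce measured isometric twitch kinetics and work-loop shapes:

* **Activation dynamics**: `da/dt = (u − a)/τ`, with `τ = τ_act` while the
  excitation is at or above the current activation and `τ = τ_deact`
  otherwise. Integration uses the exact exponential update per sample, so
  the step response is the closed-form `1 − exp(−t/τ)` to machine precision
  and the output is a convex combination of inputs, hence bounded in [0, 1].
* **Excitation**: each 0.2 ms stimulus pulse switches a full active state on
  for `excitation_ms`; pulses at the 200 Hz fusion frequency therefore merge
  into sustained excitation (tetanus), while a single pulse produces a
  twitch. This extra parameter is what lets one first-order stage express
  both twitch and tetanus.
* **Contractile element**: `F = a·f_max·fL(L)·fV(v) + F_pas(L)`. `fL` is 1
  on the plateau (`L ≥ l0`) with a parabolic ascending limb of width
  `fl_width·l0` (default 0.5); imposed trajectories keep `L ≤ l0`, i.e. the
  ascending limb and plateau only, mirroring the experimental practice of
  avoiding descending-limb instability. `fV` is the Hill hyperbola for
  shortening (curvature `a/P0 = 0.25`, `v_max = 10 l0 s⁻¹`, generic fast
  mammalian muscle values) and a linear eccentric branch capped at
  1.5 `f_max` — the conventional bound that prevents unbounded lengthening
  force. The passive element is slack below `l0` and linear beyond, so it
  never engages in the synthesized trials.
* **Calibration** (`calibrate_hill_params()`): on the plateau the isometric
  force peaks when the active state switches off, so `excitation_ms` is set
  to the twitch rise-time target (36.25 ms); `τ_deact` is found by bisection
  on the simulated half-relaxation time (31.0 ms) and `τ_act` by bisection
  on the simulated twitch:tetanus ratio (0.43). The defaults baked into
  `hill_params()` are these calibrated values; `f_max = 7.39` N is the force
  corresponding to 132.9 kN m⁻² of isometric stress over the 55.6 mm²
  digastric PCSA, and `l0 = 11.59` mm is the mean fibre length, so
  mass-specific work comes out in a physiologically sensible range.

## Synthetic trial design

The generator's defaults are the study conditions, fixed once:

* **Cycle frequency 3.4 Hz.** No chew frequency is printed alongside the
  work and power values, but net work divided by net power implies a cycle
  duration near 0.29–0.30 s on both sides; 3.4 Hz is the consistent choice.
* **Gape waveform.** Piecewise-linear gape (peak 15°) against cycle phase
  with knots at the phase boundaries (18.66 / 60.51 / 68.84%) and distinct
  per-phase speeds (fast closing ≫ slow closing; slow opening ≪ fast
  opening), so the velocity-threshold phase rule recovers the boundaries by
  construction. The exact in vivo waveshape is unpublished; the template is
  configurable in code, and amplitude/timing — not waveshape — are the
  validated features.
* **Strain proportional to gape**, zero at occlusion and most negative at
  maximum gape (a jaw opener is shortest at full gape), scaled to
  peak-to-peak 0.32 (working) or 0.23 (balancing). Muscle length for the
  force simulation is `l0·(1 + strain)`.
* **Activity window.** The stimulation envelope is a cosine-ramped boxcar
  (10 ms ramps) from 61.09% of each cycle to 10.99% of the next (working) or
  62.08% to 1.45% (balancing). The balancing envelope amplitude (≈0.60) is
  chosen so its *integrated* EMG is 47% of the working side's, the designed
  recruitment ratio.
* **Lead-in rest.** One second of EMG-silent occlusion precedes cycling: it
  is the resting-length window for strain and the burst-free baseline for
  the 2-sd threshold — a continuous chew sequence alone contains no 200 ms
  silent stretch at 3.4 Hz.
* **Markers and noise.** Skull (static) and mandible (hinging about the
  condylar z-axis, with a small yaw excursion during closing) carry three
  beads each; coordinate noise is 0.036 mm so the inter-marker distance sd —
  the tracking-precision metric — is 0.036·√2 ≈ 0.051 mm. The intramuscular
  bead pair rests 6 mm apart and its separation follows the strain
  trajectory.
* **EMG synthesis.** Band-limited (80–400 Hz) zero-mean Gaussian carrier
  noise amplitude-modulated by the stimulation envelope on a 0.01 V noise
  floor, sampled at 2 kHz. This reproduces the envelope statistics the
  analysis relies on, not motor-unit structure.
* **Determinism.** One generator seeded per trial; the seed is recorded in
  the truth record and regeneration is bit-identical.

What the generator does **not** emulate: cycle-to-cycle kinematic and
strain variability (the waveform is deterministic; only marker and EMG
noise vary), bolus-dependent modulation, tendon compliance (treated as a
stiff linkage), pennation gearing, motor-unit recruitment order, and
fatigue. Passing recovery tests therefore demonstrates the correctness of
the analysis chain under the stated noise model — not that real recordings
would behave this way. In particular, published in vivo group means (strain
amplitudes, phase boundaries, isometric stress, twitch:tetanus ratio) are
measurements of real animals used here only as scenario design values and
calibration corridors.

## Statistics

* **Pooled t.** The two-sample tests use the pooled-variance Student t with
  `df = n₁ + n₂ − 2`, computable from summary statistics alone
  (`ttest_from_summary()`); published degrees of freedom of this form (6
  and 92) identify the pooled, not Welch, test — for equal group sizes the
  two statistics coincide but their degrees of freedom do not. Reported
  p-values are two-tailed.
* **Curve comparison.** `compare_curves()` computes pointwise pooled t
  statistics on the 101-point cycle grid and controls the family-wise error
  with the permutation distribution of the maximum |t| over the cycle:
  group labels are permuted exhaustively when the number of assignments is
  below 20,000 and by 10,000 seeded random draws otherwise; the threshold is
  the (1 − α) quantile and clusters are maximal supra-threshold runs. This
  targets the same inference as one-dimensional statistical parametric
  mapping but replaces the random-field-theory threshold with a
  max-statistic permutation threshold — a deliberate, documented divergence:
  identical inferential target, different null machinery, exact by
  construction for exchangeable curves.

## Architecture morphospace

`PCSA = M cosθ/(ρ·L_f)` with density 0.001056 g mm⁻³ and `L_f` the mean of
the fibre-length measurements. The displacement/force/power boundaries in
published morphospace plots are visual; the package uses a within-set
median split of mean fibre length and PCSA as the reproducible rule
(configurable to mean or user-set splits), labelling the short-fibre/low-
PCSA quadrant "unspecialised". The shipped rabbit jaw-muscle table is
synthetic where it must be: the digastric row uses printed values (mass
back-computed from the printed PCSA), while the six jaw-closer rows are
representative constructed values, named and documented as such.

## Numerical choices

* Zero-phase Butterworth filtering (order 4; 25 Hz for kinematics and
  distances, 30 Hz for EMG envelopes) applies `signal::filtfilt` after
  odd-reflection padding of about nine time constants, so constant traces
  pass through unchanged and edges carry no start-up transient. The
  effective gain of the two passes is `1/(1 + (tan(πf/fs)/tan(πfc/fs))^{2n})`
  (bilinear design).
* The discrete work integral and the time-integral of instantaneous power
  (central-difference velocity) are algebraically identical, so energy
  accounting is exact at any sampling density; the trapezoid converges at
  second order on smooth loops and is exact for force linear in length.
* Twitch timing uses linear sub-sample interpolation at the half-peak
  crossing.
* Angle traces are unwrapped before differencing; velocities use central
  differences with one-sided endpoints.
* Degenerate inputs fail loudly: collinear marker templates, cutoffs at or
  above Nyquist, envelopes outside [0, 1], monotonic gape (no occlusion),
  empty resting windows, zero reference integrals and non-positive masses
  all raise validation errors rather than propagating silently.

## Problem sizes

The shipped tests and acceptance script run at desk scale by design:
5-cycle trials at 250 Hz kinematics / 2 kHz EMG, twitch simulations at
10 kHz, 500 null simulations with 5 curves per group on the 101-point grid
(252 exhaustive permutations each), and 100-seed Monte-Carlo property
checks. These sizes make every stage's behaviour observable in seconds
while leaving the estimators' asymptotics unexercised — a deliberate
trade-off for a validation-oriented synthetic harness.

## Known limitations

* The Hill surrogate's twitch stage is phenomenological: rise time equals
  the active-state duration by construction, so the calibration pins the
  printed kinetics without claiming mechanistic calcium dynamics.
* Morphospace labels depend on the muscle set through the median split;
  with small sets, muscles sitting exactly at a split point fall to the
  "not long / not high" side by the strict-inequality rule.
* The pipeline treats cycles as independent replicates, as the underlying
  comparisons do; no animal-level mixed-effects structure is modelled.
* Work-loop magnitudes of the synthetic trials depend on the Hill defaults
  (notably the eccentric cap and deactivation time constant) and are not
  tuned to reproduce published in vivo work values — only ground-truth
  consistency is asserted.
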