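---
title: "Methods: BOLD sLFO lag-structure analysis"
author: "slfolag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BOLD sLFO lag-structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slfolag)
```

## The model

Resting and task BOLD fMRI signals carry a spontaneous low-frequency
oscillation (sLFO, < 0.1 Hz) that is largely of systemic, blood-borne
origin. Because the oscillation travels with the blood, it arrives at each
voxel with a delay determined by that voxel's position in the vascular
tree: the *lag structure*. `slfolag` treats the sLFO as a virtual
intravascular tracer and implements the full analysis chain built on that
view:

1. **Lag mapping** — recursive cross-correlogram tracking of the sLFO phase
   outward from the global-signal phase, in 0.5-s steps, producing a voxel
   lag map and one seed time course per lag bin.
2. **Deperfusioning** — removal of the lag structure by regressing each
   voxel against its own lag bin's seed series (a "dynamic" form of global
   signal regression), compared against uniform GSR, low-pass GSR, and
   global scaling.
3. **rBTT / velocity** — the instantaneous phase difference between
   adjacent lag bins, estimated in a sliding Kaiser window, divided by the
   0.5-s step gives the relative BOLD transit time; its reciprocal is the
   instantaneous blood velocity relative to baseline.
4. **Multi-echo decomposition** — per-frame S0 and T2\* fields from a
   dual-echo acquisition under single-compartment monoexponential decay,
   `S(TE) = S0 exp(-TE/T2*)`, with `T2* = (TE2-TE1)/ln(S1/S2)`.
5. **Regional analysis** — inlet / center / outlet partitioning of the
   vasculature purely by lag sign and magnitude, sLFO magnitude (SD of
   percent signal change), inter-map ICC(2,1).

**Sign convention (project-wide).** Positive lag means the voxel *leads*
the global-signal phase — the arterial ("upstream") side. All modules use
this convention; none re-derives it.

## The synthetic test bed

No participant data accompany the method, so every stage is validated
against a generator (`synth_spec()` / `simulate_bold()`) whose ground truth
is known exactly. Voxel signals are synthesized through the physical decay
model: `y(v,t) = S0(v,t) exp(-TE/T2*(v,t))`, with

* an **advected sLFO**: a band-limited (0.008–0.07 Hz by default) unit-variance
  waveform `w` entering `1/T2*` as `a·w(t + tau_v / vrel(t))`, so that a
  voxel with delay `tau_v > 0` leads the global phase by `tau_v` when
  `vrel = 1`;
* a **quasi-static velocity model**: a relative-velocity profile `vrel(t)`
  scales every delay instantaneously as `tau/vrel(t)`. This is the minimal
  model for which the rBTT ground truth is closed-form
  (`d(t) = step/vrel(t)`); velocity changes of interest are slow relative
  to transit, so explicit advection along a vessel graph is not modelled;
* **NVC events**: a canonical double-gamma HRF (peak ~5 s, undershoot
  ~15 s, unit peak) convolved with the event boxcar, added to `1/T2*` in
  the active mask. The generator can set the sample correlation between
  `w` and the task regressor *by construction* (exactly orthogonal at 0);
* an **S0 channel**: a 0.2-Hz respiration-locked waveform with an
  anterior/posterior sign flip, entering `S0` multiplicatively — the
  non-BOLD component that multi-echo decomposition must separate;
* **thermal noise** (additive Gaussian) and **spike frames** (transient
  global deflection > 1% plus a > 1 mm entry in the emitted motion table).

The default delay field is a smooth axial gradient spanning +4…−4 s
(artery-to-vein ordering) with a small oblique secondary gradient (±0.25 s
across the second axis). The obliquity matters: vascular territories are
not planar, and it gives every 0.5-s lag bin a continuous spread of true
delays. A strictly planar field on a coarse grid makes each bin a
single-valued plate whose quantized phase drifts against the 0.5-s
recursion grid.

Reference study conditions (defaults): 20×20×10 voxels, 1080 frames at
TR 0.5 s, sLFO amplitude 2% of baseline, NVC 1%, noise SD 0.5%, baseline
T2\* 40 ms read at TE 35 ms (dual-echo: TE 11.2/32.78 ms), S0 channel
0.5%. These are the values the analysis chain quotes or, where unstated,
typical 3-T gray-matter physiology.

What the generator does **not** emulate: vascular-graph branching with
realistic path dispersion, draining-vein geometry, cardiac-band
pulsatility, waveform deformation along the path, and spatially correlated
noise. Passing tests therefore demonstrate the estimators' correctness
under the stated model, not robustness to every physiological confound of
real data.

## Numerical choices

* **Band-pass filtering** is a zero-phase frequency-domain filter with
  raised-cosine transitions (default 15% of each edge) applied after
  mirror-padding. Lag estimation is phase-critical, so a zero-phase filter
  is required; IIR designs (e.g. Butterworth + `filtfilt`) are numerically
  fragile at 0.008 Hz relative to a 1-Hz sampling rate. `make_slfo()`
  synthesizes its waveform directly on the spectral grid (random phases,
  tapered band), which makes the band-power property exact rather than
  approximate.
* **Correlogram peaks** are located at integer frame shifts only; the bin
  width *is* the tracking step, so sub-frame refinement would add spurious
  precision (data at other TRs should be resampled to 0.5 s first, as the
  multi-echo runs are). A voxel whose peak ties between two lags is left
  unassigned for the hole-filling passes, because a wrong assignment
  propagates through the recursion.
* **Recursion order**: upstream and downstream runs proceed independently
  from the initial lag-zero seed. For disjoint bins the result is
  identical to alternating directions; only seed composition at the range
  edges could differ.
* **Hole filling** pass 1 averages lags of *in-phase* sources only:
  correlation above threshold at zero shift and not exceeded at a ±1-frame
  shift. sLFO-band signals correlate appreciably across several seconds of
  lag, so averaging over every voxel passing the bare threshold would drag
  estimates toward the global mean lag. Weighted linear averaging is used
  (not circular phase averaging): lags live on a bounded linear axis.
  Pass 2 fills single isolated holes with the mean of their 6 face
  neighbours, reading pre-pass-2 values only.
* **Spike detection** compares the global signal and each motion parameter
  to a 5-frame running-median reference. This flags exactly the deviant
  frames of 1–2-frame excursions (never the recovery step) and is immune
  to slow in-band drift of the global signal, which a consecutive-frame or
  last-accepted-frame rule misattributes to dropout. Limitations:
  excursions of ≥ 3 frames and sustained level shifts are deliberately not
  flagged (the latter belong to the motion regressors). Either criterion
  (global-change OR displacement) suffices to flag a frame, since signal
  dropout can occur without recorded motion; the per-criterion hits are
  reported so a conjunctive rule is recoverable.
* **Instantaneous phase difference**: a windowed cross-correlation peak
  with parabolic sub-sample refinement on the 0.02-s grid, computed for
  all window centres at once by FFT convolution with the Kaiser taper
  (window 30 s, β = 4). Analytic-signal (Hilbert) phase is unsuitable for
  broadband fluctuations. The peak search is restricted to 0.5 ± 0.25 s to
  prevent cycle hopping: phase differences are perturbations around the
  0.5-s bin step. Centres with an out-of-span or weak (r < 0.3) peak
  return NA.
* **Deperfusioning** regresses the band-limited bin seed out of the
  full-band voxel series and subtracts the fitted component, so content
  outside the sLFO band passes through untouched (re-filtering the
  residual would alter it). Voxels that received a lag only through hole
  filling have no bin membership; they use the nearest bin's seed. Voxels
  with no lag at all fall back to low-pass GSR. Both counts are reported.
* **GLM**: OLS with intercept, linear drift, and the HRF-convolved
  regressor (unit peak, so percent-change data yield betas in percent).
  A linear trend is the minimal stand-in for a dedicated high-pass step.
* **Multi-echo validity**: `T2* ≤ 0` or `> 100 ms` (closed upper boundary,
  to within a relative `1e-12` guard) marks a sample as noise; invalid
  samples stay missing through decomposition and are linearly interpolated
  only at the temporal-analysis stage (`interpolate_invalid()`), with the
  count reported.
* **ICC(2,1)** is computed from the two-way ANOVA mean squares with maps
  as raters: `(MSR − MSE) / (MSR + (k−1)MSE + k(MSC − MSE)/n)`.
* **Regions**: the ±7-s lag structure uses a ±2.5-s center; rBTT-style
  ±4-s structures use `equal_bin_halfwidth()`, which picks the half-width
  splitting the 17 bins into 5/7/5 (the closest symmetric three-way
  split).

## Design points that were genuinely open

* **Untracked voxels** are encoded as NaN in written lag maps, so sign and
  units survive into downstream tools.
* **"Euclidean distance ± 1 mm or ± 1° rotation"**: translations are
  combined by Euclidean norm; rotations are checked per axis. Mixing mm
  and degrees in a single norm is ill-defined.
* **Event-locked averaging** uses a configurable peri-event window
  (default −10…+60 s) with the pre-event mean as baseline, re-anchored at
  the nominal 0.5-s step.
* **Deperfusioning and task variance.** The bin seeds are empirical
  averages; in finite runs they carry chance correlation with any task
  regressor, scaled by the sLFO/NVC amplitude ratio, and deperfusioning
  removes that shared part. With sLFO 2% and NVC 1.5% over a 6-min run
  the active-voxel beta attenuates by roughly 15%; with a weak sLFO
  (0.5%) and a strong task (2%) recovery is within 10%. This is a real
  property of lag-structure removal, not an estimator defect, and it is
  why the mean-beta comparisons report orderings rather than magnitudes.

## Problem sizes

The shipped tests and the acceptance script run the full reference volume
(20×20×10 × 1080 frames) for lag mapping, deperfusioning, and velocity
recovery, a 12×8×3 × 720-frame grid across 20 seeds for the
spurious-deactivation ordering, and smaller grids for unit-level
properties. These sizes keep each stage's ground-truth behaviour
measurable (every 0.5-s bin populated, ≥ 5 sLFO cycles per run) at
interactive runtimes.

## Known limitations

* Tracking assumes the phase is unique within the correlogram range, which
  couples the band upper edge to the tracking range (0.07 Hz for ±7 s,
  0.12 Hz for ±4 s). Out-of-range delays alias back into the range.
* The quasi-static velocity model ignores transit-time dispersion and
  waveform deformation; rBTT ground truth is exact only under it.
* Group-level inference (random effects, FWE correction, repeated-measures
  ANOVA) is out of scope; the package emits the per-dataset tables such
  analyses consume.
* The spike detector does not flag sustained level shifts or ≥ 3-frame
  dropouts.
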