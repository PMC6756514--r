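# slfolag

Lag-structure analysis of BOLD low-frequency oscillations in R.

The spontaneous low-frequency oscillation (sLFO, < 0.1 Hz) in BOLD fMRI is
largely systemic and travels with the blood, so it reaches each voxel with a
delay set by the voxel's position in the cerebral vascular tree. Mapping
that delay ("lag mapping") recovers a perfusion-ordered picture of the
vasculature from an ordinary fMRI run; removing the resulting *lag
structure* is a principled, per-voxel-phase form of global signal
regression; and the small fluctuations of the phase *differences* between
neighbouring vascular territories carry relative blood-velocity changes.

`slfolag` is for researchers who want to apply or study these ideas with a
fully tested, ground-truth-validated implementation. It provides:

- **Lag mapping** (`track_lags`, `fill_holes`): recursive cross-correlogram
  tracking of the sLFO phase from the global-signal phase outward, in 0.5-s
  steps over ±7 s (±4 s for velocity runs), with correlation-threshold
  gating (r ≥ 0.3) and two-pass hole filling. Sign convention: positive lag
  = voxel leads the global phase = arterial side.
- **Deperfusioning** (`deperfusion`): per-lag-bin regression of each voxel
  against its own seed time course ("dynamic GSR"), alongside uniform GSR,
  low-pass GSR, and global scaling (`gsr`, `global_scaling`), evaluated
  with a single-run canonical-HRF GLM (`fit_glm`).
- **Relative BOLD transit time** (`instantaneous_phase_diff`,
  `rbtt_trace`): sliding Kaiser-window (30 s, β = 4) cross-correlation at
  0.02-s resolution between adjacent lag bins; phase difference / 0.5 s =
  rBTT, and 1/rBTT is the instantaneous relative velocity.
- **Multi-echo decomposition** (`me_decompose`, `me_synthesize`): per-frame
  S0 and T2\* from dual-echo data under monoexponential decay,
  `T2* = (TE2−TE1)/ln(S1/S2)`, with the 100-ms/negative-T2\* noise rule.
- **Regional analysis** (`partition_regions`, `regional_summary`,
  `icc_2_1`): inlet/center/outlet partitioning by lag, sLFO magnitude (SD
  of percent signal change), phase delays, and ICC(2,1) map similarity.
- **A synthetic 4D generator** (`synth_spec`, `simulate_bold`) with exact
  ground truth — propagating sLFO with a known delay field, velocity
  modulation, HRF-convolved task responses, independent S0/T2\* channels
  for dual-echo synthesis, thermal noise, and motion/intensity spikes —
  used to validate every stage end to end.
- **Preprocessing** (`detect_spikes`, `repair_frames`, `motion_design`,
  `regress_out`, `bandpass`, `percent_change`) and a declarative pipeline
  (`run_pipeline`) with a YAML config, NIfTI/TSV outputs, a parameter log,
  and a thin CLI (`inst/cli/slfo.R`).

See `vignettes/lag-structure-methods.Rmd` for the model, the estimator
choices, and the generator's scope.

## Worked example

Generate the reference synthetic dataset, map its lag structure, remove it,
and summarise the vascular regions:

```r
library(slfolag)

spec <- synth_spec(grid = c(20, 20, 10), n_frames = 1080, delay_range_s = 4,
                   noise_sd_pct = 0.5, rng_seed = 42)
sim <- simulate_bold(spec)

pct <- percent_change(sim$volume)
vb  <- bandpass(pct, 0.008, 0.07)
ls  <- fill_holes(track_lags(vb, corr_threshold = 0.3,
                             step_s = 0.5, range_s = 4), vb)
ls
#> <lag_structure> 17 bins, lags +4 .. -4 s (step 0.5 s)
#>   tracked 4000 / 4000 masked voxels (r >= 0.3)

cor(ls$lag_map[sim$volume$mask], sim$truth$delay_field[sim$volume$mask])
#> [1] 0.998                      # estimated lag map vs true delay field

clean <- deperfusion(pct, ls)
#> deperfusion: 3970 binned, 30 nearest-bin (hole-filled), 0 GSR-fallback voxels
1 - mean(band_variance(clean)) / mean(band_variance(pct))
#> [1] 0.994                      # 99.4% of sLFO-band variance removed

rg <- partition_regions(ls, equal_bin_halfwidth(ls, 4))
regional_summary(pct, rg)
#>   region n_voxels magnitude_pct phase_vs_center_s
#> 1  inlet     1109      1.981844          2.867025
#> 2 center     1777      1.920165          0.000000
#> 3 outlet     1114      1.951202         -2.836758
```

The lag map correlates at r = 0.998 with the generator's delay field (mean
absolute error 0.12 s, half the 0.25-s bin half-width); deperfusioning
removes essentially all sLFO-band variance; and the regional summary shows
the inlet leading and the outlet trailing the center by ±2.9 s with the
uniform 2% sLFO magnitude the generator injected.

The same chain runs from a config file:

```sh
Rscript inst/cli/slfo.R run --config config.yaml --out out/
```

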