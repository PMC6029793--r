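---
title: "Isolating narrative networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating narrative networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Two stimulus conditions present the *same* story through different media: an
audiovisual movie, and its script shown as timed text slides whose onsets and
durations are locked to the corresponding film events. Because the narrative
events are synchronized across conditions, any brain network that tracks the
story content — rather than the visual or orthographic surface — should show
correlated activity between the two runs, while sensory networks should not.

`narranet` operationalizes this idea as a pipeline over multi-subject,
two-condition BOLD data:

1. **Group spatial ICA.** Every run (subject x condition) is modelled as a
   sum of spatial components with run-specific time-courses,
   `Y ≈ Σ_k tc_k ⊗ map_k`. Runs are voxel-mean-centred, reduced along time
   by a run-level PCA of rank `r1`, stacked along the reduced-time axis, and
   reduced again to `K` whitened dimensions. An InfoMax unmixing matrix is
   estimated on the whitened spatial data by full-batch natural-gradient
   ascent with a logistic score, `dW = lr (I + (1 − 2g(WX)) (WX)'/n) W`. The
   logistic score targets super-Gaussian (sparse) sources, which is exactly
   what localized spatial maps are. Because all runs enter one decomposition,
   component `k` is automatically the *same* network in every subject and
   both conditions.
2. **GICA3 back-reconstruction.** Run-specific maps are
   `R · W M_j X_j` and time-courses `(1/R) · F_j G_j A`, where `F_j, G_j` are
   the run-level and group-level PCA back-projections, `M_j` the partitioned
   whitener, `A = W^{-1}`, and `R` the number of runs. This partition makes
   the average of all run maps equal the group maps exactly — a property the
   tests assert to machine precision.
3. **Cross-modal ranking.** Ranking A correlates the *group-averaged* movie
   and script time-courses per component ("correlation over averages");
   ranking B averages *subject-level* cross-condition correlations ("average
   over correlations"). A's modality-wise averaging suppresses
   subject-specific intrinsic fluctuations, so it is the primary ranking;
   B's subject-level correlations are attenuated by subject noise, and the
   tests check `r_B ≤ r_A + 0.05` for shared signals.
4. **Inference by circular shift permutation.** The null distribution of a
   cross-modal (or dialog) correlation is built by circularly shifting one
   series over every admissible offset — all offsets with absolute circular
   value of at least 2 TRs, in either direction. For 212 volumes this gives
   exactly 209 shifts; pooling over 40 components gives an 8360-value null.
   Circular shifting preserves each series' autocorrelation while breaking
   the alignment, which is the property that makes the percentile a valid
   p-value. Two-tailed p-values double the smaller one-sided
   add-one-corrected percentile, `p = min(1, 2·min((#{null ≤ r}+1)/(N+1),
   (#{null ≥ r}+1)/(N+1)))`, and are Benjamini–Hochberg adjusted over the
   `K` components.
5. **Dialog regressor.** A boolean dialog on/off envelope sampled on a
   microtime grid (16 bins per TR) is convolved with the canonical
   double-gamma HRF, linearly interpolated to volume midpoints, high-pass
   filtered and z-scored. Component time-courses correlated with it
   (subject-level, then averaged) classify networks as dialog-activated or
   dialog-deactivated.
6. **Group maps.** Condition-averaged subject maps enter a voxelwise
   one-sample t-test (df = subjects − 1); maps are thresholded at a
   Bonferroni-corrected height threshold with a cluster extent minimum, and
   clusters are labelled against an integer-labelled atlas.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_components` (K) | 40 | – | study-scale model order; small synthetic studies use K = number of planted sources |
| `r1` | min(1.5·K, t−1) | – | run-level PCA over-retention before the second stage, the usual group-ICA convention |
| `fwhm` | 7 | mm | spatial smoothing; 0 disables |
| `cutoff_hz` | 0.01 | Hz | DCT high-pass; removes drift below the cutoff |
| `min_shift` | 2 | TRs | smallest circular offset admitted to the null, so near-aligned shifts cannot contaminate it |
| `fdr_q` | 0.05 | – | BH level over components |
| `top_k` | 5 | – | components promoted to "narrative" status |
| `n_peak_voxels` | 500 | voxels | peak neighbourhood for sign validation |
| `height_p`, `extent` | 0.001, 50 | –, voxels | group-map height and cluster-extent thresholds |
| `tr` | 2.015 | s | acquisition interval |

InfoMax specifics (logistic score, full-batch natural gradient, learning
rate 0.01 with annealing x0.9 on direction reversals and mild acceleration
x1.02 while the direction is stable, capped at 0.1; convergence when
`max|dW| < 1e-6`; 2000 iterations maximum) are fixed, documented arguments
— no toolbox defaults are inherited. On rotationally unidentified inputs
(pure Gaussian noise, which the type-I calibration study deliberately
feeds in) the iteration legitimately exhausts `max_iter`; the fit then
carries a structured warning rather than an error, and `strict = TRUE`
upgrades it to an error for callers that require convergence.

## What the generator emulates — and what it does not

`synthetic_config()` defaults describe the emulated study: 31 subjects, two
conditions of 212 volumes at TR 2.015 s, a 20x20x12 voxel grid
(deliberately desk-scale; every algorithm is shape-agnostic, and the full
2 mm MNI grid would only multiply runtimes), baseline 100 so percent
scaling is meaningful, event slides of 1–4 s with mean 3.13 s, and
counterbalanced condition order (half the subjects movie-first; the
analysis is asserted to ignore this flag).

Planted sources are Gaussian blobs (sd 1.4 voxels, weights < 0.01
truncated) on a farthest-point lattice, which guarantees pairwise spatial
correlations below 0.1 — spatial ICA assumes spatially independent maps, so
the generator enforces what the model assumes. Shared sources mix a common
innovation into both conditions with weight `sqrt(rho)`, making the target
cross-condition correlation analytic rather than tuned. The dialog-locked
source follows the HRF-convolved dialog envelope plus small noise; when an
anti-correlated (deactivated) dialog source is also planted, the two
sources receive envelope loadings `sqrt(0.65)` and `−sqrt(0.5)` — a
perfectly collinear pair would be unseparable by *any* decomposition, so
each needs its own non-envelope temporal direction.

Two generator choices deserve their rationale spelled out:

- **Drift.** Scanner drift is modelled as random coefficients on the
  discrete-cosine drift basis below 0.005 Hz (sd `drift_amplitude`, global
  across voxels). A windowed off-grid cosine may look like the more natural
  choice, but it is only ~95% removable by DCT residualization and its
  residual concentrates at the run edges; being spatially global, that
  residual surfaces as a component whose zero-lag cross-condition
  correlation the shift-permutation null cannot calibrate (shifting moves
  the edge energy away). On-basis drift is removed exactly at the 0.01 Hz
  cutoff, which is the premise of including drift at all: the filter is
  exercised, and what survives it is signal.
- **Subject structure.** Sources are subject-homogeneous with independent
  subject noise. Real narrative responses have structured inter-subject
  variability (latency shifts, amplitude differences, partially shared
  idiosyncratic networks); nothing here emulates that. Passing tests
  therefore demonstrate correctness of the *procedure* under the stated
  noise model, not robustness to realistic population heterogeneity — nor
  to EPI artefacts, hemodynamic nonlinearity, or motion-correlated signal,
  all of which are out of the generator's scope.

SNR is defined at blob peaks: `source_amplitude / noise_sd` (1 by default).
Motion traces are 6-parameter random walks (translation step sd 0.025 mm,
rotations scaled by the 50 mm sphere convention), chosen so framewise
displacement RMS lands near 0.12 mm, the scale reported for compliant
adult cohorts; motion is reported by QC but not injected into the signal.

## Numerical choices and degenerate inputs

- **High-pass filter**: projection onto the complement of the DCT drift
  basis (`k ≤ 2·t·TR·cutoff`), mean preserved, exactly idempotent and
  linear. Constant series pass through; cutoffs at or above Nyquist are
  rejected.
- **Smoothing**: separable truncated Gaussian (4 sd radius) with unit-row
  renormalization at the edges, so constants are preserved exactly and
  interior impulse mass is conserved.
- **DVARS** is computed on percent-of-voxel-mean signal by default (the
  normalization that makes a dimensionless RMS meaningful); raw-unit mode is
  available and is the mode in which DVARS is exactly invariant to adding a
  temporally constant image.
- **Correlation throughout is Pearson**; shifted correlations are computed
  by the FFT circular cross-correlation identity (valid because circular
  shifts preserve mean and variance) and are tested against a naive loop.
- **Ties**: component ranks break ties by ascending index; peak-voxel
  neighbourhoods break distance ties by larger absolute map weight.
- **Zero-variance cases**: constant maps contribute 0 to the match tensor
  (with a warning count); zero-variance voxels get t = 0 (with a warning);
  constant series are rejected wherever a correlation would be undefined.
- **Sign conventions**: group maps are normalized to unit RMS with positive
  absolute peak; back-reconstructed components are sign-validated against
  the mean BOLD around each map's peak ("nearest 500 voxels" reads as
  nearest by Euclidean distance — top-500-by-weight is the other reading of
  an ambiguous phrase; the Euclidean reading keeps the neighbourhood
  spatially compact).
- **FWE**: Bonferroni over in-mask voxels — conservative and exactly
  reproducible, where random-field theory would need smoothness estimation
  that a desk-scale synthetic grid cannot support. Uncorrected mode exists
  for small grids.
- **Connectivity**: 18-neighbour default (faces + edges), with 6 and 26
  selectable.

## Problem sizes used by the test-suite studies

The acceptance studies run at the emulated design's full size where the
quantity depends on it — parameter recovery uses 31 subjects x 212 volumes
x 20x20x12 voxels with 3 shared sources at target r = 0.7, 4
modality-specific sources, SNR 1 and K = 7, over 20 seeds. Calibration
studies that only need many null components use smaller cohorts (type-I:
6 subjects at K = 40 over 20 seeds; dialog recovery: 12 subjects at K = 6
over 10 seeds), sizes chosen once as the smallest at which the statistics
in question are stable.

## Known limitations

- GICA back-reconstruction is the GICA3 partition only; GICA1/GICA2 and
  ICASSO-style stability resampling are not implemented.
- The permutation scheme assumes (circular) stationarity of the series;
  strongly non-stationary artefacts aligned across conditions would inflate
  it (the drift discussion above is exactly such a case).
- Ranking A's literal invariance is to a common positive rescaling of each
  condition's time-courses; rescaling *individual subjects* changes the
  group average and thus, in general, the statistic. Ranking B is invariant
  to arbitrary positive per-subject, per-condition rescalings.
- The atlas is any integer-labelled volume on the data grid; no anatomical
  atlas ships with the package, and `synthetic_atlas()` is a labelled
  k-means partition, not anatomy.
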