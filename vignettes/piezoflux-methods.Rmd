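---
title: "Methods: interblade-distance estimation and functional-assay fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interblade-distance estimation and functional-assay fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piezoflux)
```

## The measurement problem

PIEZO1 is a trimeric mechanosensitive channel whose three blades curve
into the membrane at rest and flatten upon activation. Labelling the
distal blade tips and localizing them with 3D-MINFLUX/DNA-PAINT turns the
conformation of a *single channel* into a geometric quantity: the
interblade distance, defined as the mean of the three pairwise 3D
distances between blade-tip label positions. Conformational change shows
up as a shift of the interblade-distance distribution across a population
of channels, typically by ~2 nm against a ~5.5 nm-wide conformational
spread, so every step between raw localizations and the final two-sample
test matters.

DNA-PAINT complicates the geometry in a useful way: each label site is
visited repeatedly by imager strands, producing many short emission traces
(grouped by their trace ID, TID), each of which yields a cloud of
localizations. The pipeline therefore reduces localizations → traces →
trace centers → protomer sites → trimers.

## Localization filtering

The filter chain runs in a fixed order; each step's defaults are the
values used throughout this package:

* **cfr ≤ 0.8** and **efo ≤ cutoff** per localization. Both metrics flag
  multi-emitter contamination. The cfr cutoff is taken as inclusive (a
  localization at exactly 0.8 is kept); no authoritative convention
  exists, and the choice only moves ties. The efo cutoff has no canonical
  absolute value, so the default is the dataset's own 95th percentile
  (configurable as an absolute kHz value); the cutoff actually applied is
  written to the run report so the choice is auditable.
* **Trace-level exclusion**: a trace is dropped if its *sample* (n−1)
  standard deviation exceeds 10 nm on **any** single axis — the strictest
  reading of an "x, y, z" rule, chosen because a trace dispersed on even
  one axis is not a reliable point emitter — or if it has fewer than 3
  localizations. Ties at exactly 10 nm are kept (strict `>`).
* **Head trimming**: the first 2 localizations of each trace (in time
  order) are removed; the start of a binding event is often displaced from
  the converged localization cloud. A 3-localization trace keeps its last
  localization and survives, which is the literal consequence of running
  the size filter *before* trimming.
* **z × 0.7**: the refractive-index mismatch between coverslip and
  aqueous sample compresses the apparent axial scale; multiplying z by 0.7
  restores it. Scaling commutes with the center-of-mass step, so applying
  it after trimming is consequence-free (asserted by a test).
* **Centers of mass**: unweighted per-trace mean of x, y, z.

Tightening any cutoff can only shrink the surviving set; this
monotonicity is property-tested.

## Protomer merging and trimer identification

Repeated traces on the same blade tip are merged by DBSCAN with ε = 8 nm
and minPoints = 2 in the 3D Euclidean metric, ε reflecting MINFLUX
localization precision plus tag/linker flexibility. Two conventions are
worth spelling out because implementations differ:

* minPoints counts the point itself, so minPoints = 2 means "self plus at
  least one neighbour". With that convention the clustering equals the
  connected components of the ε proximity graph, which is exactly what the
  test oracle computes independently via graph components.
* DBSCAN noise points (singleton centers) are *kept* as single-trace
  protomer sites: a protomer detected only once is still a protomer.

Triple-labelled trimers are site triples satisfying all of:

1. all three pairwise 3D distances < 40 nm — the largest physically
   possible blade-tip separation in the fully flattened conformation, so
   anything wider cannot be one channel (strict `<`, ties rejected);
2. no non-member site within 60 nm of **any** member (the strictest
   reading of an isolation rule; measuring from the centroid instead is
   available but not default) — this suppresses chance triples in crowded
   regions and guarantees no two accepted trimers share a site;
3. maximum internal triangle angle < 120°, rejecting near-collinear
   artefacts that cannot be a trimeric arrangement.

Distances and angles are computed in 3D on z-corrected coordinates; the
40 nm bound derives from 3D structure, so applying it to a 2D projection
would conflate tilt with conformation. The bivariate Gaussian fit of each
protomer's raw in-plane (x, y) localizations is provided for visualization
and as an alternative blade-position estimate; its ML mean equals the
arithmetic mean, and a singular covariance is ridge-regularized with a
logged message.

`find_trimers()` enumerates triangles of the <40 nm proximity graph rather
than all C(n,3) triples; tests compare it against exhaustive enumeration
on hundreds of random site sets.

## Cohort statistics

Interblade-distance samples are summarized as mean ± SEM with unbiased
SD. Two-condition comparisons are gated on normality: both groups are
tested with the D'Agostino–Pearson K² omnibus test (implemented from the
standard skewness and kurtosis z-approximations; it needs n ≥ 8, smaller
groups fall back to Mann–Whitney with a warning). If both pass at
α = 0.05 (configurable; no canonical value exists for the gate), a
two-sided *equal-variance* Student t-test is used — the classic test, with
Welch available by flag — otherwise a two-sided Mann–Whitney U. No
multiple-testing adjustment is applied, matching common practice for
single planned comparisons. `power_check()` wraps the whole gated
procedure in a simulation loop; under normal nulls at n = 100 per group
its type-I error stays within [0.03, 0.07] (verified with 2000
simulations).

## Functional-assay quantification

* **Mechanical threshold**: first stimulus whose peak deviation from the
  pre-stimulus baseline exceeds 6× the baseline SD. A zero baseline SD
  (noise-free synthetic traces) is replaced by an absolute floor
  (default 0.5 pA, logged in the result).
* **Inactivation**: nonlinear least squares of
  `I(t) = C1 + C2·exp(−(t−t0)/τ)` with `t0` fixed at the window start —
  leaving it free is degenerate with `C2`. Traces with no detectable
  decaying component are flagged degenerate rather than fitted. Cell-level
  τ averages sweeps whose peak magnitude lies in [100, 1500] pA, with
  equal weights (weighting by peak size has no principled basis here).
* **Pressure response**: per-sweep peak over the 500 ms stimulus window,
  normalized by the cell's maximal response; Boltzmann fit
  `R(P) = 1/(1 + exp((P − P50)/k))` with `k > 0` so the response grows as
  pressure becomes more negative. P50 is reported on the sampled pressure
  axis (negative mmHg for suction) *and* as a magnitude, because sign
  conventions vary across reports. Fits with P50 beyond the sampled range
  plus one protocol step are flagged as extrapolated.
* **Peak/sustained ratio**: peak over the mean of the final 10% of the
  stimulus window (the "sustained" fraction is not canonically defined;
  10% is the default and configurable), both baseline-subtracted; a fully
  inactivated sustained level produces a capped, flagged ratio.
* **Single-channel amplitude**: per 1 s segment, a Freedman–Diaconis
  histogram of the current samples is fitted with the sum of two Gaussians
  initialized at the two dominant histogram modes; the amplitude is the
  difference of the fitted peak positions, signed open-minus-closed with
  the taller component taken as the closed level. Segments whose fitted
  modes are not separated relative to their widths (or the bin width) are
  treated as event-free; noise-free two-level traces short-circuit to the
  exact level difference. Conductance is the OLS slope of amplitude vs
  voltage (pA/mV × 1000 = pS).
* **Calcium imaging**: F/F0 with F0 averaged over a 10 s control window;
  dose-response fitting averages per-cell maximal F/F0 per concentration
  and fits a four-parameter logistic in log10 concentration. The maximal
  response is taken within the drug window only (not washout).

All current-axis quantifications are scale-consistent: scaling currents by
a constant leaves τ, P50, thresholds and peak/sustained ratios unchanged
and scales amplitudes and conductance linearly (property-tested).

## What the synthetic generators emulate — and what they do not

`generate_minflux_dataset()` places equilateral-up-to-jitter blade-tip
triangles whose side length is drawn from a truncated normal on (0, 40]
nm, then emulates, per labelled protomer, repeated DNA-PAINT traces
(Poisson count, floor 1) of noisy localizations (Poisson count, floor 3 so
the minimum-size filter stays exercised). Defaults and their rationale:

| parameter | default | rationale |
|---|---|---|
| `loc_sd` | 2 nm/axis | mid-range MINFLUX localization precision |
| `linkage_sd` | 1.5 nm/axis | mean 3D label offset ≈ 2.4 nm (nanobody + docking strand) |
| `z_plane_sd` | 10 nm | membrane topography across the field |
| `traces_per_label` | 3 | enough repeats to exercise DBSCAN merging while keeping tests fast |
| `locs_per_trace` | 6 | typical short binding events; 4 survive trimming on average |
| `label_efficiency` | 0.8 | realistic nanobody labelling; unreported for real samples, free parameter |
| `background_trace_density` | 2 /µm² | sparse nonspecific binding; unreported, free parameter |
| `multi_emitter_fraction` | 0.1 | contaminated traces draw cfr strictly above 0.8 and high efo, so filter efficacy is measurable |

Emitted z values are *divided* by 0.7 so the pipeline's z-correction is
exercised rather than bypassed, and timestamps are sequential per trace
(only ordering is used). Trimer centroids are placed ≥ 150 nm apart so the
isolation rule acts on background and neighbouring channels rather than on
packing artefacts.

Not emulated: blinking kinetics, photon budgets, PSF/iteration-level
localization, drift, or multi-colour channels. Generation starts at the
"valid localization" level, so passing tests demonstrate the correctness
of the *analysis*, not robustness to upstream acquisition pathologies.

The functional generators produce exactly the forms their fits assume
(square pressure pulses with Boltzmann peak amplitudes plus peak-level
noise, single exponentials plus sample noise, two-level channel traces
with per-sample independent openings, logistic dose responses with
cell-level noise); they validate parameter recovery, not model adequacy on
real recordings. The toy pose ensembles place single-atom residues 20 Å
apart and ligand atoms either ~1.5 Å from a planned residue or ≥ 15 Å from
all of them, so planned contact fractions are reproduced exactly by
construction — a construction oracle for the contact counting, not a
physical docking model.

## Selection bias of the trimer rules: a known limitation

The acceptance rules act on the *measured* geometry and therefore
truncate the recovered distribution on both sides: DBSCAN merging (ε =
8 nm) collapses trimers whose blade tips come within chaining distance,
removing the smallest interblade distances, while the 40 nm pairwise bound
rejects the widest triangles. On simulated data this is clearly visible:
with a true conformational spread of 5.5 nm, the recovered SD shrinks to
≈ 5.2 nm and the recovered means move inward — a curved-regime condition
(true mean 21.7 nm) is biased up by ≈ +0.7 nm, a flatter condition (true
mean 23.9 nm) by only ≈ +0.2 nm. A true 2.2 nm flattening shift is
consequently compressed to ≈ 1.7–1.9 nm after selection, and the
detection rate of the two-sample comparison at ~100 trimers per condition
lands near 60–70% rather than the ≈ 80% a naive power calculation at the
true shift suggests. Any study design based on these selection rules
should budget sample sizes against the *post-selection* shift, not the
conformational one. The package makes this measurable because the
generator records per-trimer ground truth.

## Numerical choices and problem sizes

Nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with data-derived
starting values (tail mean and first-sample offset for decays, the
half-response stimulus for sigmoids) and positivity bounds on time
constants and Gaussian widths; non-convergence is flagged, never silently
replaced. Degenerate inputs are first-class: flat decay traces, zero
baseline SD, unimodal amplitude histograms, singular covariances and
empty filter outputs all return flagged results instead of errors where a
flag is actionable.

The shipped tests run the full pipeline at 110 trimers per condition and
100 replicate runs for the two-condition study, 100–200 seeds for the fit
simulations, 2000 simulations for the type-I calibration, and 200 random
site sets for the geometry oracles — sizes chosen so the whole suite
finishes in a couple of minutes on a single core while keeping Monte-Carlo
standard errors well below the asserted tolerances.
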