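# piezoflux

Quantification pipeline for 3D-MINFLUX / DNA-PAINT imaging of the
mechanosensitive ion channel PIEZO1, together with the functional-assay
fits that usually accompany such a study.

PIEZO1 is a trimeric, propeller-shaped channel whose three peripheral
blades flatten when the channel activates. With an ALFA tag at the distal
end of each blade, 3D-MINFLUX localizes the three blade tips of single
channels in intact cells with nanometre precision, and the **interblade
distance** — the mean of the three pairwise blade-tip distances — becomes a
per-channel readout of flattening (curved ≈ small, flat ≈ large). Agonists
such as Yoda1 shift the interblade-distance distribution by a couple of
nanometres; resolving that shift requires a careful chain of filtering and
geometric selection, which this package implements as tested, reusable
functions:

1. **Localization filtering** (`filter_pipeline()`): cfr ≤ 0.8 and efo
   cutoffs against multi-emitter contamination; traces (TID groups) with
   any-axis SD > 10 nm or < 3 localizations removed; first 2 localizations
   trimmed; z × 0.7 refractive-index correction; per-trace centers of mass.
2. **Protomer merging** (`cluster_protomers()`): DBSCAN (ε = 8 nm,
   minPoints = 2) merges repeated DNA-PAINT binding traces on the same
   blade tip into one protomer site.
3. **Trimer identification** (`find_trimers()`): site triples with all
   pairwise distances < 40 nm, no other site within 60 nm, and maximum
   internal angle < 120°; each accepted trimer reports its interblade
   distance `(d12 + d13 + d23) / 3`.
4. **Cohort statistics** (`compare_conditions()`): condition summaries
   (mean ± SEM) and a D'Agostino–Pearson-gated choice between Student's
   unpaired t-test and Mann–Whitney U.
5. **Functional fits** (`fit_inactivation()`, `fit_boltzmann()`,
   `fit_ec50()`, `single_channel_iv()`, `detect_threshold()`, ...): the
   single-exponential inactivation constant `I(t) = C1 + C2·e^(−(t−t0)/τ)`,
   Boltzmann pressure-response P50, sigmoid dose-response EC50, unitary
   conductance from amplitude-histogram double-Gaussian fits, 6×SD
   mechanical thresholds, peak/sustained ratios and F/F0 normalization.
6. **Docking-pose contacts** (`contact_frequency()`): fraction of poses in
   which each receptor residue lies within 3.5 Å of the ligand.

Every stage has a matching synthetic generator
(`generate_minflux_dataset()`, `generate_pressure_sweeps()`,
`generate_current_decay()`, `generate_single_channel()`,
`generate_dose_response()`, `generate_toy_pose_ensemble()`) that produces
ground-truth-annotated inputs, so the whole pipeline is testable without
any microscope data.

## Worked example

Simulate a control field and an agonist-treated field of trimers, run the
pipeline and compare conditions:

```r
library(piezoflux)

cfg  <- synth_minflux_config(n_trimers = 110, interblade_mean = 21.7,
                             interblade_sd = 5.5, label_efficiency = 1,
                             seed = 42)
ctl  <- trimer_pipeline(generate_minflux_dataset(cfg)$localizations)

cfgY <- cfg; cfgY$interblade_mean <- 23.9; cfgY$seed <- 43
yoda <- trimer_pipeline(generate_minflux_dataset(cfgY)$localizations)

summarize_distances(ctl$trimers$interblade_nm)
#> n = 95, mean = 22.170 +/- 0.526 (SEM) nm, SD = 5.125 nm
summarize_distances(yoda$trimers$interblade_nm)
#> n = 96, mean = 23.988 +/- 0.571 (SEM) nm, SD = 5.591 nm
compare_conditions(ctl$trimers$interblade_nm, yoda$trimers$interblade_nm)
#> Student t test: statistic = -2.341, p = 0.02027
#> effect (mean A - mean B): -1.817 nm
#> normality gate p-values: A = 0.753, B = 0.207
```

From 110 simulated trimers per condition, 95/96 triple-labelled channels
pass the geometric rules; the recovered means sit close to the generating
means (21.7 and 23.9 nm), the normality gate passes both groups, and the
~1.8 nm flattening shift is detected by the t-test. The pipeline report
(`ctl$report`) records per-stage counts (here 6577 localizations in, 608
removed by the cfr filter, efo cutoff 246 kHz, 969 traces, 336 merged
protomer sites).

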