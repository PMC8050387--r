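# neuritor

Neurite outgrowth quantification from two-channel live-cell microscopy, for
high-content screening of neuronal differentiation.

Neuroblastoma lines such as SH-SY5Y respond to differentiation stimuli
(retinoic acid, growth-factor signalling, knockdown of negative regulators)
by extending neurites — thin projections from the cell body whose extent is
the standard morphological readout of differentiation. On a screening
microscope each field is acquired as a Hoechst-stained nuclei channel plus
a cell/neurite channel. `neuritor` segments both, reduces neurites to
measured skeletons, and compares conditions statistically:

* **Nuclei** (the per-field cell count): Gaussian smoothing, grayscale-
  opening illumination correction, Otsu threshold with a robust offset,
  hole filling, area gating in µm², watershed splitting of touching nuclei
  on a smoothed distance transform, border exclusion.
* **Neurites**: multi-scale Hessian ridge (tubeness) filter
  `R(σ) = σ²·max(−λ₁, 0)` with across-ridge non-maximum suppression to
  extract the ridge centerline, exclusion of cell bodies (nuclei dilated
  by a soma margin), Zhang–Suen skeletonization with redundant-pixel
  reduction, spur pruning, and a minimum component length.
* **Length** of a unit-width skeleton: Σ over unique 8-adjacent pixel
  pairs of 1 (orthogonal) / √2 (diagonal) steps × pixel size (µm).
* **Per-field metrics**: nuclei count, total and per-cell neurite length,
  component and branch-point counts, neurite-positive cell fraction
  (assigned length ≥ 20 µm by default).
* **Statistics**: per-condition median with seeded percentile-bootstrap
  95% CI; Welch (or pooled) two-sample t test, one-way ANOVA with
  Bonferroni-corrected vs-control comparisons; star map
  p < 0.05/0.01/0.001/0.0001 → \*/\*\*/\*\*\*/\*\*\*\*.
* **Synthetic fields with analytic ground truth**: nuclei as blurred
  ellipses, somata as discs, neurites as constant-width strokes along
  bounded-curvature circular-arc chains (arc length exact by
  construction), Poisson + Gaussian noise calibrated to a requested SNR.
  Every stage of the package is validated against this generator.

## Worked example

```r
library(neuritor)

sp  <- synthetic_spec(field_shape = c(384L, 384L), n_nuclei = 15,
                      n_neurites = 8, neurite_length_um = c(40, 100),
                      snr = 6, seed = 42)
g   <- generate_field(sp)
nuc <- segment_nuclei(g$field$nuclei_channel, pixel_size_um = 0.65)
sk  <- segment_neurites(g$field, nuc)
quantify_field(nuc, sk, field_id = "demo", condition = "siCtrl")
#> <field_metrics> demo [siCtrl]: 15 nuclei, 465.6 um neurite (31 um/cell)

g$truth$total_length_outside_um   # generator ground truth
#> [1] 485.03
```

All 15 nuclei are recovered and the measured 465.6 µm of skeleton is within
4% of the 485 µm of true arc length outside the cell bodies.

A two-condition screen end to end — simulate, segment, quantify, compare:

```r
sp   <- synthetic_spec(field_shape = c(256L, 256L), n_nuclei = 8,
                       n_neurites = 4, neurite_length_um = c(30, 60), snr = 6)
long <- sp; long$neurite_length_um <- c(60, 120)
exp <- generate_experiment(list(siGFP = list(spec = sp,  n_fields = 8),
                                siCbl = list(spec = long, n_fields = 8)),
                           "exp", master_seed = 7)

cfg <- default_config()
cfg$stats$control <- "siGFP"
out <- run_pipeline(exp$manifest_path, cfg, "out")
out$comparison
#>                       metric group n median ci_lo ci_hi         test statistic    df       p stars
#> 1 neurite_length_per_cell_um siGFP 8  17.43 15.63 18.16         <NA>        NA    NA      NA  <NA>
#> 2 neurite_length_per_cell_um siCbl 8  39.37 35.59 42.07 two_sample_t     18.07 9.647 9.3e-09  ****
```

The doubled generator neurite length shows up as a doubled per-cell median
and a four-star Welch t test against the control. `out/` also contains
`metrics.csv` (one row per field), per-field overlays on request
(neurites white, nuclei cyan over the grayscale cell channel),
`config_resolved.yaml` and a run log.

The same pipeline runs from a shell via the bundled CLI:

```sh
Rscript inst/cli/neuritor.R simulate --out exp --n-fields 8
Rscript inst/cli/neuritor.R run --manifest exp/manifest.csv --out results --overlays
Rscript inst/cli/neuritor.R compare --metrics results/metrics.csv --control control --out cmp.csv
```

For real data, point a manifest CSV (`file`, `field_id`, `condition`,
optional `pixel_size_um`, `nuclei_page`, `cell_page`) at your two-page
grayscale TIFFs and call `run_pipeline()` — see `?read_manifest`.

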