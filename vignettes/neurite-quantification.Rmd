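---
title: "Quantifying neurite outgrowth from two-channel live-cell fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurite outgrowth from two-channel live-cell fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Neurite outgrowth — the extension of thin cellular projections from a
neuronal or neuroblastoma cell body — is a standard morphological marker of
differentiation. In a high-content screening setting, an automated
microscope collects many fields per condition; each field carries a
Hoechst-stained nuclei channel (the per-field cell count) and a cell
channel from which neurites must be segmented. `neuritor` turns such a pair
of channels into per-field morphometrics (nuclei count, total and per-cell
neurite length, neurite-positive cell fraction) and compares conditions the
way differentiation screens are usually reported: medians with bootstrap
confidence intervals, t tests, and one-way ANOVA with per-condition
comparisons against a control.

Because public image sets for this assay are not generally available, the
package ships a synthetic field generator with *analytic* ground truth.
Every stage of the pipeline is validated against it, and the package's
acceptance checks regenerate those validations from scratch.

```{r, eval = FALSE}
library(neuritor)

sp <- synthetic_spec(field_shape = c(384L, 384L), n_nuclei = 15,
                     n_neurites = 8, snr = 6, seed = 1)
g   <- generate_field(sp)
nuc <- segment_nuclei(g$field$nuclei_channel, pixel_size_um = 0.65)
sk  <- segment_neurites(g$field, nuc)
quantify_field(nuc, sk, field_id = g$field$field_id)
```

## Nuclei segmentation

The nuclei channel is processed as: Gaussian smoothing → illumination
correction → global threshold → hole filling → area gating → watershed
splitting → border exclusion → relabeling. The design choices that matter:

* **Illumination correction** subtracts a grayscale-opening background
  estimate (disc radius `background_radius_px`, default 25 px, which must
  exceed the nucleus radius). Opening is positively homogeneous, so the
  correction is exact under any positive rescaling of the intensities —
  this, together with expressing the threshold offset in robust MAD units,
  makes counts invariant to affine intensity changes (`a·I + b`, `a > 0`),
  a property the test suite asserts.
* **Smoothing sigma** defaults to 1.5 px. Heavier smoothing (2 px and up)
  visibly rounds off the waist between touching nuclei; the
  distance-transform saddle between the two lobes then disappears and the
  watershed cannot separate them. 1.5 px still suppresses shot noise at
  the signal-to-noise ratios this assay produces (SNR ≥ 5).
* **Thresholding** is Otsu on the corrected, max-normalized channel with an
  additive offset in units of the channel's median absolute deviation. A
  floor of `median + 3·MAD` guards the degenerate case of a field with no
  real foreground at all, where Otsu would otherwise bisect the noise and
  the watershed would cut the resulting continent into plausible-sized
  pieces: such fields correctly report zero nuclei.
* **Area gating** runs in two stages around the watershed: the minimum-area
  gate (default 30 µm²) runs first so debris does not seed basins, and the
  maximum-area gate (default 500 µm²) runs *after* splitting — a fused
  pair of nuclei exceeds the maximum and would be deleted before it could
  be split if the gates both ran first.
* **Watershed splitting** runs on the Euclidean distance transform of the
  mask, lightly smoothed (Gaussian sigma 0.7 px, re-zeroed outside the
  mask) so that boundary roughness does not seed spurious basins, with a
  basin-depth tolerance of 0.25 px. On synthetic fields this combination
  counts well-separated nuclei exactly while separating ≥ 94% of fused
  pairs up to 30% overlap of the radius sum. A higher tolerance trades
  splitting power for robustness; both knobs are exposed in
  [nuclei_params()].
* Nuclei touching the field border are excluded by default (partial nuclei
  bias both counts and areas); labeling is 8-connected throughout.

## Neurite segmentation

Neurites are thin (2–5 px at 10×), curvilinear, and much dimmer than cell
bodies, so the pipeline is built around a multi-scale Hessian ridge
("tubeness") filter rather than plain intensity thresholding:

1. **Ridge response.** At each scale σ the channel is convolved with
   Gaussian-derivative kernels to form the Hessian; the response is
   `σ²·max(−λ₁, 0)` with λ₁ the more negative eigenvalue, maximal across a
   bright ridge of width ≈ 2σ. Responses are combined across scales by a
   per-pixel maximum. Default scales are `c(1.5, 2.5)` px, matched to
   neurites a few pixels wide: scale 1 amplifies single-pixel noise and
   scales ≥ 4 respond strongly to soma rims, so the spread-out default of
   1–4 px costs far more than it buys on this structure size. The channel
   is max-normalized first, making the response scale-free.
2. **Centerline extraction.** The response is *not* thresholded into a
   band. The tubeness response of a line is a ridge with substantial
   flanks; any band threshold low enough to keep dim neurites keeps the
   flanks too, and the resulting two-rail mask skeletonizes into a braid
   that overcounts length by 50–90%. Instead the pipeline keeps only
   pixels that are local maxima of the response *across* the ridge (along
   the eigenvector of λ₁, quantized to the four grid directions) — the
   classic ridge-line extraction — and above a noise floor of
   `median + k·MAD` of the response (`response_threshold`, default k = 8)
   with a small signal-relative floor (25% of the field's peak response)
   for very clean fields where the MAD floor collapses.
3. **Soma exclusion.** Nucleus labels dilated by `soma_dilation_um`
   (default 8 µm) are removed from the mask, so only projections outside
   cell bodies are measured. The margin is measured from the *nucleus*
   boundary and must reach past the soma edge plus the ridge response's
   spread at the soma rim; with ~7 µm somata around 4–7 µm nuclei, 5 µm
   would leave each cell's rim crest in the mask as a spurious ~40 µm
   "ring neurite".
4. **Skeletonization** (Zhang–Suen thinning) plus two reduction passes: a
   simple-point cleanup of any fully set 2×2 block, and removal of
   redundant pixels whose neighbours are mutually 8-connected. The second
   pass matters for correctness of the length measure: parallel thinning
   provably never deletes "staircase double" pixels (their crossing number
   is 2), and each such pixel adds a spurious triangle of adjacencies that
   the pair-counting length convention would count.
5. **Pruning and filtering.** Terminal spurs shorter than
   `prune_spur_length_um` (default 5 µm) are walked back from each
   endpoint and deleted; whole components that are simple paths are never
   pruned. Components shorter than `min_component_length_um` (default
   10 µm) are dropped — this is also what removes isolated noise crests
   that survive the response floor.

**Length convention.** The length of a unit-width skeleton is the sum over
unique 8-adjacent pixel pairs of 1 (orthogonal) or √2 (diagonal) steps,
times the pixel size. No corner-cut or perimeter corrections are applied.
The convention is exact for axis-aligned and 45° lines and overestimates
intermediate orientations by up to ~8%; in practice this is largely offset
by the ~half-width erosion of the skeleton at each neurite end, and the
measured median absolute error on curved synthetic neurites is ~3%.
Crossing neurites are not disentangled — they merge into one component,
which is counted once (lengths still sum correctly; component counts do
not).

## Per-field metrics and statistics

Each skeleton component is assigned to the nucleus whose centroid is
nearest to the component's closest pixel (ties to the lower label), giving
per-cell neurite lengths that exactly partition the total. A cell is
*neurite-positive* when its assigned length reaches
`min_neurite_length_um` (default 20 µm, about one to two SH-SY5Y soma
diameters; the literature does not fix this threshold, so it is exposed
and echoed in every output). Fields with zero nuclei get `NA` per-cell
metrics and are flagged excluded rather than imputed. The statistical unit
is the field, matching per-image quantification on a screening microscope.

Condition-level comparison reports, per group, the median with a seeded
percentile-bootstrap 95% CI (B = 10,000 by default), and tests group
differences with a Welch two-sample t test (two groups; the pooled variant
is a flag) or one-way ANOVA (more groups) with each-treatment-vs-control t
statistics on the pooled within-group mean square, Bonferroni-corrected;
raw and corrected p values are both reported, and stars follow the
conventional map (p < 0.05/0.01/0.001/0.0001 → \*/\*\*/\*\*\*/\*\*\*\*).
Calibration is checked by simulation: null rejection rates of both tests
at α = 0.05 fall in [0.04, 0.06] over 5,000 replicates, and bootstrap CI
coverage of a standard-normal median is within [0.93, 0.97] over 1,000
replicates.

## The synthetic generator

`generate_field()` renders what the segmentation stages assume and records
what they should recover:

* **Nuclei** are Gaussian-blurred ellipses (semi-major 4–7 µm, axis ratio
  0.75–1 by default; circles on request, which is what the touching-nuclei
  validation uses so that "percent overlap" is well defined). Placement is
  rejection sampling under a pairwise overlap constraint.
* **Somata** are blurred discs (default 7 µm) at every nucleus.
* **Neurites** leave a soma boundary and follow chains of circular arcs
  with bounded curvature (default ≤ 0.05 rad/µm, i.e. bending radius
  ≥ 20 µm), so the true arc length is *analytic*, not estimated; a dense
  polyline integration agrees to < 0.1% and is asserted in the tests. The
  ground truth records both the full arc length and the part outside the
  soma exclusion zone; recovery is judged against the latter because the
  tool by definition measures only projections outside cell bodies. Paths
  that would leave the field or re-enter any cell's exclusion zone are
  resampled (bounded retries, then an error naming the constraint).
* **Noise** is Poisson shot noise on the signal plus Gaussian read noise
  (SD 2 counts). The signal amplitude is calibrated by solving
  `x² = snr²·(background + x + σ_read²)` so that
  (peak − background)/SD-at-peak equals the requested SNR exactly; the
  realized SNR of generated fields is within 10% of the request.
* Per-field seeds are derived deterministically from a master seed, so an
  experiment of any size reproduces byte-for-byte.

What the generator does *not* emulate: phase-contrast or transmitted-light
texture, uneven illumination (the pipeline corrects it, but the generator
does not produce it), varying neurite brightness along a shaft, fasciculed
or branching neurites (crossings occur, branches are not generated), focus
drift and photobleaching. Passing the synthetic validations therefore
demonstrates the geometry and calibration of the measurement chain, not
robustness to every real-world artefact; on real data the exposed
thresholds (`response_threshold`, `soma_dilation_um`, area gates) are the
knobs to revisit, and both ridge polarities are supported because
live-cell contrast may be either sign.

## Validation scale

The shipped validations run on 320–400 px fields at 0.65 µm/px: 100 fields
for nuclei counting (10–40 nuclei each), 50 for pair splitting, 50
single-neurite and 50 multi-neurite fields for length recovery, a 2 × 25
field two-condition screen, and 5,000/1,000 replicate calibration runs for
the tests and the bootstrap. These sizes give stable rates while keeping
the whole validation suite to a few minutes on one CPU; the same code
paths run unchanged at larger field counts.

## Known limitations

* Crossing neurites form one component; the neurite-positive fraction can
  therefore undercount contributing cells in dense fields.
* Component-to-cell assignment is by nearest nucleus centroid, not by
  tracing connectivity through the soma; in very dense cultures a neurite
  passing close to a foreign nucleus can be misassigned.
* The length convention's orientation bias (bounded at ~8%, typically ~3%
  after end erosion) is inherent to unweighted 8-connected chain codes;
  applying a corner-count correction would change every reported length
  and is deliberately not done.
* Nuclei splitting assumes roughly convex nuclei; chains of three or more
  mutually fused nuclei are outside the validated regime.
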