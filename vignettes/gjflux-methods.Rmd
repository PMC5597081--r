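---
title: "Methods: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gjflux re-implements, as a tested package, the quantification stack used in
high-content studies of gap-junction (connexin 43, Cx43) trafficking:
2D puncta localization with subcellular compartment fractions, 3D plaque
volumetry, fly-CNS tract densitometry, flow-cytometry recycling
normalizations, proteasome kinetics, and evoked-response latency extraction.
Because no raw assay data is shipped, every stage is validated against a
synthetic-data generator whose ground truth is exact by construction.  This
vignette records the models, the tunable parameters that matter, the
numerical choices, and what a green test does and does not establish.

## The 2D high-content model

A field of view is a set of registered channels (`DNA`, `CX43`, `ITGA3`,
`EEA1`, `LAMP1`, optional `GFP`).  The pipeline is:

1. **Illumination correction.** Each channel is divided by a smooth,
   mean-normalized gain estimate.  The classic estimate is a 200 x 200 px
   median filter of the plate-averaged image (`compute_gain_field(stat =
   "median")`), evaluated exactly on a 16-px grid and bilinearly
   interpolated — indistinguishable from the dense filter for smooth bias.
   At this package's simulation scale (hundreds of punctae in a ~0.3 Mpx
   field), diffraction spots cover a large fraction of the field, and the
   plain window median tracks local object density rather than
   illumination.  The pipeline wrapper therefore uses `stat = "background"`:
   the window median of pixels below a global object cutoff
   (median + 10% of the robust dynamic range).  This masked median is
   nearly linear in the local photon rate, so the multiplicative bias is
   recovered to a few percent from a single field; the median default is
   kept for plate-scale data where it is the standard.
2. **Nuclei.** Otsu threshold on the DNA channel, hole filling, a
   distance-transform watershed that splits touching nuclei (markers are
   plateau-merged distance maxima), then an equivalent-circle diameter gate
   of 20-60 px and a solidity (circularity) gate of 0.8.
3. **Cells.** Every above-threshold pixel of the cell-body channel is
   assigned to the geodesically nearest nucleus by multi-source flooding,
   so cells partition the foreground and cell labels biject with nucleus
   labels.  The default threshold is the lower cut of a three-class Otsu:
   with background, cytoplasm, and a bright membrane rim present, two-class
   Otsu can lock onto the cytoplasm/rim split instead of the
   background/cell split, which multilevel Otsu avoids.
4. **Punctae.** Connected components above threshold inside the cell mask,
   gated at 8-20 px equivalent diameter, each assigned to the cell holding
   its centroid.  The default threshold (`"halfmax"`) places the object
   boundary at half the robust peak amplitude — the convention under which
   the measured diameter of a diffraction-limited Gaussian spot equals its
   FWHM.  All size gates carry a half-pixel allowance on both sides because
   object diameters are only defined to the pixel.
5. **Surface and compartments.** The ITGA3 surface mask is the upper cut of
   the three-class Otsu (the bright rim).  A Cx43 puncta is `surface` if
   any of its pixels intersect that mask, `EE`/`LYS` if they intersect a
   retained EEA1/LAMP1 puncta (colocalization = at least one shared pixel;
   a centroid-containment mode is available).  Multi-hit punctae resolve
   with priority surface > early endosome > lysosome — the protocol reports
   mutually exclusive fractions without stating a tie rule, so the rule is
   explicit here; unmatched punctae are `other` and excluded before the
   three-way fraction is normalized to exactly 100%.
6. **Aggregation.** Unweighted means, sites to well and wells to condition,
   carrying n at each level.  For unbalanced designs this hierarchical mean
   deliberately differs from the pooled mean.

Tract densitometry follows the ImageJ conventions: sum-slices projection,
per-ROI area and mean grey value (MGV), integrated density = area x MGV
(exact by definition), and an area-weighted mean MGV over the two bilateral
tracts.  ROI polygons use half-open pixel-center semantics so adjacent ROIs
never double-count a pixel.

## The synthetic monolayer: the stated world

`make_monolayer()` renders `n_cells` (default 20) cells on a jittered grid
(a near-confluent epithelium; cells cover roughly 85-90% of the field,
leaving enough true background for a bimodal foreground threshold).  Cells
are Voronoi regions clipped to disks; nuclei are hard disks; the membrane
rim is the 3-px inner band of each cell, co-rendered bright into ITGA3.
Each cell carries exactly `punctae_per_cell` (default 10) punctae whose
compartments are a single multinomial draw over the requested fractions
(default 60/25/15).  Surface punctae sit on the rim at cell-cell interfaces
(where gap junctions live); EE/LYS punctae are co-rendered at identical
positions into EEA1/LAMP1 so object-level colocalization is exactly
recoverable.  Illumination bias is a random quadratic polynomial scaled to
the requested amplitude (default 20%) and mean-normalized; noise is Poisson
shot noise (200 photons per intensity unit) plus Gaussian read noise
(sd 0.01) — the standard epifluorescence camera model.

Two choices deserve justification:

* **Size distributions.** The printed 20-60 px (nuclei) and 8-20 px
  (punctae) ranges are *detection filters*.  Sampling object sizes
  uniformly across a filter band would place a material fraction of objects
  within measurement noise of a gate boundary, making "exact count"
  invariants impossible for any detector — a discretization fact, not a
  detector defect.  Sizes are therefore drawn from truncated normals
  centred in the band (mean = midpoint, sd = width/8: nuclei ~N(40, 5),
  punctae ~N(14, 1.5)), emulating a homogeneous cell line and
  diffraction-limited spots whose filter brackets the population.  The
  printed ranges remain the *gate* defaults.
* **Resolvability.** Punctae are placed with pairwise centre separation of
  at least 0.75 x the summed diameters, the distance at which two summed
  Gaussian tails stay below half-maximum at the midpoint.  The generator
  thus states a world of *resolvable* punctae; it does not emulate clumped
  or overlapping spots, out-of-focus blur, or marker decoys
  (EEA1/LAMP1-positive objects without Cx43).  A green recovery test
  establishes detector correctness on resolvable spots over realistic
  noise and illumination bias — nothing more.

The monolayer is inset 14 px from the field border and puncta centres keep
0.6 x diameter clear of the image edge: an edge-clipped object has no
recoverable size by construction, so the stated world contains none (real
pipelines handle the same problem by discarding border-touching objects).
The generator rejects impossible packings explicitly (too many cells for
the field, or punctae that cannot be placed without violating
resolvability — placement retries randomized orders and falls back to
exact feasibility sets before giving up) instead of silently truncating.

## 3D plaques

Plaques are 3D connected components (26-connectivity by default; the
original acquisition software's connectivity is unstated, so it is
configurable) above an intensity threshold, with volume = voxel count x
physical voxel volume — anisotropic voxels (0.4 um slice steps) are handled
by physical volume, never by resampling.  The 5-100 um^3 gate is inclusive
at both bounds ("within a range" read inclusively).  Rendered spheres
recover their analytic volume within one voxel shell; interface colabeling
flags a plaque when any voxel is marker-positive.

## Cytometry normalization chains

Population summaries are geometric means, `exp(mean(log x))`; non-positive
events are dropped with a warning count because the log is undefined.
Efflux: each condition's intracellular-label geometric mean is divided by
its own saturated t = 0 level (after the 45-min uptake), then all
conditions are divided by the reference condition's value at the 7.5-min
anchor and scaled to percent — so the reference passes through exactly
100% at 7.5 min by construction.  Receptor ratio: isotype backgrounds are
*subtracted* before the surface/total quotient (the protocol says isotypes
"determine background" without the arithmetic; subtraction is the choice
here, logged and configurable); a non-positive denominator is treated as
failed staining and is an error.  Uptake is divided by the ratio and
referenced to control, making it invariant to joint instrument-gain
rescaling.  FCS binary parsing is out of scope; events arrive as CSV.

## Traces and kinetics

The latency of an evoked response is measured from the beginning of the
stimulation artifact to the beginning of the EPSP.  The artifact onset is
the first sample whose |dV/dt| exceeds half the window's peak slope; after
0.2 ms of blanking, the EPSP onset is coarsely the first sample above
baseline mean + 3 SD holding for 5 samples — the protocol specifies only
"the beginning of the EPSP", so the criterion is explicit and configurable
— and is then refined to sub-sample precision by least squares against a
flat-then-exponential-rise model (grid over onset and rise constant,
continuous refinement of the onset).  Refinement matters: a pure threshold
crossing carries a systematic delay of order the rise constant divided by
the SNR, which would dominate at the one-sample-period accuracy the
validation demands.  Failures (no onset within the response window) are
flagged, excluded from the latency mean, and surfaced as a response
probability.

What accuracy is attainable depends on trace quality.  A Cramer-Rao bound
for the onset of an exponential rise gives sd(t0) ≈ (σ/A)·sqrt(2·tau/fs):
at 40 kHz with a 0.5-ms rise, one-sample (0.025 ms) *absolute* accuracy
requires SNR ≳ 10, and is out of reach for any estimator at SNR = 5 (where
the bound alone is ~1.5 samples before parameter-covariance inflation).
The validation therefore checks mean-absolute error < 1 sample at the
generator's realistic default quality (15 mV EPSPs over 0.5 mV noise,
SNR 30 — intracellular muscle recordings are high-SNR), and separately
checks *unbiasedness* (|mean signed error| < 1 sample over 100 seeds) down
to SNR 5, which averaging makes well-posed.  Response frequency counts upward crossings of a robust
median + k MAD criterion with a 20-ms refractory separation, divided by
the window (default 5 s).  Proteasome activity is the OLS slope of AMC
fluorescence against time (16 points at 2-min steps by default), with the
closed-form standard error.

## Statistical layer

The age x genotype interaction is tested by type-II sums of squares (model
comparison of additive vs interaction fits; the original software's SS
convention is unstated, so the choice is documented) — identical to the
classical decomposition for balanced designs.  Post hoc comparisons:
Tukey-Kramer via the studentized range with unequal-n standard errors, and
Dunnett many-to-one adjusted p-values computed by direct numerical
integration of the multivariate-t probability (Simpson quadrature over the
control variate and the pooled-SD scale), validated against the k = 1
reduction to a plain t-test and by familywise-error simulation.  Normality
uses the Lilliefors KS statistic with the Dallal-Wilkinson approximation
for the corrected p (flagged as an approximation in the output).  No
multiplicity control beyond the named procedures is added.  All outputs
report mean +/- SEM with stars at *P < 0.05, **P < 0.01, ***P < 0.001.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col) with pixel centres on integer
  coordinates; ROI polygons are half-open.
* Empty DNA channel → empty mask (not an error); a nucleus outside the
  cell foreground degenerates to a nucleus-sized cell with a message;
  empty puncta sets and empty plaque sets are valid results.
* Gates: inclusive bounds; image gates carry the half-pixel quantization
  allowance described above; the 3D volume gate is applied to physical
  volumes.
* Determinism: every generator takes a seed and restores the caller's RNG
  state; identical seeds give bit-identical outputs.
* One validation tolerance was re-derived rather than copied: a +/-5% band
  on an empirical variance estimated from 500 Monte-Carlo draws is
  narrower than that estimate's own sampling error (sd ≈ sqrt(2/499) ≈
  6.3%), so the kinetics acceptance test checks (a) the estimator's
  closed-form variance against the oracle within 5% (well-posed at 500
  seeds) and (b) the empirical variance inside the central 99.9%
  chi-square band around the oracle.

## Known limitations

* The generator's realism gaps listed above (no clumping, no decoy
  markers, no chromatic shift, hard-edged nuclei).
* Field persistence is plain text (one matrix per channel plus JSON
  metadata and a truth CSV); no TIFF/OME-TIFF reader or writer is bundled
  because the target environment provides none.
* The Dunnett integration is accurate to ~1e-4 in p, ample for starring
  but not for extreme tail probabilities.
* The fly-CNS densitometry quantifies user-supplied ROI polygons; it does
  not find tracts automatically.
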