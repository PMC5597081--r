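# gjflux

Quantification stack for gap-junction trafficking assays, built for
scientists who need the *measurement* layer of a high-content trafficking
study to be reproducible and testable: where do connexin 43 (Cx43) punctae
sit in the cell (surface vs early endosome vs lysosome), how large are 3D
gap-junction plaques, how fast does a fly's escape circuit respond, how
quickly is internalized transferrin recycled, and are the differences
statistically supported.

Every analysis stage is paired with a synthetic-data generator that knows
its own ground truth, so the whole pipeline is validated end to end without
any external download.

## What it computes

**2D high-content imaging** (epithelial monolayers, channels DNA / CX43 /
ITGA3 / EEA1 / LAMP1 / GFP):

- illumination (flat-field) estimation — 200 x 200 px plate median filter,
  plus a robust masked-median background variant — and correction by
  division;
- nuclei by Otsu + distance-transform watershed, gated to 20-60 px
  equivalent diameter and circular shape; cells by seeded geodesic
  propagation from nuclei (one cell per nucleus, always);
- punctae as connected components gated to 8-20 px equivalent diameter,
  assigned to cells, split by GFP transfection where present;
- compartment fractions: a puncta is **surface** if it intersects the
  ITGA3-labelled rim mask, **early endosome** / **lysosome** if it shares
  pixels with an EEA1 / LAMP1 puncta; the three-way fraction is normalized
  to exactly 100% (multi-hits resolve surface-first);
- hierarchical aggregation, sites → wells → conditions, with n and SEM;
- fly-CNS tract densitometry: sum-slices projection, per-ROI area, mean
  grey value (MGV), integrated density = area x MGV, and the area-weighted
  mean MGV over both bilateral tracts.

**3D plaques**: 26-connected components in confocal z-stacks (0.4 um slice
steps), physical volumes, the inclusive 5-100 um^3 gate, per-plaque mean
signal and cell-cell-interface colabeling flags.

**Cytometry**: geometric means; transferrin efflux normalized per condition
to the saturated t = 0 level and anchored to the reference condition at
7.5 min (= 100% by construction); surface/total receptor ratio with isotype
background subtraction; ratio-normalized uptake.

**Electrophysiology & kinetics**: response latency from stimulation
artifact onset to EPSP onset with sub-sample refinement, response
probability, air-puff response frequency over 5 s windows, and proteasome
activity as the OLS slope of AMC accumulation (R^2 and SE included).

**Statistics**: two-way (age x genotype) interaction ANOVA (type-II SS),
one-way ANOVA post hocs (Tukey-Kramer; Dunnett vs a named control, computed
by direct multivariate-t integration), Lilliefors/Dallal-Wilkinson
normality check, mean ± SEM reporting with significance stars.

## Worked example

```r
library(gjflux)

# a synthetic monolayer: 20 cells, 10 punctae/cell, truth fractions
# 60/25/15, 20% illumination bias, Poisson-Gaussian noise
field <- make_monolayer(monolayer_params(seed = 1))
table(field$truth$puncta$compartment)
#>      EE     LYS surface
#>      41      32     127

q <- quantify_field(field$images)
q$n_cells
#> [1] 20
q$n_punctae
#> [1] 200
q$fractions
#> <compartment fractions> surface 63.5% | early endosome 20.5% | lysosome 16.0% (n=200 classified of 200)
```

All 20 cells and all 200 punctae are recovered, and the measured
surface / early-endosome / lysosome percentages (63.5 / 20.5 / 16.0) equal
the realized truth of this seed exactly (127/41/32 punctae). The same field
carries a 20% smooth gain field; counts are identical with and without it
after flat-field correction.

```r
# 3D volume gate: only the 50 um^3 plaque survives the 5-100 um^3 gate
z <- make_zstack(c(4, 50, 120), seed = 1)
detect_plaques(z$volume)$volume_um3
#> [1] 49.872

# response latency, artifact -> EPSP onset
tr <- make_trace(trace_params(true_latency_ms = 0.8, seed = 1))
detect_latency(tr)$mean_latency_ms
#> [1] 0.7962057

# proteasome activity: slope of AMC accumulation
proteasome_slope(make_kinetic_series(5, 3, noise_sd = 0.5, seed = 1))
#> <kinetic fit> slope 2.998 a.u./min (se 0.0138, R^2 0.9997, n=16)
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/gjflux.R", package="gjflux"))') \
    simulate monolayer --seed 1 --out field/
# ... quantify-2d --field field/ --out results/
# ... ephys latency --trace trace.csv --stim 10
# ... cytometry efflux --events events.csv --reference elevated
```

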