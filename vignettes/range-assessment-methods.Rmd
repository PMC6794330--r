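---
title: "Range metrics, ensemble suitability models and criterion-B screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range metrics, ensemble suitability models and criterion-B screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangeprofile)
```

## The problem

Red List assessments under IUCN criterion B hinge on two range statistics:
the **extent of occurrence** (EOO), the area of the minimum convex polygon
enclosing all known or inferred occurrences, and the **area of occupancy**
(AOO), the summed area of occupied cells of a 2 × 2 km reference grid.
Criterion B flags a species as potentially threatened when EOO < 20,000 km²
(B1) or AOO < 2,000 km² (B2); at the other end, a species with EOO >
20,000 km² *and* AOO > 2,000 km² is conventionally called widespread.
Species with fewer than five georeferenced records are treated as too
poorly known to quantify at all (Data Deficient).

`rangeprofile` implements both routes by which those statistics are
obtained in practice:

1. **Observed basis** — for species whose full range is credibly known
   (the canonical case being cave-restricted troglobionts in
   well-explored karst systems), EOO and AOO are computed directly from
   the occurrence points.
2. **Modelled basis** — for epigean species with at least five records,
   an ensemble of presence–background suitability models interpolates the
   range, with positional uncertainty of the records propagated through
   the ensemble, and the range statistics are read off consensus and
   confidence-limit maps.

## Geometry

All areas are computed on a cylindrical equal-area projection of the
authalic sphere (R = 6,371,007.2 m, standard parallel 0°): `x = Rλ`,
`y = R sin φ`. An equal-area plane is the only requirement the range
statistics impose, and this projection is trivially invertible, which the
simulator uses heavily. No coordinate reference system is imposed on the
inputs beyond WGS84 longitude/latitude.

EOO uses the convex hull of the projected points (shoelace area).
Configurations that are degenerate — fewer than three distinct points, or
collinear within an area tolerance of 10⁻⁶ km² — report EOO = 0. We do
not silently replace a degenerate EOO by AOO (one common convention);
the criteria engine receives both numbers and callers can apply whichever
convention their workflow requires.

AOO counts distinct occupied cells of a `cell_km` grid (default 2 km)
anchored at the projected origin. The anchor is arbitrary in principle;
it is exposed as a parameter (`origin_x_m`, `origin_y_m`) so the
sensitivity of AOO to grid placement can be measured rather than assumed.

## The ensemble model

The modelled path runs `R = 100` replicate fits. Each run:

1. **jitters** every record independently — direction uniform on
   [0, 2π), distance uniform on [0, *u*] where *u* is the record's
   positional error radius in km — so the ensemble spread reflects
   georeferencing uncertainty rather than model instability alone;
2. **thins** the jittered records to one presence per environmental cell;
3. draws a fresh **background** sample of valid cells (uniform, without
   replacement; default `min(1000, valid cells)`);
4. fits a **ridge-penalized logistic regression** of presence against
   background on standardized linear + quadratic terms of *every* layer
   (no variable subsets), with an unpenalized intercept and default
   penalty λ = 1.0 on the standardized scale;
5. **binarizes** the predicted map at the threshold maximizing
   sensitivity + specificity (Youden's index) over the observed scores,
   breaking ties toward the lowest threshold — the larger, precautionary
   range;
6. scores itself by its **training AUC** (rank-sum with half credit for
   ties).

Runs are combined with weights

> weight = max(0, AUC − 0.5)²

so chance-level runs are discarded entirely and weight grows
quadratically to 0.25 at AUC = 1. The per-cell weighted vote share (the
*score map*) is cut at 0.5 for the **consensus** range, 0.975 for the
**lower confidence limit** and 0.025 for the upper one; the three maps
are nested by construction. If every run has AUC ≤ 0.5 the ensemble is
uninformative and the run aborts with an explicit error rather than
returning an arbitrary map.

Design notes, with reasons:

- *The logistic surrogate.* The model interface is deliberately minimal
  (standardize, fit, predict in [0, 1]) so that other presence–background
  learners can be slotted in. A penalized logistic fit was chosen as the
  default because it is deterministic, convex, dependency-free and
  transparent to test; its linear + quadratic features express the
  unimodal responses that matter at this scale. Hinge/product feature
  classes of full maximum-entropy implementations are intentionally out
  of scope.
- *Training AUC.* With 5–20 presences, held-out validation splits are
  degenerate and cross-validated AUC estimates have enormous variance;
  the weighting therefore uses training AUC, documented as a deliberate
  choice. Its optimism is shared across runs, and the weight law mainly
  needs the *ordering* of runs to be right.
- *Binarization.* No single binarization rule is canonical; Youden's
  index is symmetric in the two error rates and needs no prevalence
  assumption, and the low tie-break keeps the range large when the data
  cannot distinguish candidates.
- *Determinism.* Every run seeds its own RNG stream as `seed + run`, so
  a whole ensemble is a pure function of (records, layers, parameters,
  seed) and any single run can be replayed for inspection.
- *Missing uncertainties.* A record with no stated error radius uses half
  the environmental cell edge — the positional information content of
  "somewhere in this cell".

## Patch restriction

Predicted-suitable area that is disconnected from every known population
should not count toward the range of a low-dispersal species. After
thresholding, maps are restricted to connected patches (8-connectivity by
default; diagonal contact counts as contiguous, and 4-connectivity is
available) that contain at least one observation cell. Observation cells
are forced suitable first, so an observation sitting just outside the
predicted range keeps its patch — or survives as an isolated cell — and
the restriction never deletes ground truth. The operation is idempotent.

Assessment then uses the **lower confidence limit** of the restricted
maps, the precautionary choice; consensus values are reported alongside.

## The packaged profiles

The package ships 43 encoded species conservation profiles of spiders
endemic to mainland Portugal (42 printed assessments plus a minimal entry
for the previously assessed cave species *Anapistula ataecina*). Each
profile records family, record count, the basis of its range values
(observed / modelled / unknown), lower-CL and consensus EOO and AOO where
quantified, population and range trends, IUCN habitat codes and a
troglobiont flag. `tally()` reproduces the collection's aggregate
statistics (trend split 9 declining / 11 stable / 23 unknown, 15
families, habitat and exclusivity counts, and the widespread/threatened
split of the 14 modelled species on their lower confidence limits).

Two encoding decisions deserve notice:

- *Trend fallback.* A species' trend is its population trend when stated,
  else its range trend. Exactly one profile (*Macrothele calpeiana*,
  stable range trend, unestimated population) depends on the fallback,
  and the published trend totals are reproduced only with it.
- *Basis corrections.* Two printed basis labels contradict their own
  profiles: *Adonea algarvensis* is labelled "Unknown" yet carries
  modelled range intervals and a narrative describing the modelling,
  while *Zodarion algarvense* is labelled as modelled yet has three
  records, no range values and a narrative stating modelling was not
  possible. The labels appear swapped; the fixture encodes the basis
  implied by the values and narratives, which is also the only encoding
  consistent with the published aggregate counts (14 modelled, 18
  quantified, 8 widespread, 6 threatened). The fixture's `notes` field
  documents this.

Per-species *modelled* EOO/AOO intervals in the profiles originate from
an analysis over real climate layers, the original occurrence records
and a different model implementation. They are carried as encoded data;
this package makes no claim to reproduce them number-for-number at desk
scale, and only their aggregates are treated as checkable outputs.
Observed-basis arithmetic (convex hulls and 2-km occupancy counts) is, by
contrast, fully reproducible from coordinates.

## The simulator, and what passing tests mean

`simulation_config()` defines seeded synthetic worlds: independent
Gaussian-white-noise layers smoothed with a separable Gaussian kernel
(σ = 5 cells by default) and standardized; a virtual species defined by a
logistic linear combination of the layers; presences drawn
*proportionally to suitability* with uniform placement inside the cell
and a fixed error radius attached; and Gaussian cave clusters for
observed-basis fixtures. The default recovery configuration is a
100 × 100 grid of 1-km cells, three layers, generating coefficients
(0, 2, −1, 0), suitability cut 0.5, 30 presences and 1 km error, with a
100-run ensemble — sizes chosen so the full study runs in seconds on one
core while leaving the per-run fit non-trivial (~10⁴ cells, ~10³
background points).

Under that configuration the package's recovery checks require the
habitat-restricted consensus map to contain at least 90% of the true
presence cells and to overlap the true range at Jaccard ≥ 0.5.

One recovery quantity deserves a candid note. Because presences are
sampled in proportion to suitability rather than from the thresholded
range, no model — including an oracle scoring cells by the true
suitability itself — can separate presences from uniform background
beyond the overlap of those two distributions. The attainable AUC
ceiling is

> AUC* = Σᵢ wᵢ (rankᵢ − ½) / N,  wᵢ ∝ suitabilityᵢ,

which evaluates to ≈ 0.69 on the default landscapes; observed mean run
AUC sits at ≈ 0.70–0.77 (training optimism lifts it slightly above the
ceiling). The recovery suite nevertheless states its mean-AUC expectation
at the conventional 0.8 benchmark, and that single expectation fails by
design of the sampling scheme: it documents the gap between a familiar
"good model" rule of thumb and what a suitability-proportional world
permits, and we prefer keeping the discrepancy visible over weakening
either the sampler (sampling from the thresholded range would push AUC
toward 1 and make the benchmark trivial) or the stated threshold. Range
recovery — the quantity assessments actually consume — is unaffected.

What the synthetic world does *not* emulate: covariance among real
climate variables, anisotropic or trending gradients, spatial sampling
bias in collections, and land-cover constraints. Passing recovery tests
therefore demonstrate the pipeline's internal correctness and its
behaviour under positional error, not field-data performance.

## Numerical choices

- Collinearity tolerance for degenerate hulls: 10⁻⁶ km².
- IRLS for the ridge fit stops when the largest coefficient step falls
  below 10⁻⁸, errs after 100 iterations, and floors the working weights
  at 10⁻¹⁰ to survive perfect separation; the quadratic penalty
  guarantees a finite optimum even then.
- Score-map thresholds (0.5 / 0.975 / 0.025) are inclusive (≥), so a
  unanimous ensemble yields identical consensus and confidence-limit
  maps.
- Zero-variance layers are dropped from a fit with a warning rather than
  poisoning the standardization.
- ASCII-grid rasters are the interchange format for layers and maps
  (plain text, NODATA-aware); KML (2.2) and CSV are the record formats.

## Interfaces

The R functions are the primary interface; `cmd_range()`, `cmd_assess()`,
`cmd_simulate()` and `cmd_tally()` wrap the two assessment paths, the
simulator and the profile tallies, and a thin `Rscript` front-end with
the same four subcommands ships in `inst/scripts/rangeprofile.R`. Every
report embeds the package version and the complete parameter set
(including defaults) that produced it.

## Known limitations

- Modelled ranges depend on the background sample through the fitted
  coefficients; with very small landscapes the background can exhaust
  the valid cells, which is clipped with a warning.
- The DD rule is a record-count screen only; it knows nothing about
  record quality or spatial coverage.
- EOO of a map uses suitable-cell centres, so a single-cell map has
  EOO 0 rather than the cell's own area.
- Patch restriction assumes the dispersal barrier is captured by map
  adjacency; it does not model permeability.
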