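---
title: "Quantifying skin aging from histology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skin aging from histology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(dermatomics)
```

# The measurement problem

Intrinsic skin aging remodels the dermal-epidermal junction: rete ridges — the
downward protrusions of the epidermis that anchor it to the dermis — become
shorter, thinner and (at some sites) sparser, basal proliferation (Ki67)
declines, hemidesmosomal adhesion (integrin β4) weakens, and papillary
microvessels compact. Manual scoring of these phenotypes on a few selected
fields is slow and observer-dependent. `dermatomics` implements an automated
whole-section alternative: it segments the epidermis from H&E images, reduces
each epidermal region to a skeleton graph whose longest path is the epidermal
midline and whose validated side-branches are rete ridges, extracts
distributional morphometrics, quantifies the companion immunofluorescence
markers, and combines everything in a Random Forest that predicts skin age and
scores longitudinal change (e.g. before/after xenografting).

# Pipeline stages

## Tissue detection and slice extraction

Whole-slide images are read as image pyramids (flat images count as one-level
pyramids). Work happens on a raster with an effective downsample factor of 16
(`target_factor`); if no pyramid level matches, the closest finer level is
resampled down (bilinear for images, nearest-neighbour for masks). Tissue is
the conjunction of two Otsu masks — one on the HSV hue channel, one on the
per-pixel channel minimum — dilated (3×3 box, 2 iterations), hole-filled, and
cleaned of components under 50,000 px (`min_component_px`). The hue threshold
polarity is not knowable a priori, so the side of the threshold that overlaps
the dark (non-white) pixels more is taken as tissue and recorded in the mask
provenance. Each 8-connected component becomes a slice, cropped at the
high-fidelity level via its scaled bounding box.

## Epidermis segmentation

Each slice crop is Gaussian-smoothed per channel (σ = 2) and converted to
8-bit LAB and HSV encodings (L scaled to 0–255, A/B offset by 128, hue on
0–179 by default — exposed as `hue_max` because a 0–255 convention is equally
plausible for the `H < 110` rule). Pixels matching any exclusion rule are
masked out: `L < 50`; `L >` a site-dependent cap (abdomen 140, xenograft 160,
buttock 200); `L < 100 & A < 150`; `H < 110`; `S < 40`; exactly gray pixels
(`R = G = B`). The kept pixels feed a PCA (Macenko-style) stain fit in optical
density: OD vectors above a transparency floor of 0.15 are projected on their
dominant plane and the 1st/99th angle percentiles become the two stain
directions, ordered hematoxylin-first (largest red-channel OD). The nuclear
channel is the hematoxylin concentration from least-squares unmixing of the
stain matrix — raw projection onto the hematoxylin vector does not separate
the channels because H&E OD vectors are ~40° apart, so eosin-rich pixels would
leak through. Concentrations below 0.2 are zeroed, the channel is
Gaussian-filtered (σ = 2) and Otsu-thresholded into a nuclear-density mask,
which is refined morphologically: opening (3×3), removal of objects < 64 px,
opening with 4 iterations, a 10×10 box-mean filter, and a strict
local-mean > 0.5 cut. The surviving 8-connected components are the epidermal
"trees".

## Skeleton graph and rete-ridge validation

Each tree is thinned (Zhang–Suen) to a 1-px skeleton. With 8-connectivity,
skeleton pixels with more than two neighbours are junction pixels (8-adjacent
clusters merge to one junction node; thinning routinely emits such clusters
and merging prevents spurious zero-length branches) and pixels with exactly
one neighbour are endpoints (one node per pixel — an isolated two-pixel
segment is two endpoints). Non-node pixels are labelled into branches; only
branches adjacent to exactly two distinct nodes are kept, parallel edges
collapse to the lighter one, and the minimum spanning tree is computed with
edge weight = branch pixel count (ties broken by branch id). A double sweep
(farthest vertex from the lowest-id vertex, then farthest from that) yields
the tree diameter — the epidermal midline. Components whose midline counts
fewer than 500 pixels (`min_path_px`) are rejected outright; rejection is per
component, so one slide may contribute both accepted and rejected trees, and
every rejection is logged rather than silently dropped.

Every remaining MST edge is a provisional rete ridge, validated
directionally: a ridge must point *away* from the outer tissue surface. With
`d_tip` and `d_base` the nearest-boundary distances of the distal and
proximal nodes (queried on a precomputed exact Euclidean distance map of the
whole-slice tissue boundary), an edge is valid iff `d_tip >= d_base` — the
tie is deliberately kept, since only a tip *strictly* closer to the surface
marks an upward spur. Two further design points deserve mention:

* **Boundary scope.** Validation defaults to the whole-slice tissue boundary
  (dominated by the outer surface), making the rule a directional filter that
  keeps dermis-pointing branches; validating against the epidermal-component
  boundary would discard true ridges, whose tips hug the epidermal outline.
  Both scopes are implemented (`boundary_scope`).
* **Endpoint-terminated ridges.** A single anatomical ridge can skeletonize
  into a chain of edges when a Y-junction forms at a wide ridge mouth. A
  ridge terminates at an endpoint node; edges whose distal node is a junction
  are classified `internal_connector` and are not counted. The length
  formula below automatically credits the full chain to the leaf edge.

## Morphometrics

Per accepted component: thickness at every midline pixel is twice the
distance to the nearest epidermal-component boundary (the component boundary,
not the tissue boundary, so that the ×2 rule yields the band thickness);
ridge length is branch length + base-to-midline distance + tip-to-boundary
distance; base and end thickness are twice the base/tip distance to the
epidermal boundary, and the dilation factor is their ratio (≈1 for blunt,
non-tapering ridges). Per-slice records pool all accepted components: total
midline length ("epidermal length"), validated ridge count, ridge density
(count / length), epidermis area per length, and for the thickness profile
and each ridge metric the mean, SD, median, IQR, percentiles 5/25/75/95 and
range (quantile type 7, linear interpolation — fixed for reproducibility).
Ridge-free slices carry missing ridge aggregates (zeros would bias the
models) with density 0. All features are in pixels; an optional
pixels-per-mm converts reported lengths.

Per-feature age trends are ordinary least squares fits of feature on age,
with the Wald (regression t) test on the slope and a 95% confidence band for
the mean response. Constant features are flagged (`slope 0, p = 1`), and a
saturated two-point fit is flagged with an undefined p-value rather than
erroring.

## Immunofluorescence quantification

ITGB4 is the arithmetic mean of raw intensities in a manually annotated
basal-epidermis ROI. Ki67-positive cells (supplied as coordinates or counts —
automatic nucleus detection is out of scope, matching the manual counting
protocol) are normalized to epidermal length, and cells inside rete ridges to
the ridge count (undefined when there are no ridges). CD31 microvessels are
segmented in a papillary-dermis ROI by intensity thresholding (Otsu within
the ROI by default; the resolved value is recorded), 8-connected labelling,
and a ≥ 5 px anti-speckle guard. Per-object features are area, perimeter,
inertia-ellipse major/minor axes and eccentricity, aspect ratio, solidity
(area over rasterized convex-hull area, so convex objects stay ≤ 1), and
sum/mean/median intensity. Section summaries compute per-region distribution
statistics plus the CD31⁺ area fraction, then average across the five
protocol regions (pooling across regions before the percentiles is available
behind `pool = TRUE`; averaging per-region statistics is the default reading
of the protocol).

## Age models and xenograft deltas

Feature tables from the three assays join on the accession `ID` (xenograft
keys concatenate donor and condition, e.g. `D03_Young`); rows with missing
predictors are excluded. Two Random Forest regressors (500 trees; all
features candidate at each split, the regression default of the reference
implementation whose protocol this mirrors) predict age in years:

* the **full model** on all predictors, and
* the **reduced-polynomial model** on the top 8 predictors by normalized
  mean-decrease-in-impurity importance (ties by input column order), expanded
  to degree 2 without bias — 8 linear + 8 squared + 28 pairwise products =
  44 predictors, named `f`, `f^2`, `fA*fB` in input order. No centering or
  scaling is applied: forests are scale-invariant.

Both are scored by 5-fold shuffled cross-validation (fold membership depends
only on the row count and the seed, default 42); MAE and R² are computed per
fold and averaged (pooled-prediction R² is a reasonable alternative the
package does not default to), and the final forest is refit on all rows. CV
operates on one row per sample (slice-aggregated means); slice-level rows
also work since folding is row-based. For xenografts, per-slice predictions
are averaged within each (Sample, Condition), pivoted wide, and differenced:
`delta_pre_young = Pre − Young` (the predicted-age drop after grafting into a
young host), `delta_pre_old`, `delta_young_old`. Donors missing a condition
get missing deltas.

# The synthetic phantoms

No clinical images accompany the method (archived tissue-bank material), so
the package ships a first-class generator whose defaults are the study
conditions of every ground-truth test:

* **H&E phantom** — an epidermis band (default thickness 40 px) with
  trapezoidal, round-tipped rete ridges (default 6 ridges, 80 px long, base
  24 px, end 20 px, spaced 3.5 base-widths apart) under a sinusoidal surface
  (amplitude 6 px), tapered band ends (a thinning skeleton of a blunt
  rectangle forks at the corners; a tapered end terminates cleanly in one
  endpoint), dense nuclear dots, and a pale dermis block. The image is
  composed in OD space, `I = exp(-(c_h H + c_e E))`, on the canonical H&E
  vectors with per-class stain loads (epidermal cytoplasm 0.6/0.5, nuclei
  1.8/0.1, dermis 0.05/1.0) chosen so every class lands inside the buttock
  color-filter window as real tissue does, plus Gaussian intensity noise
  (sd 0.008). The seed fully determines the output.
* **IF phantoms** — a basal band of stated mean intensity (ITGB4), bright
  nuclei at recorded coordinates (Ki67), and non-overlapping filled ellipses
  of known axes and intensity (CD31).
* **Feature tables** — 16 slice-aggregate features, linear in age plus
  Gaussian noise: eight "planted" features whose slopes mirror the directions
  seen in aging skin (end/base thickness, ridge length, ITGB4, Ki67
  decreasing; dilation factor and CD31 solidity increasing) at per-feature
  age correlations of r ≈ 0.72–0.74 (a clean-phantom notch above the best
  single-feature association reported on real tissue), and eight
  age-independent nuisance features. Xenograft tables draw `Pre` slices at
  the donor's age and `Young`/`Old` slices at the donor's age minus a planted
  15-year rejuvenation.

Two generator-geometry facts matter when reading recovery results. First,
the skeleton junction of a ridge sits at band mid-depth, so the measured
*base thickness* (twice the junction-to-boundary distance) tracks the local
band thickness rather than the drawn ridge base width; the drawn end width is
what the *end thickness* tracks. The per-ridge truth therefore records these
analytic expectations, and the recovery grid varies band thickness to probe
base-thickness recovery. Second, thinning retracts the skeleton endpoint
slightly deeper into the ridge tip than the half-width that the
tip-to-boundary term compensates, giving measured ridge lengths a systematic
~10% shortfall against `length + thickness/2`; recovery is therefore asserted
as a correlation across the grid (r ≥ 0.9) plus a 15% band on the idealized
rectangular-ridge case.

What the phantoms deliberately do **not** emulate: stain variability across
slides, out-of-focus and compression artifacts, stratum corneum and adnexal
structures, touching or fragmented sections, and non-linear age trajectories.
Passing tests demonstrate that the algorithms recover known geometry and
statistical structure under clean conditions — not clinical-grade robustness.

The donor age range for xenograft simulations defaults to 62–75 years:
donors must be elderly, but the rejuvenated state (age − 15) must remain
inside the trained age support (uniform 20–80) for the shift to be
identifiable — a bounded-range learner cannot predict outside the ages it has
seen. Even so, Random Forest regression-to-the-mean attenuates recovered
deltas to ≈ 11–13 of the planted 15 years; this attenuation is a property of
the estimator, visible in the acceptance outputs, and worth remembering when
interpreting absolute delta magnitudes on real data.

# Numerical choices and degenerate inputs

* Coordinates are row-major and 0-based externally (half-open bounding
  boxes); masks and images are R matrices/arrays internally.
* 8-connectivity everywhere (labelling, skeleton neighbourhoods, CD31
  objects); the labelling and Zhang–Suen thinning are compiled (Rcpp) since
  no installed package provides them with this connectivity.
* Nearest-boundary queries use exact Euclidean distance maps
  (`EBImage::distmap`) with lookups at rounded coordinates (±0.5 px
  discretization, negligible against the ×2 thickness rule).
* Otsu on (near-)constant input returns an empty mask with a warning, never
  an error; a degenerate (single-stain) OD cloud errors unless the caller
  opts into the canonical H&E fallback vectors.
* MST ties are broken by an infinitesimal branch-id perturbation of the
  weights; double-sweep ties by lowest vertex id — graph summaries are
  byte-identical across runs.
* The even-sized 10×10 uniform filter uses summed-area tables with the
  window spanning offsets −4…+5 and zero padding.
* The 500-px midline rule is applied to the midline pixel count, which is
  also the "epidermal length" feature; the two uses are unified on the same
  quantity.

# Problem sizes

The test-suite and acceptance studies use phantom rasters of roughly
200–260 × 650–1850 px (grids of 8 parameter combinations spanning 2–12
ridges, lengths 30–120 px, base widths 12–40 px, band thickness 24–60 px),
1,000 null simulations for Wald-test calibration, and 10 seeds × (full +
reduced) model fits at n = 60 samples — sizes chosen so a complete run
reproduces every claim in minutes on a laptop while still exercising the
stated parameter ranges.

# Worked example

```{r example, eval = FALSE}
ph  <- render_he_phantom(skin_phantom_spec(seed = 1))
out <- run_pipeline(list(slice = ph$image),
                    pipeline_config(site = "buttock", target_factor = 1))
out$features[, c("ridge_count", "ridge_density", "thickness_median")]

tab  <- simulate_feature_table(seed = 1)
full <- train_full(tab)
red  <- train_reduced(tab, full)
glance(red)
autoplot(red)

graft <- simulate_xenograft_table(seed = 2)
predict_and_delta(red, graft)
```

# Known limitations

* Ridge lengths carry the ~10% thinning-retraction bias described above.
* The hue-encoding convention for `H < 110` (0–179 vs 0–255) is a genuine
  ambiguity of the threshold set; both are selectable, the default being the
  one under which all thresholds are self-consistent.
* The directional ridge filter assumes the outer surface dominates the
  tissue boundary; heavily fragmented sections would weaken that assumption.
* The model modules accept an explicit predictor list rather than asserting
  a canonical 48-feature panel: the exact composition of such a panel is
  site- and assay-dependent, and the feature dictionary produced by the
  pipeline is a superset.
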