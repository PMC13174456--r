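# dermatomics

Automated "imageomics" of skin aging: epidermal segmentation and rete-ridge
morphometry from H&E histology, immunofluorescence marker quantification
(ITGB4, Ki67, CD31), and Random Forest skin-age modeling — with a synthetic
phantom generator that makes the whole pipeline testable without clinical
images.

## Who this is for

Dermatology and skin-biology groups who want objective, whole-section
measurements of intrinsic skin aging — rete-ridge geometry, epidermal
thickness distributions, basal adhesion and proliferation markers,
papillary-dermis microvessel morphometry — and a compact predictive model of
"skin age" that can score longitudinal change, such as the apparent
rejuvenation of human skin xenografted onto mice.

## What it computes

**Epidermis segmentation.** Slide pyramids are downsampled (~16×), tissue is
detected as the conjunction of two Otsu masks (HSV hue; per-pixel channel
minimum), and each connected component becomes a slice. Within a slice the
epidermis is isolated by empirical LAB/HSV color rules (e.g. `L<50`,
site-dependent `L>` caps, `H<110`, `S<40`, `R=G=B`), a Macenko-style PCA
stain fit in optical density `OD = -log(I/I₀)`, least-squares unmixing to
the hematoxylin (nuclear) channel thresholded at 0.2, Gaussian filtering,
Otsu, and morphological refinement (opening, small-object removal, opening
×4, 10×10 uniform filter, local mean > 0.5).

**Skeleton graph.** Each epidermal component is thinned to a skeleton; pixels
with >2 neighbours are junctions, with exactly 1 are endpoints; branches
become edges weighted by pixel count. On the minimum spanning tree, a
two-pass sweep finds the longest path — the epidermal **midline** (components
under 500 midline pixels are rejected). Every other MST edge is a provisional
**rete ridge**, kept iff its endpoint tip is not closer to the outer tissue
boundary than its junction base (`d_tip ≥ d_base`) — a directional filter
that keeps dermis-pointing ridges and discards surface spurs.

**Morphometrics.** Thickness = 2 × midline-to-boundary distance; ridge
length = branch + base-to-midline + tip-to-boundary; base/end thickness =
2 × base/tip-to-boundary; dilation factor = end/base. Per-slice records carry
ridge count, density (count/length), area per length, and full distribution
summaries (mean, SD, median, IQR, p5/p25/p75/p95, range). Per-feature age
trends are OLS fits with Wald slope tests and 95% confidence bands.

**IF quantification.** ITGB4 mean intensity in the basal epidermis;
Ki67⁺ cells per epidermal length and per rete ridge; CD31 objects segmented
in the papillary dermis with per-object area, eccentricity, solidity,
perimeter, axes, aspect ratio and intensities, summarized over five regions
per sample plus the CD31⁺ area fraction.

**Age models.** A full Random Forest (500 trees) on all predictors, and a
reduced model on the top-8 importance-ranked predictors after a degree-2,
no-bias polynomial expansion (8 linear + 8 squared + 28 products = 44
predictors), both scored by 5-fold shuffled cross-validation (MAE, R²).
`predict_and_delta()` averages per-slice predictions within (donor,
condition), pivots wide, and reports the xenograft deltas
`Pre−Young`, `Pre−Old`, `Young−Old`.

**Synthetic phantoms.** `render_he_phantom()` builds H&E-like sections with
known band thickness, ridge count/length/widths, nuclei and stain vectors;
`render_if_phantom()` builds ITGB4/Ki67/CD31 images with known truth;
`simulate_feature_table()` builds age-linear feature tables. Every
ground-truth test in the package runs against these.

## Worked example

```r
library(dermatomics)

# a phantom section with 6 known rete ridges, processed end-to-end
ph  <- render_he_phantom(skin_phantom_spec(seed = 1))
out <- run_pipeline(list(slice = ph$image),
                    pipeline_config(site = "buttock", target_factor = 1))
out$features[, c("ridge_count", "ridge_density", "thickness_median",
                 "ridge_length_median", "dilation_factor_median")]
#>   ridge_count ridge_density thickness_median ridge_length_median
#> 1           6        0.0085               36                  87
#>   dilation_factor_median
#> 1                 0.4227
```

All 6 generated ridges are recovered; the median measured ridge length (87 px)
sits near the geometric expectation for 80 px protrusions under a 40 px band,
and the median thickness (36 px) reflects the band after morphological
refinement.

```r
# age modeling on a synthetic cohort (n = 60, ages 20-80)
tab  <- simulate_feature_table(seed = 1)
full <- train_full(tab)
red  <- train_reduced(tab, full)
glance(red)
#>   type        n n_predictors cv_mae cv_r2 n_trees cv_folds
#> 1 reduced    60           44   5.40 0.802     500        5

# planted 15-year xenograft rejuvenation, recovered per donor
graft <- simulate_xenograft_table(seed = 2)
predict_and_delta(red, graft)
#>   Sample   Pre Young   Old delta_pre_young delta_pre_old
#> 1    D01 64.05 46.12 52.29           17.93         11.76
#> 2    D02 70.99 57.93 53.55           13.07         17.44
#> 3    D03 67.43 57.71 55.61            9.72         11.82
#> 4    D04 60.85 46.06 50.53           14.79         10.32
#> 5    D05 67.64 59.73 59.67            7.91          7.97
```

The reduced-polynomial model cross-validates at MAE ≈ 5.4 years (R² ≈ 0.80)
on this clean cohort, and the recovered per-donor deltas scatter around the
planted 15-year shift (attenuated slightly by forest regression-to-the-mean;
see the methods vignette).

## Documentation

The methods vignette (`vignettes/dermatomics-methods.Rmd`) describes the
segmentation model and its assumptions, every tunable threshold with units
and defaults, what the phantoms do and do not emulate, numerical and
tie-breaking choices, and known limitations.
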