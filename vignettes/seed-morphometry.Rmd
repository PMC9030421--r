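---
title: "Seed silhouette morphometry and discriminant classification with seedmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed silhouette morphometry and discriminant classification with seedmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmorph)
library(dplyr)
```

## The problem

Seeds, fruit stones and endocarps carry cultivar-level shape signal: a grape
pip or plum stone from one landrace differs subtly but consistently from
another in elongation, bluntness and outline curvature. Archaeobotanists
exploit this by scanning modern reference collections and waterlogged
archaeological material on a flatbed scanner, measuring the silhouettes, and
asking a discriminant classifier which modern class each ancient specimen
resembles. `seedmorph` implements that workflow end to end:

1. **Segmentation** — a scanned image (white or black background, known dpi)
   is thresholded automatically, connected components become per-specimen
   binary masks, and each mask's outer boundary is traced through pixel
   centres.
2. **Morphometry** — 26 descriptors per specimen: 10 primary measures
   (perimeter, polygon area, pixel count, inscribed/enclosing radii about
   the centroid, Feret diameter, breadth, convex-hull perimeter and area,
   minimal-bounding-circle radius) and 16 derived ratios and equivalents
   (circularity, roundness, aspect ratio, solidity, convexity,
   rectangularity, ...).
3. **Classification** — stepwise linear discriminant analysis driven by
   Wilks' lambda partial-F statistics, leave-one-out cross-validation, and
   allocation of an `UNKNOWN` cohort to the reference classes as a
   row-percentage table.
4. **Synthetic populations** — a superellipse silhouette generator with
   analytic ground truth, so every stage is testable without physical seed
   collections.

## The measurement model

A specimen is a single 8-connected foreground component (background treated
4-connected — the standard duality), holes filled. Its boundary polygon runs
through the centres of the boundary pixels (foreground pixels with a
4-connected background neighbour — exactly the pixels a Moore-neighbour
contour walk visits), counter-clockwise, starting at the top-most then
left-most boundary pixel. From mask and polygon:

* `Perim`: Euclidean arc length of the pixel-centre polygon (steps of 1 and
  `sqrt(2)`; no corner-smoothing correction).
* `Area`: shoelace area of that polygon; `Pixels` is kept separately as the
  raw foreground count.
* `MinR`, `MaxR`: minimal and maximal distance from the foreground
  pixel-mass centroid (our reading of the "middle" of the seed) to the
  polygon vertices.
* `Feret`: maximum caliper distance, computed by rotating calipers over
  antipodal pairs of the convex hull; `Breadth` is the caliper extent
  perpendicular to the realized Feret direction, so `ArBBox = Feret *
  Breadth` is the Feret-aligned bounding box.
* `CHull`, `CArea`: convex-hull perimeter (a length — the derived ratios
  divide it by lengths) and area.
* `MBCRadius`: radius of the minimal enclosing circle of the hull vertices,
  by Welzl's algorithm with a deterministic input scramble.

The 16 derived descriptors are algebraic in these (see
`?derived_measures`). One deserves a note: the classical descriptor table
this panel follows prints *perimeter equivalent diameter* as `Area / pi`,
dimensionally an area and almost certainly a misprint of `Perim / pi`.
`seedmorph` reproduces the printed formula by default and offers
`perequivd_convention = "perimeter_over_pi"` for the conventional form.

### Digitization bias, quantified

Descriptors of a digitized shape differ from the continuous limit in ways
that matter when you compare against closed forms:

* The pixel-centre staircase perimeter of a smooth outline exceeds the true
  perimeter by a chain-length factor averaging `(8/pi)(sqrt(2)-1) ~ 1.055`
  over orientations. Circularity of a digitized disk therefore converges to
  about `1 / 1.055^2 ~ 0.90`, not 1, and perimeter-based ratios (`Circ`,
  `Convexity`, `Shape`) wobble a few percent with orientation for blocky
  outlines. The error *decreases* monotonically with radius; the tests pin
  the r = 200 disk inside [0.08, 0.12] of 1.
* The boundary polygon sits roughly half a pixel inside the continuous
  outline, so polygon areas run low by about `P/(2A)` relative terms
  (about 1% for a disk of radius 100, 1.5% for a 100 x 50 ellipse), and
  `MinR` of an ellipse is about half a pixel under the semi-minor axis.
  `Pixels` is nearly unbiased for curved outlines but counts
  `(w+1)(h+1)` for a lattice-aligned `w x h` rectangle.
* Hull-based quantities (`Feret`, `Breadth`, `MBCRadius`, `CArea`, `CHull`)
  converge fast and are reliable to well under 1% at working sizes.

The oracle tests therefore check every descriptor against an independent
brute-force digitization oracle at 1% (lengths/areas) and 2% (ratios), and
additionally check the continuous closed forms for the descriptors whose
digitized values converge at the reference sizes. `Solidity >= 0.99` holds
for convex silhouettes with semi-axes above ~60 px; `Convexity` for convex
digitized shapes sits in [0.92, 1] because of the perimeter factor — a
property of the measurement dialect, not an error.

## The classifier

Selection is the classical stepwise procedure: with `S` the current set,
a candidate `j` enters when its partial F,

    F_enter = (1 - L) / L * (n - g - |S|) / (g - 1),   L = Lambda(S + j) / Lambda(S),

is maximal and at least `f_to_enter`, provided its within-group tolerance
(1 - R^2 against `S` in the pooled-within metric) is at least `tolerance`;
an included variable leaves when its partial F-to-remove falls below
`f_to_remove`. `Lambda(S) = det(W_S) / det(T_S)` is Wilks' lambda. Defaults
`f_to_enter = 3.84`, `f_to_remove = 2.71`, `tolerance = 0.001` are the
long-standing defaults of the classical statistics packages for this
procedure. Rows labelled `UNKNOWN` never influence selection, fitting or
cross-validation.

The discriminant itself is the Gaussian linear rule with pooled within-class
covariance; priors default to equal across classes because reference
collection sizes are sampling artefacts, not prevalence. Posterior ties
break towards the lexicographically first class label, for determinism.
Classification is invariant to affine rescaling of any descriptor, so px
versus mm units cannot change an assignment.

**Cross-validation.** `cross_validate()` performs selection once on the full
labelled table and then refits the discriminant without each held-out
specimen (exact mean/SSCP downdates, so LOO is deterministic and seed-free).
This is the source-faithful variant, and it is *optimistic*: on pure-noise
data with 26 candidate descriptors, the once-selected features are the ones
that look best on the full table, and the measured LOO accuracy for two
identical-distribution classes of 100 runs ~5 points above the 50% chance
level. `honest = TRUE` re-runs selection inside every fold, which removes
that bias at the price of a noisier estimate (cross-validated accuracies are
correlated across folds, so their spread exceeds the binomial
`sqrt(p(1-p)/n)`). When no descriptor passes `f_to_enter` at step 1,
`stepwise_select()` raises an informative error; `cross_validate()` instead
falls back to prior-only classification so that chance-level data yields a
chance-level table rather than a failure.

**Allocation.** An unknown cohort is summarised as the percentage of
specimens assigned to each class, rounded to one decimal by largest
remainder so every row totals exactly 100.0, mirroring the layout of
published allocation tables; the per-specimen posteriors ride along as an
attribute.

## The synthetic generator

`sample_population()` draws silhouettes from the superellipse family
`|x/a|^m + |y/b|^m = 1`: `a` (px) sets size, `b/a` in (0, 1] the aspect,
and the exponent `m` blends ellipse (`m = 2`) into rectangle-like
(`m` large). A low-order radial Fourier perturbation
`r(theta) (1 + sum_k c_k cos(k theta + phi_k))`, harmonics 2-5, adds
specimen-level outline roughness. Parameters are truncated-normal per class
(`a >= 4` px, aspect in (0.05, 1], `m` in [1.2, 12], amplitudes clamped to
±0.12 so outlines stay star-shaped), rotation is uniform, and rasterization
samples pixel centres against the polar inside test. One seed governs a
population; regeneration is bit-identical and the caller's RNG state is
untouched.

This family spans elongation, bluntness and boundary roughness — the axes
that separate plum-stone-, watermelon-seed- and grape-pip-like outlines —
with few, interpretable parameters, and it admits an analytic oracle
(`analytic_features()`: closed forms at `m = 2` and `m = Inf`, dense
boundary quadrature in between, computed independently of the raster
pipeline). It does **not** emulate bilateral asymmetry, the beak/chalaza
detail of real pips, surface texture, or waterlogging deformation; passing
the synthetic recovery tests shows the measurement and classification
machinery is sound, not that any particular real collection is separable.

The shipped example specification
(`system.file("extdata", "example_class_specs.json", package = "seedmorph")`)
defines three classes at 400 dpi scale with semi-major axes of about 180,
75 and 45 px (11.4, 4.8 and 2.9 mm) — loosely plum, watermelon and grape.
The validation suites use smaller populations chosen once: the invariant
sweep draws 1000 masks spanning sizes 12-50 px, aspects 0.35-1, exponents
1.4-4 and noise up to 0.08; the end-to-end recovery experiment uses three
classes of 100 at a common size (45 ± 4 px) differing only in aspect
(0.45/0.60/0.75) and exponent (1.7/2.0/2.6) plus a 70-specimen unknown
cohort, so recovery rests on shape rather than size.

## Worked example

```{r example, eval = FALSE}
specs <- example_class_specs()
pop <- sample_population(specs, dpi = 400, seed = 7)

# render a synthetic scan and take it through the image path
sc <- render_scan(pop[pop$class_label == "grape", ], background_mode = "white")
segs <- segment_seeds(sc$scan, min_area_px = 100)
features <- extract_features(segs, units = "px", dpi = 400,
                             class_label = "grape")

# or skip rendering and measure the population directly
train <- extract_features(pop)
sel <- stepwise_select(train, stepwise_config())
model <- fit_lda(train, sel$selected)
cv <- cross_validate(train)
cv$overall_correct

unknown <- extract_features(
  sample_population(mutate(specs[3, ], n = 30L), seed = 8),
  class_label = "UNKNOWN"
)
allocate_unknowns(model, unknown)
```

The one-command variant writes every artifact (feature CSVs, allocation
tables, model JSON, stepwise trace, resolved-config provenance) to a
directory:

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config("out", mode = "simulate", seed = 7))
res$results$cv
```

## Numerical choices and edge cases

* **Thresholding** is Otsu's criterion on the grey histogram — parameter-free
  and well suited to high-contrast scanner images; the threshold is recorded
  in the segmentation output. Polarity is inverted for white backgrounds so
  foreground is always the seed. Only the single supplied image is measured;
  white/black scan pairs are not fused.
* **Touching seeds** are not separated (no watershed); they surface as one
  merged mask. Operators are assumed to lay seeds apart.
* **Degenerate specimens** (fewer than 3 boundary pixels, or zero polygon
  area, e.g. 1-2-pixel specks surviving the area filter) are rejected
  per-specimen with a warning and a `rejects` listing; a run fails only if
  every specimen is degenerate.
* **Singularities**: exact collinearity is blocked at selection time by the
  tolerance rule; a singular pooled covariance at fit time is a typed error
  naming the features involved.
* **Determinism**: segmentation, measurement and LOO are seed-free and
  bit-reproducible; simulation and k-fold use one explicit seed recorded in
  the provenance JSON. Welzl's algorithm uses a fixed deterministic input
  scramble rather than RNG shuffling.
* **Status codes**: `run_pipeline()` maps typed failures to stable statuses
  (2 validation, 3 I/O, 4 degenerate data, 5 model failure) instead of
  raising, so callers can branch on outcome.

## Known limitations

* The 26-descriptor panel is outline-only: no elliptic Fourier harmonics,
  texture, colour or 3-D information.
* The staircase perimeter dialect is faithful to pixel-centre tracing but
  makes perimeter-based ratios resolution- and orientation-dependent;
  compare such ratios only across images of similar scale.
* Stepwise selection inherits the known liabilities of the classical
  procedure (greedy path, optimistic once-selected CV); the honest-CV flag
  and the step log are provided so users can see and counter both.
* The synthetic generator validates machinery, not biology; claims about
  real cultivar separability still require real reference collections.
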