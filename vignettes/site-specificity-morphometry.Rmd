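---
title: "Site-specific cortical bone morphometry: methods and design notes"
author: "sitespec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific cortical bone morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Conventional cortical micro-CT analysis of mouse long bones averages a
block of slices around one or two user-chosen regions of interest. Because
cortical geometry changes continuously along the bone — the proximal tibia
is large, thin-walled and strongly eccentric, the distal tibia small,
thick-walled and near-circular — single-site summaries both miss localized
responses and depend on exactly where the region was placed. `sitespec`
instead analyzes the single reconstructed cross-section at *every* 1% of
the bone's length and treats "site" as an explicit factor in the
statistics.

The pipeline is:

1. **Slice selection.** A stack of `n` sequential cross-sections is
   parameterized so that slice `round(p/100 * (n - 1))` (0-based, half
   rounded away from zero) sits at percent site `p`. Sites 10–90% are
   analyzed (81 slices); the extremes are excluded because proximal
   trabecular bone and the distal calcaneus confound cortical
   segmentation. Whether the scanner exports proximal-first or
   distal-first is a config flag (`reversed`), since file order alone
   cannot tell.
2. **Segmentation.** Pixel intensities of each slice are split by exact
   1-D two-means clustering; the fibula and speckle are removed by keeping
   the largest 8-connected component; non-bone pixels unreachable from the
   image border (4-connected flood fill, the standard dual connectivity)
   are marrow. A slice whose cortex does not enclose a cavity is flagged
   *breached*: marrow and total area are undefined there, cortical area is
   still valid.
3. **Morphometry.** Cortical/marrow/total areas, mean cross-sectional
   thickness, principal second moments of area and the polar moment of
   inertia (PMI), Feret caliper diameters and angle, eccentricity and the
   centroid.
4. **Orientation and curvature.** All coordinates are rotated so the Feret
   angle of the 37% site (a fixed, arbitrary reference) is 0°; the
   straight central axis is the line through the 5% and 95% centroids; and
   curvature is reported as the per-site absolute centroid deviation from
   that axis, componentwise (anterior–posterior `dev_x`, medial–lateral
   `dev_y`).
5. **Statistics.** Long-format cohorts (mouse, limb, group, site, measure)
   feed `value ~ site + group + site:group`, with a random mouse intercept
   for paired (left/right-limb) designs, Wald type-III tests for the
   overall intervention and the site-by-intervention interaction, and a
   Bonferroni-corrected per-site map gated on overall significance.

```{r}
library(sitespec)
gen <- generatePhantomStack(phantomSpec())
profile <- runSiteSpecificity(stack = gen$stack, outPath = "output")
head(profileData(profile))
```

## Segmentation choices

**Exact two-means instead of Lloyd's algorithm.** In one dimension the
optimal 2-means partition is a split point in sorted order, so the global
optimum is found by a linear scan over the unique intensities with prefix
sums. There is no random initialization; re-analysis of the same image is
bit-identical, which is what makes the pipeline's reproducibility exactly
R² = 1 rather than approximately so. The threshold is the midpoint of the
two cluster means, so partial-volume pixels are assigned purely by
similarity to the cluster means.

**Connectivity.** Foreground components use 8-connectivity, the
background flood fill 4-connectivity. This is the standard dual pairing
that prevents a diagonal line of bone pixels from "leaking" marrow to the
outside and vice versa. Component labeling runs on a fast 4-connected
pass whose labels are then merged across diagonal adjacencies.

**Breach rule.** `breached` is defined as *no enclosed marrow and a
substantially non-convex cortex* (convex-hull area deficit above 5%). The
deficit clause separates a genuinely solid convex section — which is
enclosed, with `Ma.Ar = 0` — from a broken ring whose interior connects to
the border. Concave-but-solid sections are conservatively flagged
breached; for cortical diaphyseal bone this is not a practical case.

**Options.** `darkBone` inverts the polarity for inverted reconstructions;
`minSpeck` (default off) removes sub-threshold specks before component
selection; `minArea` warns when the surviving component is implausibly
small (e.g. a pure-noise image).

## Morphometry conventions

Coordinates are x = columns, y = rows, origin at the top-left pixel
centre, 0-based. Areas are pixel counts (reported both in px² and mm²
using the in-plane pixel size, default 4.8 µm — areas are *not* averaged
over neighbouring slices).

**Second moments of area.** Each pixel contributes unit area at its
centre plus its own 1/12 square self-moment, so single-row masks have a
nonzero minimum moment and rasterized shapes converge to the continuum
closed forms (for axis-aligned rectangles the pixel sums are exact). The
principal moments are the eigenvalues of the 2×2 tensor; PMI is the trace,
identically `i_min + i_max`.

**Cross-sectional thickness** uses the largest-inscribed-disk (local
thickness) model: the Euclidean distance transform supplies candidate
disk centres and radii; centres on the distance ridge (8-neighbourhood
local maxima) paint their diameters onto the pixels they cover, with each
pixel's own distance value as a floor. On lattice-aligned even-width
strips the estimate is exact; on odd widths it is +1 px; on curved walls
the bias is about +0.5–1 px. Phantom walls are 15–30 px, so the relative
bias stays in the few-percent range; this, plus the ~1–2% approximation of
using the nominal wall thickness as the analytic reference for an
offset-ellipse wall, is why the phantom thickness check uses a 6%
tolerance where other measures use 5%.

**Feret calipers** work on the convex hull of the pixel *corners* (so a
single pixel has extent 1): the maximum diameter is the largest hull
vertex distance, the minimum the smallest projection width over hull-edge
directions (rotating calipers). The *angle* of the maximum chord deserves
a note: chord length is quadratically flat around the major axis, so for a
smooth, mildly eccentric section the direction is intrinsically uncertain
by ±2–3° at these image sizes — no estimator faithful to the caliper
definition can do better, and empirical checks with parabolic and
fine-grid refinements confirm it. `sitespec` stabilizes the estimate by
averaging the directions of all chords within half a pixel of the maximum
(an axial circular mean). Real cortical sections are corner-stabilized
(the tibial crest pins the max chord), so the practical uncertainty on
scan data is far smaller than the smooth-ellipse worst case exercised by
the phantom.

This angle uncertainty has one visible consequence: orientation
normalization rotates the centroid path by the measured reference angle,
so an error δ leaks first-order into the *split* of the centroid deviation
between `dev_x` and `dev_y` while leaving the total deviation
`sqrt(dev_x² + dev_y²)` invariant (rotations preserve distances). The
rigid-placement invariance tests therefore check the total deviation at
2% of the bowing amplitude and the components at 1 px.

**Eccentricity** is `sqrt(1 - (feret_min/feret_max)²)`, the
major/minor-axis form bounded in [0, 1). The plain ratio variant is a
one-line change if a Bruker-style ratio is preferred, but the square-root
form is the default and the one validated here.

## Orientation, axis and curvature

Normalization rotates *coordinates*, never images, about the
reference-site centroid, so rotation-invariant scalars are untouched and
the operation is deterministic and idempotent. If the 37% site is missing
or breached the nearest measured site is used (with a warning). The
central axis is fitted through the 5%/95% centroids — those slices are
segmented on demand even though they lie outside the analyzed range — and
falls back to the outermost analyzed sites when an anchor cannot be
segmented; the anchors actually used are recorded in the CSV header.
Deviations are absolute values: the direction of curvature is deliberately
discarded, matching the semi-automated convention that makes bones
comparable regardless of scanner placement.

## Surface simulation

`perturbSurface` realizes simulated bone loss/apposition as uniform
one-pixel morphological layers restricted to one surface: cortex pixels
4-adjacent to background (periosteal) or to marrow (endosteal). A
4-connected (diamond) peel removes ≈0.89× the Euclidean perimeter per
layer, an 8-connected (box) peel ≈1.27×; the diamond is the closer
realization of "one uniform layer" and is the one used. On tibia-like
geometry a periosteal or endosteal layer costs relatively more PMI at the
proximal 37% site than at the distal 75% site — large, thin-walled,
eccentric sections concentrate their area far from the centroid — which is
the qualitative ordering the simulation reproduces; an identical-section
cylinder is the symmetry control.

## Statistics

The site model is estimated by REML (`lme4`) for paired designs and OLS
otherwise, with sum-to-zero contrasts and type-III Wald tests
(`car::Anova`) for the overall intervention and interaction terms.
Per-site intervention contrasts are computed directly from the
fixed-effect coefficients and their covariance (Wald z for mixed fits, t
with residual df for fixed fits), then Bonferroni-corrected by the number
of sites tested; the per-site map is only reported when the overall effect
is significant, mirroring the gated procedure. Singular random-effect fits
fall back to the fixed-effects model with a warning. Missing (breached)
values drop that site's row, never the mouse. The random-intercept
covariance structure is the deliberate default; an unstructured
within-mouse covariance is out of scope.

The power simulation replays the simulated-change design: sample n control
mice, duplicate their profiles ×(1 + effect) as the intervention limb of
the *same* mice, fit the mixed model, correct with Bonferroni. Sharing the
mice (rather than sampling disjoint groups) matches the way the simulated
intervention is constructed from control data and makes the contrast
within-mouse. With the default synthetic cohort (inter-mouse CV 5%,
residual CV 3%) a +10% change in cortical area is detected at p < 0.05
with n = 4, and at n = 6 essentially all 81 sites survive Bonferroni.

## The phantom

Every test runs against the synthetic phantom, whose cross-sections are
elliptical annuli (outer semi-axes a, b; inner semi-axes a−t, b−t) because
every target measure then has a closed form: areas π(ab−cd), πcd, πab;
principal moments π/4(a³b−c³d) and π/4(ab³−cd³); calipers 2a, 2b;
eccentricity √(1−(b/a)²); thickness ≈ t. The default geometry is
deliberately tibia-like and was fixed once from this closed-form analysis:
201 slices of 400×400 px; proximal sections large, thin-walled and
eccentric (a 125→76, b 100→70, wall 15→30 px from 0 to 100% site); a
gently drifting centroid path; section rotation 35°→5°; a solid fibula
approaching along a fixed direction and merging with the tibia at the 72%
site; Gaussian blur σ = 1 px for partial volume; additive Gaussian noise
with SD 5% of the bone–background contrast, clipped and quantized to
8-bit. Stacks are deterministic given the seed.

What the phantom does *not* emulate: trabecular texture, beam-hardening
and ring artifacts, a marrow-filled fibula, anatomically realistic
(non-elliptical, crested) section shapes, and absolute scale (sections
are roughly half the pixel dimensions of a 4.8 µm mouse-tibia scan, a
size chosen so the full suite runs in minutes on one CPU). Passing tests
therefore demonstrate the correctness of the geometry, the measurement
chain and the statistics on idealized cortical shapes — not robustness to
scanner artifacts. Ground truth at sites within ±2% of the junction is
excluded from tolerance checks (the merged fibula bump has no closed
form); the junction itself is validated by the component-count
transition.

## Problem sizes and runtime

The default validation runs analyze 81 sites of a 201-slice, 400 px
phantom (about 7 s per full pipeline pass), 100 mixed-model replicates for
each power setting, and 200 ordinary-least-squares replicates for the
type-I-error check — sizes chosen so the whole suite completes in a few
minutes on a single CPU while keeping every geometric feature (wall
thickness, eccentricity, junction) large enough in pixels for the stated
tolerances.

## Known limitations

- Only cortical bone is segmented; trabecular analysis is out of scope.
- BMP input is not supported (no reader available); PNG and TIFF are.
- GIF output is replaced by lossless PNG (no GIF writer available).
- The Feret angle of smooth near-circular sections is intrinsically noisy
  (see above); orientation normalization should use an eccentric
  reference site, as the 37% tibial site is in practice.
- Breach detection of concave-but-solid sections is conservative.
- The mixed model assumes a random intercept per mouse and homoscedastic
  residuals across sites; strongly heteroscedastic measures may warrant a
  variance-stabilizing transform before modeling.
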