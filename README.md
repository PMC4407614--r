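# sitespec

Site-specific cortical bone morphometry from micro-CT cross-sections.

Conventional cortical micro-CT analysis of mouse long bones summarizes one
or two operator-chosen regions of interest, yet cortical geometry changes
continuously along the bone: the proximal tibia is large, thin-walled and
eccentric, the distal tibia small, thick-walled and near-circular, and
interventions (loading, disuse, ovariectomy, aging) act at different
sites. `sitespec` analyzes the single reconstructed cross-section at
**every 1% site along the bone's length** (10–90%, 81 slices) and treats
site as an explicit factor in the statistics, producing whole-bone maps of
cortical geometry and of where an intervention acts.

It is intended for skeletal biologists and bone biomechanics researchers
working with reconstructed micro-CT slice stacks of rodent long bones.

## What it computes

Per site, from a deterministic segmentation (exact 1-D 2-means intensity
threshold, largest-component fibula exclusion, enclosed-cavity marrow
labeling with a breach flag):

- **Ct.Ar, Ma.Ar, Tt.Ar** — cortical, marrow and total cross-sectional
  area (px² and mm²); on a breached cortex Ma.Ar/Tt.Ar are undefined
  while Ct.Ar remains reliable;
- **Cs.Th** — mean cross-sectional thickness (largest-inscribed-disk local
  thickness);
- **IMin, IMax, PMI** — principal second moments of area about the
  centroid and the polar moment of inertia, PMI = IMin + IMax;
- **Feret max/min/angle, eccentricity** = √(1 − (Feret min/Feret max)²);
- **centroid and curvature** — after rotating all bones so the Feret angle
  at the 37% site is 0° (x = anterior–posterior, y = medial–lateral), the
  absolute centroid deviation |dev_x|, |dev_y| from the straight central
  axis through the 5% and 95% centroids.

Cohorts of such profiles feed a mixed model `value ~ site + group +
site:group` (random mouse intercept for paired limb designs), with
type-III Wald tests for the overall intervention and the
site-by-intervention interaction, Bonferroni-corrected per-site maps gated
on overall significance, and a simulated-change power analysis. A
morphological surface simulation quantifies how periosteal or endosteal
remodelling layers change PMI site by site. A synthetic tibia-like phantom
(elliptical-annulus sections with closed-form ground truth, a merging
fibula, partial-volume blur and noise) makes the entire pipeline testable
without scan data.

## Worked example

Analyze a bone (here the built-in phantom; for scan data use
`runSiteSpecificity(inPath = "path/to/slices", outPath = "output")`):

```r
library(sitespec)
gen <- generatePhantomStack(phantomSpec())
profile <- runSiteSpecificity(stack = gen$stack, verbose = TRUE)
#> phantom: 81 sites, 0 breached; axis anchors 5%/95%; ref site 37%
profile
#> BoneProfile 'phantom': 81 sites (10--90%), 0 breached,
#>   orientation normalized at 37% site
d <- profileData(profile)
d[d$site_pct %in% c(10, 37, 50, 75, 90),
  c("site_pct", "ct_ar", "ma_ar", "cs_th", "pmi", "eccentricity",
    "dev_x", "dev_y")]
#>  site_pct ct_ar ma_ar  cs_th       pmi eccentricity dev_x dev_y
#>        10 10187 31007 15.157 118715283        0.599 2.820 0.141
#>        37 10280 23910 16.816  96236456        0.578 9.992 0.146
#>        50 10397 18637 19.031  79617014        0.546 8.195 0.515
#>        75 11122  9454 25.850  53338194        0.435 1.039 0.575
#>        90 11081  7134 28.185  44832774        0.411 0.187 0.206
```

Reading the rows: the proximal 10% site has a thin cortex (Cs.Th ≈ 15 px)
around a large marrow cavity and a high polar moment of inertia; by the
90% site the wall has thickened to ≈ 28 px, the section is nearly
circular (eccentricity 0.41) and PMI has fallen by more than half —
exactly the proximal-to-distal gradient that single-site analyses cannot
see. `dev_x` peaks near mid-shaft: the phantom's bowed centroid path.
When `outPath` is given the run also writes `profile.csv` (one row per
site, provenance in `#` comment lines) and a lossless binarized image
`site_<pct>.png` per site.

Cohort statistics on a synthetic intervention:

```r
tab <- generateCohort(phantomSpec(), nMice = 6, groupEffects = 1.10,
                      paired = TRUE, seed = 1)
fit <- bonferroniPosthoc(fitSiteModel(tab, "ct_ar", paired = TRUE))
fit
#> SiteModelResult (mixed): overall p = 0, interaction p = 0.449
#>   80 of 81 sites significant after Bonferroni
```

A command-line front end is installed with the package
(`system.file("scripts", "sitespec.R", package = "sitespec")`) with
subcommands `analyze`, `phantom`, `simulate-surface` and `cohort-stats`.

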