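test_that("noiseless unblurred sections are exact two-level images", {
  spec <- cylinderSpec(blurSigma = 0, noiseSd = 0)
  cs <- crossSectionMask(spec, 50)
  expect_identical(sort(unique(as.vector(cs$image))), c(40L, 180L))
  expect_identical(cs$image == 180L, cs$bone)
  # segmentation of the noiseless section recovers the mask bit-exactly
  lab <- segmentSlice(cs$image, sitePct = 50)
  expect_identical(cortexMask(lab), cs$cortex)
})

test_that("the fibula is separate proximally and merges at the junction", {
  spec <- phantomSpec()
  pre <- crossSectionMask(spec, 40)
  expect_true(any(pre$fibula))
  expect_false(any(pre$fibula & pre$cortex))
  comp <- sitespec:::labelComponents8(pre$bone)
  expect_identical(max(comp), 2L)
  post <- crossSectionMask(spec, 80)
  expect_false(any(post$fibula))
  expect_identical(max(sitespec:::labelComponents8(post$bone)), 1L)
})

test_that("stack generation is deterministic given the seed", {
  spec <- smallSpec(nSlices = 12L, imageSize = 100L)
  s1 <- generatePhantomStack(spec)$stack
  s2 <- generatePhantomStack(spec)$stack
  for (i in seq_len(nSlices(s1)))
    expect_identical(slices(s1)[[i]], slices(s2)[[i]])
  # a different seed changes the noise realization
  s3 <- generatePhantomStack(smallSpec(nSlices = 12L, imageSize = 100L,
                                       seed = 999L))$stack
  expect_false(identical(slices(s1)[[1L]], slices(s3)[[1L]]))
})

test_that("ground-truth closed forms agree with numeric integration", {
  spec <- phantomSpec()
  gt <- phantomGroundTruth(spec, c(20, 37, 55, 75))
  # polar quadrature of the elliptical annulus: r(theta) per boundary
  th <- seq(0, 2 * pi, length.out = 2e5 + 1)[-1]
  dth <- th[2L] - th[1L]
  for (k in seq_len(nrow(gt))) {
    p <- sitespec:::phantomParams(spec, gt$site_pct[k])
    rOf <- function(a, b) a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    ro <- rOf(p$a, p$b); ri <- rOf(p$a - p$t, p$b - p$t)
    area <- sum(ro^2 - ri^2) / 2 * dth
    ixx <- sum((ro^4 - ri^4) * sin(th)^2) / 4 * dth
    iyy <- sum((ro^4 - ri^4) * cos(th)^2) / 4 * dth
    expect_rel(gt$ct_ar[k], area, 1e-6, "quadrature Ct.Ar")
    expect_rel(gt$i_min[k], ixx, 1e-6, "quadrature i_min")   # b < a: Ixx min
    expect_rel(gt$i_max[k], iyy, 1e-6, "quadrature i_max")
    expect_rel(gt$pmi[k], ixx + iyy, 1e-6, "quadrature pmi")
  }
})

test_that("the full pipeline tracks ground truth at every analysis site", {
  gen <- getDefaultStack()
  prof <- runSiteSpecificity(stack = gen$stack)
  d <- profileData(prof)
  gt <- gen$groundTruth
  expect_identical(nrow(d), 81L)
  keep <- !gt$in_junction_window     # merged-fibula sites have no closed form
  for (col in c("ct_ar", "ma_ar", "tt_ar", "i_min", "i_max", "pmi",
                "feret_max", "feret_min")) {
    relErr <- abs(d[[col]][keep] / gt[[col]][keep] - 1)
    expect_lt(max(relErr), 0.05)
  }
  expect_lt(max(abs(d$cs_th[keep] / gt$cs_th[keep] - 1)), 0.06)
  expect_lt(max(abs(d$eccentricity[keep] - gt$eccentricity[keep])), 0.03)
  # centroids: compare deviations in the normalized frame via ground truth
  expect_false(any(d$breached))
  .fixtureCache$defaultProfile <- prof
})

test_that("the tibia-fibula junction is recovered within 2% of length", {
  spec <- phantomSpec()
  nComp <- vapply(60:80, function(s) {
    cs <- crossSectionMask(spec, s)
    max(sitespec:::labelComponents8(binarizeSlice(cs$image)))
  }, integer(1L))
  detected <- (60:80)[which(nComp == 1L)[1L]]
  expect_lte(abs(detected - spec@fibula$junctionSite), 2)
})

test_that("pipeline accuracy improves with image resolution", {
  coarse <- cylinderSpec(radius = 30, wall = 8, imageSize = 100L,
                         nSlices = 11L)
  fine <- cylinderSpec(radius = 60, wall = 16, imageSize = 200L,
                       nSlices = 11L)
  err <- vapply(list(coarse, fine), function(sp) {
    lab <- segmentSlice(crossSectionMask(sp, 50)$image, sitePct = 50)
    gt <- phantomGroundTruth(sp, 50)
    abs(secondMoments(cortexMask(lab))$pmi / gt$pmi - 1)
  }, numeric(1L))
  expect_lt(err[2L], err[1L])
})

test_that("breach sites produce breached slices through the pipeline", {
  spec <- smallSpec(nSlices = 101L, imageSize = 200L, breachSites = 50)
  cs <- crossSectionMask(spec, 50)
  lab <- segmentSlice(cs$image, sitePct = 50)
  expect_true(breached(lab))
  intact <- segmentSlice(crossSectionMask(spec, 40)$image, sitePct = 40)
  expect_false(breached(intact))
})

test_that("cohort tables have the documented layout and scaling", {
  spec <- cylinderSpec()
  tab <- generateCohort(spec, nMice = 3, interMouseCv = 0, residualCv = 0,
                        paired = FALSE, seed = 1)
  expect_identical(nrow(tab), 2L * 3L * 81L)
  expect_setequal(unique(tab$group), c("control", "intervention"))
  # no noise, no effect: values equal the ground truth exactly
  gt <- phantomGroundTruth(spec)
  expect_equal(tab$value[tab$mouse_id == "c01"], gt$ct_ar)
  paired <- generateCohort(spec, nMice = 15, paired = TRUE, seed = 2)
  expect_identical(nrow(paired), 15L * 2L * 81L)
  expect_identical(length(unique(paired$mouse_id)), 15L)
  # an intervention multiplier acts multiplicatively on the right sites
  eff <- generateCohort(spec, nMice = 3, interMouseCv = 0, residualCv = 0,
                        groupEffects = 1.1, paired = TRUE, seed = 3)
  left <- eff$value[eff$limb == "left" & eff$mouse_id == "m01"]
  right <- eff$value[eff$limb == "right" & eff$mouse_id == "m01"]
  expect_equal(right, 1.1 * left, tolerance = 1e-12)
})
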