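test_that("area measures match closed forms and honour the breach rule", {
  ann <- rasterAnnulus(130, 65, 65, 50, 30)
  lab <- classifyCavity(ann)
  a <- areaMeasures(lab, voxelGeometry(4.8))
  expect_rel(a$ct_ar, pi * (50^2 - 30^2), 0.02, "Ct.Ar")
  expect_rel(a$ma_ar, pi * 30^2, 0.02, "Ma.Ar")
  expect_rel(a$tt_ar, pi * 50^2, 0.02, "Tt.Ar")
  expect_identical(a$tt_ar, a$ct_ar + a$ma_ar)
  expect_equal(a$ct_ar_mm2, a$ct_ar * (4.8 / 1000)^2)
  labC <- classifyCavity(rasterCShape(130, 65, 65, 50, 30))
  aC <- areaMeasures(labC)
  expect_true(is.na(aC$ma_ar) && is.na(aC$tt_ar))
  expect_gt(aC$ct_ar, 0)
})

test_that("centroid is exact and translation-equivariant", {
  d <- rasterDisk(130, 60, 40, 25)
  cen <- maskCentroid(d)
  expect_equal(unname(cen["x"]), 60, tolerance = 0.1)
  expect_equal(unname(cen["y"]), 40, tolerance = 0.1)
  px <- matrix(FALSE, 30, 30)
  px[21, 11] <- TRUE   # row 21 -> y = 20, col 11 -> x = 10
  expect_equal(unname(maskCentroid(px)), c(10, 20))
  shifted <- rasterDisk(130, 60 + 13, 40 + 7, 25)
  expect_equal(unname(maskCentroid(shifted) - cen), c(13, 7),
               tolerance = 1e-9)
  expect_error(maskCentroid(matrix(FALSE, 5, 5)), "empty")
})

test_that("second moments match closed forms and the rotation oracle", {
  d <- rasterDisk(130, 65, 65, 50)
  m <- secondMoments(d)
  expect_rel(m$i_min, pi * 50^4 / 4, 0.02, "disk i_min")
  expect_rel(m$i_max, pi * 50^4 / 4, 0.02, "disk i_max")
  expect_rel(m$pmi, pi * 50^4 / 2, 0.02, "disk pmi")
  ann <- rasterAnnulus(130, 65, 65, 50, 30)
  expect_rel(secondMoments(ann)$pmi, pi / 2 * (50^4 - 30^4), 0.02,
             "annulus pmi")
  # axis-aligned rectangles are exact against w h^3 / 12
  rect <- rasterRect(100, 41, 60, 11, 90)   # h = 20 rows, w = 80 cols
  mr <- secondMoments(rect)
  expect_equal(mr$i_min, 80 * 20^3 / 12, tolerance = 1e-12)
  expect_equal(mr$i_max, 20 * 80^3 / 12, tolerance = 1e-12)
  expect_equal(mr$principal_angle, 90)   # max bending resistance about y
  set.seed(11)
  for (i in 1:8) {
    blob <- randomBlob()
    if (sum(blob) < 10) next
    m <- secondMoments(blob)
    o <- bruteMoments(blob)
    # trace invariance is exact; principal values match exhaustive rotation
    expect_equal(m$pmi, o$ixx + o$iyy, tolerance = 1e-9)
    expect_equal(m$pmi, m$i_min + m$i_max, tolerance = 1e-9)
    expect_rel(m$i_min, o$i_min, 1e-4, "blob i_min")
    expect_rel(m$i_max, o$i_max, 1e-4, "blob i_max")
    # exact invariance under 90-degree rotation (transpose + flip)
    rot90 <- t(blob)[ncol(blob):1, ]
    m90 <- secondMoments(rot90)
    expect_equal(m90$i_min, m$i_min, tolerance = 1e-9)
    expect_equal(m90$i_max, m$i_max, tolerance = 1e-9)
  }
})

test_that("local thickness recovers strip and ring widths", {
  strip <- rasterRect(220, 101, 110, 11, 210)   # 10 x 200 px bar
  expect_rel(localThickness(strip), 10, 0.05, "strip thickness")
  ann <- rasterAnnulus(130, 65, 65, 50, 30)
  expect_rel(localThickness(ann), 20, 0.05, "ring thickness")
  # dilation strictly thickens
  expect_gt(localThickness(sitespec:::dilate8(ann)), localThickness(ann))
})

test_that("Feret calipers match ellipse closed forms and rotation search", {
  e0 <- rasterEllipse(160, 80, 80, 60, 30)
  f0 <- feretDiameters(e0)
  expect_rel(f0$feret_max, 120, 0.02, "ellipse feret max")
  expect_rel(f0$feret_min, 60, 0.02, "ellipse feret min")
  expect_lt(min(f0$feret_angle, 180 - f0$feret_angle), 1)
  e30 <- rasterEllipse(160, 80, 80, 60, 30, phiDeg = 30)
  f30 <- feretDiameters(e30)
  expect_equal(f30$feret_angle, 30, tolerance = 1)
  expect_rel(f30$feret_max, f0$feret_max, 0.01, "rotation-invariant max")
  expect_rel(f30$feret_min, f0$feret_min, 0.02, "rotation-invariant min")
  set.seed(23)
  for (i in 1:8) {
    blob <- randomBlob()
    if (sum(blob) < 5) next
    f <- feretDiameters(blob)
    o <- bruteFeret(blob)
    expect_rel(f$feret_max, o$feret_max, 0.005, "blob feret max vs brute")
    expect_rel(f$feret_min, o$feret_min, 0.005, "blob feret min vs brute")
  }
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_warning(fs <- feretDiameters(single), "single-pixel")
  expect_equal(fs$feret_max, 1)
  expect_equal(fs$feret_min, 1)
})

test_that("eccentricity follows the major/minor caliper formula", {
  expect_equal(feretEccentricity(100, 100), 0)
  expect_equal(feretEccentricity(120, 60), sqrt(3) / 2)
  # continuous limit toward circularity
  e <- feretEccentricity(100, 100 - 10^seq(-1, -6))
  expect_true(all(diff(e) < 0) && e[length(e)] < 1e-2)
  expect_error(feretEccentricity(10, 0), "positive")
  expect_error(feretEccentricity(5, 10), ">=")
})

test_that("measureSlice composes all fields and preserves Ct.Ar exactly", {
  spec <- phantomSpec()
  cs <- crossSectionMask(spec, 55)
  lab <- segmentSlice(cs$image, sitePct = 55)
  m <- measureSlice(lab)
  expect_identical(m$ct_ar, as.numeric(sum(cortexMask(lab))))
  expect_equal(m$pmi, m$i_min + m$i_max, tolerance = 1e-9)
  expect_false(any(is.na(unlist(m[c("ct_ar", "ma_ar", "tt_ar", "cs_th",
                                    "pmi", "feret_max", "eccentricity")]))))
  # breached slice: areas missing, cortex-based measures still present
  labC <- classifyCavity(rasterCShape(130, 65, 65, 50, 30), sitePct = 40)
  mC <- measureSlice(labC)
  expect_true(is.na(mC$ma_ar) && is.na(mC$tt_ar))
  expect_false(any(is.na(unlist(mC[c("ct_ar", "cs_th", "i_min", "i_max",
                                     "pmi", "feret_max", "feret_min")]))))
  expect_true(mC$breached)
})
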