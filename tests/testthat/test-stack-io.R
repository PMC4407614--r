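test_that("slice folders are read in natural sort order", {
  dir <- withr::local_tempdir()
  vals <- c(s1 = 10, s2 = 20, s3 = 30, s4 = 40, s5 = 50, s6 = 60,
            s7 = 70, s8 = 80, s9 = 90, s10 = 100, s20 = 110)
  for (nm in names(vals))
    png::writePNG(matrix(vals[[nm]] / 255, 8, 8),
                  file.path(dir, paste0(nm, ".png")))
  stk <- readStack(dir)
  expect_identical(nSlices(stk), 11L)
  got <- vapply(slices(stk), function(s) s[1, 1], integer(1L))
  expect_identical(got, as.integer(unname(vals[order(as.numeric(
    sub("s", "", names(vals))))])))
  # reversed flips the order
  stkR <- readStack(dir, reversed = TRUE)
  expect_identical(slices(stkR)[[1L]], slices(stk)[[11L]])
})

test_that("stack reading validates inputs and converts colour to luminance", {
  dir <- withr::local_tempdir()
  expect_error(readStack(dir), "no slices found")
  expect_error(readStack(file.path(dir, "nope")), "does not exist")
  for (i in 1:11)
    png::writePNG(matrix(0.5, 8, 8), file.path(dir, sprintf("a%02d.png", i)))
  png::writePNG(matrix(0.5, 9, 9), file.path(dir, "a12.png"))
  expect_error(readStack(dir), "inconsistent slice shape")
  # colour image collapses by Rec.709 luminance
  dir2 <- withr::local_tempdir()
  rgb <- array(0, c(8, 8, 3)); rgb[, , 1] <- 1   # pure red
  for (i in 1:11)
    png::writePNG(rgb, file.path(dir2, sprintf("c%02d.png", i)))
  stk <- readStack(dir2)
  expect_identical(slices(stk)[[1L]][1, 1], as.integer(round(0.2126 * 255)))
})

test_that("a phantom stack written to disk reads back pixel-identical", {
  spec <- smallSpec(nSlices = 15L, imageSize = 120L)
  dir <- withr::local_tempdir()
  writePhantomFolder(spec, dir)
  mem <- generatePhantomStack(spec)$stack
  disk <- readStack(dir)
  expect_identical(nSlices(disk), nSlices(mem))
  for (i in seq_len(nSlices(mem)))
    expect_identical(slices(disk)[[i]], slices(mem)[[i]])
})

test_that("binarized slice images round-trip the cortex mask exactly", {
  lab <- classifyCavity(rasterAnnulus(100, 50, 50, 40, 25))
  path <- withr::local_tempfile(fileext = ".png")
  writeBinarizedSlice(lab, path)
  back <- readBinarizedSlice(path)
  expect_identical(back, cortexMask(lab))
  expect_identical(dim(back), dim(labelMatrix(lab)))
  # all-background labeling writes a valid all-zero image
  empty <- new("CrossSectionLabeling",
               labels = matrix(0L, 20, 20), breached = TRUE,
               threshold = 1, sitePct = 50)
  writeBinarizedSlice(empty, path)
  expect_false(any(readBinarizedSlice(path)))
})

test_that("profile CSVs round-trip losslessly with breach-aware fields", {
  set.seed(5)
  d <- emptyProfileDataFilled()
  prof <- boneProfile(d, geometry = voxelGeometry(4.8),
                      sourceId = "test-bone",
                      anchors = data.frame(site = c(5, 95),
                                           x = c(100.25, 104.5),
                                           y = c(98.125, 97.75)))
  prof@refSite <- 37
  prof@normalized <- TRUE
  path <- withr::local_tempfile(fileext = ".csv")
  writeProfileCsv(prof, path)
  lines <- readLines(path)
  expect_identical(sum(!startsWith(lines, "#")) - 1L, 81L)  # 81 data rows
  back <- readProfileCsv(path)
  db <- profileData(back)
  for (col in setdiff(names(d), "breached")) {
    both <- !is.na(d[[col]]) & !is.na(db[[col]])
    expect_identical(is.na(d[[col]]), is.na(db[[col]]))
    if (any(both))
      expect_true(max(abs(db[[col]][both] / d[[col]][both] - 1),
                      na.rm = TRUE) <= 1e-12,
                  label = sprintf("column %s within 1e-12", col))
  }
  expect_identical(db$breached, d$breached)
  # breached rows have empty Ma.Ar/Tt.Ar fields but populated Ct.Ar
  bi <- which(d$breached)
  expect_true(all(is.na(db$ma_ar[bi])) && all(is.na(db$tt_ar[bi])))
  expect_true(all(!is.na(db$ct_ar[bi])))
  expect_identical(back@refSite, 37)
  expect_true(back@normalized)
  expect_equal(anchorPoints(back), anchorPoints(prof))
  expect_equal(pixelSize(geometry(back)), 4.8)
})

test_that("profile CSV reading tolerates extras and reports missing columns", {
  d <- emptyProfileDataFilled()
  prof <- boneProfile(d)
  path <- withr::local_tempfile(fileext = ".csv")
  writeProfileCsv(prof, path)
  lines <- readLines(path)
  hdrAt <- which(!startsWith(lines, "#"))[1L]
  lines[hdrAt] <- paste0(lines[hdrAt], ",mystery")
  lines[(hdrAt + 1L):length(lines)] <-
    paste0(lines[(hdrAt + 1L):length(lines)], ",42")
  writeLines(lines, path)
  expect_warning(back <- readProfileCsv(path), "mystery")
  expect_identical(nrow(profileData(back)), 81L)
  # a schema-violating file names what is missing
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("site_pct,ct_ar\n10,100", bad)
  expect_error(readProfileCsv(bad), "pmi")
})

test_that("a hand-written three-row profile reads as three sites", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# pixel_size_um: 10",
    paste(sitespec:::csvColumns(), collapse = ","),
    "10,50,1000,500,1500,12,1e6,2e6,3e6,100,101,120,60,0,0.866,0.1,0.2,FALSE,0.1,0.05,0.15",
    "11,55,1010,,,12.5,1.1e6,2.1e6,3.2e6,100,101,120,60,1,0.866,0.1,0.2,TRUE,0.101,,",
    "12,61,1020,510,1530,13,1.2e6,2.2e6,3.4e6,100,101,120,60,2,0.866,0.1,0.2,FALSE,0.102,0.051,0.153"),
    path)
  prof <- readProfileCsv(path)
  d <- profileData(prof)
  expect_identical(nrow(d), 3L)
  expect_identical(d$site_pct, c(10, 11, 12))
  expect_true(is.na(d$ma_ar[2]) && d$breached[2])
  expect_equal(pixelSize(geometry(prof)), 10)
})
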