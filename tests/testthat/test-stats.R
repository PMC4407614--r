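test_that("cohort assembly produces the long layout and flags duplicates", {
  set.seed(31)
  profs <- list(boneProfile(emptyProfileDataFilled()),
                boneProfile(emptyProfileDataFilled()))
  meta <- data.frame(mouse_id = c("m1", "m2"), limb = "left",
                     group = c("control", "intervention"))
  tab <- buildCohortTable(profs, meta, measures = "ct_ar")
  expect_identical(nrow(tab), 2L * 81L)
  expect_identical(unique(tab$measure_name), "ct_ar")
  # breached sites keep their rows with missing values
  tab2 <- buildCohortTable(profs, meta, measures = "ma_ar")
  expect_identical(sum(is.na(tab2$value)), 2L * 3L)
  metaDup <- data.frame(mouse_id = "m1", limb = "left",
                        group = c("control", "intervention"))
  expect_error(buildCohortTable(profs, metaDup), "duplicate")
  # paired full layout: 15 mice x 2 limbs x 81 sites x 2 measures
  specs <- generateCohort(cylinderSpec(), nMice = 15, paired = TRUE,
                          measures = c("ct_ar", "pmi"), seed = 4)
  expect_identical(nrow(specs), 15L * 2L * 81L * 2L)
})

test_that("Bonferroni arithmetic, gating and monotonicity are exact", {
  ps <- data.frame(site_pct = 1:3, estimate = 1, se = 1,
                   raw_p = c(0.0001, 0.009, 0.9),
                   bonferroni_p = NA_real_, significant = NA)
  res <- new("SiteModelResult", overallP = 0.001, interactionP = 0.5,
             perSite = ps, nSitesTested = 81L, meta = list(model = "fixed"))
  out <- bonferroniPosthoc(res)
  expect_equal(perSiteResults(out)$bonferroni_p, c(0.0081, 0.729, 1))
  expect_identical(perSiteResults(out)$significant, c(TRUE, FALSE, FALSE))
  # the per-site map is not applicable when the overall test fails the gate
  res@overallP <- 0.2
  gated <- bonferroniPosthoc(res)
  expect_true(all(is.na(perSiteResults(gated)$significant)))
  # significant-site sets shrink (or stay) as the site count grows
  for (n in c(5L, 20L, 81L)) {
    res@nSitesTested <- n
    res@overallP <- 0.001
    sig <- sum(perSiteResults(bonferroniPosthoc(res))$significant)
    if (n == 5L) expect_identical(sig, 2L)
    if (n >= 20L) expect_identical(sig, 1L)
  }
})

test_that("a uniform effect is detected overall but not as an interaction", {
  tab <- generateCohort(cylinderSpec(), nMice = 6, interMouseCv = 0,
                        residualCv = 0.03, groupEffects = 1.10,
                        paired = FALSE, seed = 11)
  fit <- fitSiteModel(tab, "ct_ar", paired = FALSE)
  expect_lt(overallP(fit), 1e-6)
  expect_gt(interactionP(fit), 0.05)
  fit <- bonferroniPosthoc(fit)
  ps <- perSiteResults(fit)
  # the effect estimate recovers +10% of the flat profile at every site
  base <- phantomGroundTruth(cylinderSpec(), 50)$ct_ar
  expect_rel(mean(ps$estimate), 0.1 * base, 0.05, "mean effect estimate")
  # significant sites form the contiguous run expected of a uniform effect
  expect_gt(mean(ps$significant), 0.9)
})

test_that("a site-localized effect produces a significant interaction", {
  eff <- controlPoints(c(10, 40, 41, 90), c(1.10, 1.10, 1, 1))
  tab <- generateCohort(cylinderSpec(), nMice = 6, interMouseCv = 0,
                        residualCv = 0.03, groupEffects = eff,
                        paired = FALSE, seed = 12)
  fit <- bonferroniPosthoc(fitSiteModel(tab, "ct_ar"))
  expect_lt(interactionP(fit), 0.05)
  ps <- perSiteResults(fit)
  # the affected proximal run is flagged, the distal run is not
  expect_gt(mean(ps$significant[ps$site_pct <= 40]), 0.8)
  expect_lt(mean(ps$significant[ps$site_pct > 45]), 0.1)
})

test_that("pairing reduces the group-contrast standard error", {
  tab <- generateCohort(cylinderSpec(), nMice = 8, interMouseCv = 0.08,
                        residualCv = 0.02, groupEffects = 1.05,
                        paired = TRUE, seed = 13)
  fitPaired <- fitSiteModel(tab, "ct_ar", paired = TRUE)
  fitIgnoring <- fitSiteModel(tab, "ct_ar", paired = FALSE)
  expect_identical(fitPaired@meta$model, "mixed")
  expect_lt(mean(perSiteResults(fitPaired)$se),
            mean(perSiteResults(fitIgnoring)$se))
})

test_that("model preconditions are enforced", {
  tab <- generateCohort(cylinderSpec(), nMice = 2, seed = 14)
  expect_error(fitSiteModel(tab, "nope"), "no data")
  oneGroup <- tab[tab$group == "control", ]
  expect_error(fitSiteModel(oneGroup, "ct_ar"), "two groups")
  oneSite <- tab[tab$site_pct == 50, ]
  expect_error(fitSiteModel(oneSite, "ct_ar"), "two sites")
})

test_that("a null power simulation stays at the nominal rate", {
  tab <- generateCohort(cylinderSpec(), nMice = 8, interMouseCv = 0.05,
                        residualCv = 0.03, paired = FALSE, seed = 15)
  ctrl <- tab[tab$group == "control", ]
  pw <- powerSimulation(ctrl, effect = 0, nPerGroup = 4, nReps = 12,
                        seed = 16)
  expect_lte(pw$meanFractionSitesSignificant, 0.05)
  expect_gt(pw$medianOverallP, 0.05)
  # strong effect with low noise saturates the site map
  pw2 <- powerSimulation(ctrl, effect = 0.5, nPerGroup = 6, nReps = 5,
                         seed = 17)
  expect_gt(pw2$meanFractionSitesSignificant, 0.99)
  expect_error(powerSimulation(ctrl, nPerGroup = 20, nReps = 2, seed = 1),
               "exceeds")
  expect_error(powerSimulation(ctrl, nPerGroup = 4, nReps = 2), "seed")
})
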