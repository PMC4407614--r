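# Synthetic tibia-like phantom: grayscale stacks and cohorts with known
# analytic ground truth, standing in for scan data in every test.

#' Construct a phantom parameter set
#'
#' The default phantom emulates a young mouse tibia scaled to a compact
#' image: cross-sections are elliptical annuli that are large, relatively
#' thin-walled and eccentric proximally and smaller, thicker-walled and
#' near-circular distally; the centroid drifts gently along the bone; a
#' smaller solid fibula runs alongside, approaches the tibia and merges
#' with it at the junction site (72% by default); partial-volume blur and
#' additive intensity noise finish the image. Every default was chosen from
#' the closed-form geometry so that all target measures have analytic
#' ground truth.
#'
#' @param nSlices slices per stack.
#' @param imageSize square image edge, px.
#' @param outerA,outerB,wall,offsetX,offsetY,rotationDeg control-point
#'   tables \code{controlPoints(site, value)} interpolated over percent
#'   site: outer semi-axes (px), wall thickness (px; the inner ellipse has
#'   semi-axes outer - wall), centroid offset from the image centre (px)
#'   and in-plane section rotation (degrees).
#' @param fibula list with semi-axes \code{a}, \code{b} (px), approach
#'   direction \code{angleDeg}, \code{gap} control points (px clearance
#'   between the shells, negative = overlapping/merged) and
#'   \code{junctionSite} (percent).
#' @param blurSigma Gaussian partial-volume blur, px.
#' @param noiseSd additive Gaussian noise SD on the 0--255 intensity scale
#'   (default 5% of the bone-background contrast).
#' @param boneIntensity,backgroundIntensity two-level intensities.
#' @param breachSites percent sites with a wedge-shaped cortical gap cut.
#' @param seed RNG seed for the noise.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(nSlices = 201L,
                        imageSize = 400L,
                        outerA = controlPoints(c(0, 25, 50, 75, 100),
                                               c(130, 125, 105, 85, 76)),
                        outerB = controlPoints(c(0, 25, 50, 75, 100),
                                               c(104, 100, 88, 77, 70)),
                        wall = controlPoints(c(0, 25, 50, 75, 100),
                                             c(15, 15, 19, 26, 30)),
                        offsetX = controlPoints(c(0, 25, 50, 75, 100),
                                                c(-2, 10, 6, -2, -4)),
                        offsetY = controlPoints(c(0, 25, 50, 75, 100),
                                                c(0, 6, 3, 0, -2)),
                        rotationDeg = controlPoints(c(0, 25, 50, 75, 100),
                                                    c(35, 30, 18, 8, 5)),
                        fibula = list(a = 14, b = 12, angleDeg = -40,
                                      gap = controlPoints(
                                        c(0, 69, 70, 74, 100),
                                        c(30, 3, -2, -16, -16)),
                                      junctionSite = 72),
                        blurSigma = 1,
                        noiseSd = 7,
                        boneIntensity = 180,
                        backgroundIntensity = 40,
                        breachSites = numeric(0),
                        seed = 20260921L) {
  new("PhantomSpec", nSlices = as.integer(nSlices),
      imageSize = as.integer(imageSize), outerA = outerA, outerB = outerB,
      wall = wall, offsetX = offsetX, offsetY = offsetY,
      rotationDeg = rotationDeg, fibula = fibula, blurSigma = blurSigma,
      noiseSd = noiseSd, boneIntensity = boneIntensity,
      backgroundIntensity = backgroundIntensity,
      breachSites = as.numeric(breachSites), seed = as.integer(seed))
}

#' A circular-cylinder phantom (identical sections, no fibula)
#'
#' Symmetry control for the surface simulation: every cross-section is the
#' same centred circular annulus, so any surface perturbation must change
#' PMI equally at all sites.
#'
#' @param radius outer radius, px.
#' @param wall wall thickness, px.
#' @param ... further arguments passed to \code{\link{phantomSpec}}.
#' @inheritParams phantomSpec
#' @return A \linkS4class{PhantomSpec}.
#' @export
cylinderSpec <- function(radius = 60, wall = 15, nSlices = 201L,
                         imageSize = 200L, ...) {
  cp <- function(v) controlPoints(c(0, 100), c(v, v))
  phantomSpec(nSlices = nSlices, imageSize = imageSize,
              outerA = cp(radius), outerB = cp(radius), wall = cp(wall),
              offsetX = cp(0), offsetY = cp(0), rotationDeg = cp(0),
              fibula = list(a = 0, b = 0, angleDeg = 0,
                            gap = cp(1e6), junctionSite = 50),
              ...)
}

phantomParams <- function(spec, sitePct) {
  list(a = interpControl(spec@outerA, sitePct),
       b = interpControl(spec@outerB, sitePct),
       t = interpControl(spec@wall, sitePct),
       ox = interpControl(spec@offsetX, sitePct),
       oy = interpControl(spec@offsetY, sitePct),
       rot = interpControl(spec@rotationDeg, sitePct),
       fibGap = interpControl(spec@fibula$gap, sitePct))
}

fibulaPresent <- function(spec, sitePct) {
  spec@fibula$a > 0 & sitePct <= spec@fibula$junctionSite + 2
}

fibulaCenter <- function(spec, sitePct) {
  p <- phantomParams(spec, sitePct)
  cen <- (spec@imageSize - 1) / 2
  d <- p$a + spec@fibula$a + p$fibGap
  al <- spec@fibula$angleDeg * pi / 180
  c(x = cen + p$ox + d * cos(al), y = cen + p$oy + d * sin(al))
}

#' Rasterize one phantom cross-section
#'
#' Builds the noiseless label masks (cortex annulus, optional fibula, any
#' breach wedge) and the corresponding grayscale image after blur and
#' noise. Noise is only applied when the call happens inside a seeded
#' stack generation; called directly, the image is blurred but noise-free
#' unless \code{noise} is TRUE.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param sitePct percent site.
#' @param noise add seeded Gaussian noise (uses the current RNG state).
#' @return list with \code{image} (integer matrix), \code{cortex},
#'   \code{bone}, \code{fibula} logical ground-truth masks.
#' @export
crossSectionMask <- function(spec, sitePct, noise = FALSE) {
  stopifnot(is(spec, "PhantomSpec"))
  p <- phantomParams(spec, sitePct)
  S <- spec@imageSize
  cen <- (S - 1) / 2
  cx <- cen + p$ox; cy <- cen + p$oy
  X <- matrix(rep(0:(S - 1L), each = S), nrow = S)   # x = column index
  Y <- matrix(rep(0:(S - 1L), times = S), nrow = S)  # y = row index
  th <- p$rot * pi / 180
  dx <- X - cx; dy <- Y - cy
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  outer <- (xr / p$a)^2 + (yr / p$b)^2 <= 1
  inner <- (xr / (p$a - p$t))^2 + (yr / (p$b - p$t))^2 <= 1
  cortex <- outer & !inner
  if (length(spec@breachSites) &&
      any(abs(spec@breachSites - sitePct) < 0.5)) {
    ang <- atan2(yr, xr)                      # wedge cut in the section frame
    cortex[abs(ang) < (7.5 * pi / 180)] <- FALSE
  }
  fib <- matrix(FALSE, S, S)
  if (fibulaPresent(spec, sitePct)) {
    fc <- fibulaCenter(spec, sitePct)
    fib <- ((X - fc["x"]) / spec@fibula$a)^2 +
           ((Y - fc["y"]) / spec@fibula$b)^2 <= 1
  }
  bone <- cortex | fib
  img <- spec@backgroundIntensity +
    (spec@boneIntensity - spec@backgroundIntensity) * bone
  if (spec@blurSigma > 0)
    img <- gaussianBlur(img, spec@blurSigma)
  if (noise && spec@noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, spec@noiseSd)
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), nrow = S)
  list(image = img, cortex = cortex, bone = bone, fibula = fib)
}

#' Analytic ground truth of the phantom at given sites
#'
#' Closed forms for the elliptical annulus with outer semi-axes (a, b) and
#' inner semi-axes (a - t, b - t): areas pi(ab - cd), pi*cd, pi*ab;
#' principal second moments pi/4 (a^3 b - c^3 d) and pi/4 (a b^3 - c d^3)
#' (rotation-invariant); Feret diameters 2a and 2b; eccentricity
#' sqrt(1 - (b/a)^2). The wall thickness t is reported as the thickness
#' ground truth; for the mild eccentricities used this approximates the
#' mean local thickness of the similar-offset wall to within about 1-2%.
#' Sites within +/-2% of the tibia-fibula junction are flagged
#' \code{in_junction_window}: there the merged fibula adds area with no
#' closed form, so tolerance checks should skip them.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param sites percent sites (default the 81 analysis sites).
#' @return data.frame of per-site ground-truth measures.
#' @export
phantomGroundTruth <- function(spec, sites = 10:90) {
  p <- phantomParams(spec, sites)
  cen <- (spec@imageSize - 1) / 2
  a <- p$a; b <- p$b; cc <- p$a - p$t; d <- p$b - p$t
  breach <- if (length(spec@breachSites))
    vapply(sites, function(s) any(abs(spec@breachSites - s) < 0.5),
           logical(1L)) else rep(FALSE, length(sites))
  data.frame(
    site_pct = as.numeric(sites),
    ct_ar = pi * (a * b - cc * d),
    ma_ar = ifelse(breach, NA_real_, pi * cc * d),
    tt_ar = ifelse(breach, NA_real_, pi * a * b),
    cs_th = p$t,
    i_min = pi / 4 * (a * b^3 - cc * d^3),
    i_max = pi / 4 * (a^3 * b - cc^3 * d),
    pmi = pi / 4 * (a * b^3 - cc * d^3) + pi / 4 * (a^3 * b - cc^3 * d),
    centroid_x = cen + p$ox,
    centroid_y = cen + p$oy,
    feret_max = 2 * a,
    feret_min = 2 * b,
    feret_angle = p$rot %% 180,
    eccentricity = sqrt(1 - (b / a)^2),
    in_junction_window = spec@fibula$a > 0 &
      abs(sites - spec@fibula$junctionSite) <= 2,
    breached = breach)
}

#' Generate a full phantom image stack with its ground truth
#'
#' Deterministic given the spec's seed: the same spec always yields a
#' bit-identical stack. Slice i sits at site 100 * (i - 1) / (nSlices - 1).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param sourceId bone identifier for the stack.
#' @return list with \code{stack} (an \linkS4class{ImageStack}),
#'   \code{groundTruth} (see \code{\link{phantomGroundTruth}}).
#' @export
generatePhantomStack <- function(spec, sourceId = "phantom") {
  stopifnot(is(spec, "PhantomSpec"))
  n <- spec@nSlices
  slicesList <- withLocalSeed(spec@seed, {
    lapply(seq_len(n), function(i) {
      site <- 100 * (i - 1) / (n - 1)
      crossSectionMask(spec, site, noise = TRUE)$image
    })
  })
  list(stack = imageStack(slicesList, sourceId = sourceId),
       groundTruth = phantomGroundTruth(spec))
}

#' Write a phantom stack to disk in the slice-folder layout
#'
#' Emits slice_0001.png ... plus a ground_truth.csv, producing an "in
#' path" folder that \code{\link{readStack}} and the command-line tool can
#' consume directly.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param folder output directory (created if needed).
#' @return the folder, invisibly.
#' @export
writePhantomFolder <- function(spec, folder) {
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  gen <- generatePhantomStack(spec)
  sl <- slices(gen$stack)
  for (i in seq_along(sl))
    png::writePNG(sl[[i]] / 255,
                  file.path(folder, sprintf("slice_%04d.png", i)))
  utils::write.csv(gen$groundTruth, file.path(folder, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(folder)
}

resolveGroupEffect <- function(groupEffects, measure, sites) {
  if (is.null(groupEffects)) return(rep(1, length(sites)))
  ge <- if (is.list(groupEffects) && !is.data.frame(groupEffects))
    groupEffects[[measure]] else groupEffects
  if (is.null(ge)) return(rep(1, length(sites)))
  if (is.data.frame(ge)) return(interpControl(ge, sites))
  rep(as.numeric(ge), length.out = length(sites))
}

#' Generate a synthetic cohort table from a phantom spec
#'
#' Fast table mode for statistical simulation: per-site base values come
#' from the phantom's analytic ground truth, each mouse gets a lognormal
#' multiplicative scale (coefficient of variation \code{interMouseCv}),
#' group effects multiply the intervention values site by site, and
#' independent lognormal residual noise (\code{residualCv}) is added per
#' observation. With \code{paired = TRUE} each mouse contributes a control
#' left limb and an intervention right limb sharing the mouse scale (the
#' loaded/disused-limb design); otherwise control and intervention groups
#' are disjoint sets of \code{nMice} mice each.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nMice mice per group (>= 2).
#' @param interMouseCv coefficient of variation of the per-mouse scale.
#' @param residualCv coefficient of variation of per-observation noise.
#' @param groupEffects per-measure site-profile multipliers: a scalar, a
#'   \code{controlPoints} table, or a named list of either keyed by
#'   measure; NULL = no effect.
#' @param paired paired (two-limb) or independent-groups design.
#' @param measures measure names to emit (columns of the ground truth).
#' @param sites percent sites.
#' @param seed RNG seed.
#' @return long-format data.frame (mouse_id, limb, group, site_pct,
#'   measure_name, value).
#' @export
generateCohort <- function(spec, nMice, interMouseCv = 0.05,
                           residualCv = 0.03, groupEffects = NULL,
                           paired = FALSE, measures = "ct_ar",
                           sites = 10:90, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"), nMice >= 2)
  gt <- phantomGroundTruth(spec, sites)
  bad <- setdiff(measures, names(gt))
  if (length(bad)) stop(paste("unknown measures:", paste(bad, collapse = ", ")))
  sdlog <- function(cv) sqrt(log(1 + cv^2))
  withLocalSeed(seed, {
    mouseRows <- if (paired) {
      ids <- sprintf("m%02d", seq_len(nMice))
      data.frame(mouse_id = rep(ids, each = 2L),
                 limb = rep(c("left", "right"), nMice),
                 group = rep(c("control", "intervention"), nMice))
    } else {
      data.frame(mouse_id = c(sprintf("c%02d", seq_len(nMice)),
                              sprintf("i%02d", seq_len(nMice))),
                 limb = "left",
                 group = rep(c("control", "intervention"), each = nMice))
    }
    uniqueMice <- unique(mouseRows$mouse_id)
    scale <- stats::setNames(
      exp(stats::rnorm(length(uniqueMice), -sdlog(interMouseCv)^2 / 2,
                       sdlog(interMouseCv))), uniqueMice)
    out <- list()
    for (m in measures) {
      base <- gt[[m]]
      eff <- resolveGroupEffect(groupEffects, m, sites)
      for (r in seq_len(nrow(mouseRows))) {
        mult <- if (mouseRows$group[r] == "intervention") eff else 1
        noise <- exp(stats::rnorm(length(sites), -sdlog(residualCv)^2 / 2,
                                  sdlog(residualCv)))
        out[[length(out) + 1L]] <- data.frame(
          mouse_id = mouseRows$mouse_id[r], limb = mouseRows$limb[r],
          group = mouseRows$group[r], site_pct = as.numeric(sites),
          measure_name = m,
          value = base * scale[[mouseRows$mouse_id[r]]] * mult * noise)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
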