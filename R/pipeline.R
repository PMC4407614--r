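# End-to-end orchestration: in-path folder -> per-site segmentation and
# morphometry -> orientation normalization -> central axis and deviations
# -> output folder (collated CSV + binarized per-site images).

#' Run the full site-specificity analysis on one bone
#'
#' Reads (or takes) an image stack, selects the slice at each 1% site in
#' the analyzed range, segments it into background/cortex/marrow, measures
#' all per-slice scalars, normalizes orientation to the reference-site
#' Feret angle, fits the central axis through the anchor-site centroids
#' (segmenting the 5%/95% slices on demand) and computes the absolute
#' centroid deviations. When \code{outPath} is given, the collated CSV
#' (\code{profile.csv}) and one binarized image per site
#' (\code{site_<pct>.png}) are written there. The whole run is
#' deterministic: re-analysis of the same stack yields byte-identical
#' output.
#'
#' @param inPath folder of slice images (ignored when \code{stack} given).
#' @param stack an \linkS4class{ImageStack} to analyze directly.
#' @param outPath output folder (created if needed); NULL = no files.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @param siteMin,siteMax analyzed percent range (default 10--90).
#' @param refSite orientation reference site (default 37).
#' @param axisAnchors c(lo, hi) anchor percent sites (default c(5, 95));
#'   if an anchor slice cannot be segmented the fit falls back to the
#'   outermost analyzed sites.
#' @param pattern filename glob for \code{\link{readStack}}.
#' @param reversed flip slice order (export direction convention).
#' @param darkBone,minSpeck,minArea segmentation options (see
#'   \code{\link{segmentSlice}}).
#' @param verbose log a one-line summary.
#' @return the \linkS4class{BoneProfile}, invisibly when writing files.
#' @export
runSiteSpecificity <- function(inPath = NULL, stack = NULL, outPath = NULL,
                               geometry = voxelGeometry(),
                               siteMin = 10L, siteMax = 90L, refSite = 37,
                               axisAnchors = c(5, 95), pattern = "*",
                               reversed = FALSE, darkBone = FALSE,
                               minSpeck = 0L, minArea = 0L,
                               verbose = FALSE) {
  if (is.null(stack)) {
    if (is.null(inPath)) stop("provide either inPath or stack")
    stack <- readStack(inPath, pattern = pattern, geometry = geometry,
                       reversed = reversed)
  }
  geometry <- geometry(stack)
  n <- nSlices(stack)
  plan <- selectAnalysisSites(n, siteMin, siteMax)
  if (!is.null(outPath))
    dir.create(outPath, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(plan$sites))
  for (k in seq_along(plan$sites)) {
    site <- plan$sites[k]
    idx <- plan$indexOf[[k]]
    lab <- tryCatch(
      segmentSlice(slices(stack)[[idx + 1L]], sitePct = site,
                   darkBone = darkBone, minSpeck = minSpeck,
                   minArea = minArea),
      error = function(e) stop(sprintf(
        "segmentation failed at site %g%% (slice %d): %s", site, idx,
        conditionMessage(e)), call. = FALSE))
    row <- measureSlice(lab, geometry)
    row$slice_index <- idx
    rows[[k]] <- row
    if (!is.null(outPath))
      writeBinarizedSlice(lab, file.path(outPath,
                                         sprintf("site_%02d.png", site)))
  }
  d <- do.call(rbind, rows)
  # anchor centroids for the central axis (sites outside the analysis range
  # are segmented on demand)
  anchors <- data.frame(site = numeric(0), x = numeric(0), y = numeric(0))
  for (s in axisAnchors) {
    cen <- tryCatch({
      hit <- which(d$site_pct == s)
      if (length(hit)) {
        c(d$centroid_x[hit[1L]], d$centroid_y[hit[1L]])
      } else {
        idx <- siteToSliceIndex(n, s)
        lab <- segmentSlice(slices(stack)[[idx + 1L]], sitePct = s,
                            darkBone = darkBone, minSpeck = minSpeck)
        unname(maskCentroid(labelMatrix(lab) == LBL_CORTEX))
      }
    }, error = function(e) NULL)
    if (!is.null(cen))
      anchors <- rbind(anchors, data.frame(site = s, x = cen[1L],
                                           y = cen[2L]))
  }
  profile <- boneProfile(d, geometry = geometry, sourceId = sourceId(stack),
                         anchors = anchors)
  profile <- normalizeOrientation(profile, referenceSite = refSite)
  axis <- fitCentralAxis(profile, lo = axisAnchors[1L], hi = axisAnchors[2L])
  dev <- centroidDeviation(profile, axis)
  profile@data$dev_x <- dev$dev_x
  profile@data$dev_y <- dev$dev_y
  if (verbose)
    message(sprintf(
      "%s: %d sites, %d breached; axis anchors %g%%/%g%%; ref site %g%%",
      sourceId(stack), nrow(d), sum(d$breached), axis@anchorLo[1L],
      axis@anchorHi[1L], profile@refSite))
  if (!is.null(outPath)) {
    writeProfileCsv(profile, file.path(outPath, "profile.csv"))
    return(invisible(profile))
  }
  profile
}
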