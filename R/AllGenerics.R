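#' @rdname ImageStack-class
#' @param object,x an object.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname ImageStack-class
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))

#' @rdname VoxelGeometry-class
#' @param x an object carrying voxel geometry.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname VoxelGeometry-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname CrossSectionLabeling-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname CrossSectionLabeling-class
#' @export
setGeneric("breached", function(x) standardGeneric("breached"))

#' @rdname CrossSectionLabeling-class
#' @export
setGeneric("cortexMask", function(x) standardGeneric("cortexMask"))

#' @rdname CrossSectionLabeling-class
#' @export
setGeneric("marrowMask", function(x) standardGeneric("marrowMask"))

#' @rdname BoneProfile-class
#' @export
setGeneric("profileData", function(x) standardGeneric("profileData"))

#' @rdname BoneProfile-class
#' @export
setGeneric("anchorPoints", function(x) standardGeneric("anchorPoints"))

#' @rdname BoneProfile-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname SiteModelResult-class
#' @export
setGeneric("perSiteResults", function(x) standardGeneric("perSiteResults"))

#' @rdname SiteModelResult-class
#' @export
setGeneric("overallP", function(x) standardGeneric("overallP"))

#' @rdname SiteModelResult-class
#' @export
setGeneric("interactionP", function(x) standardGeneric("interactionP"))

# ---- accessor methods ----

#' @rdname ImageStack-class
#' @export
setMethod("nSlices", "ImageStack", function(x) length(x@slices))

#' @rdname ImageStack-class
#' @export
setMethod("slices", "ImageStack", function(x) x@slices)

#' @rdname VoxelGeometry-class
#' @export
setMethod("geometry", "ImageStack", function(x) x@geometry)

#' @rdname VoxelGeometry-class
#' @export
setMethod("geometry", "BoneProfile", function(x) x@geometry)

#' @rdname VoxelGeometry-class
#' @export
setMethod("pixelSize", "VoxelGeometry", function(x) x@pixelSize)

#' @rdname VoxelGeometry-class
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@geometry@pixelSize)

#' @rdname ImageStack-class
#' @export
setMethod("sourceId", "ImageStack", function(x) x@sourceId)

#' @rdname ImageStack-class
#' @export
setMethod("sourceId", "BoneProfile", function(x) x@sourceId)

#' @rdname CrossSectionLabeling-class
#' @export
setMethod("labelMatrix", "CrossSectionLabeling", function(x) x@labels)

#' @rdname CrossSectionLabeling-class
#' @export
setMethod("breached", "CrossSectionLabeling", function(x) x@breached)

#' @rdname CrossSectionLabeling-class
#' @export
setMethod("cortexMask", "CrossSectionLabeling",
          function(x) x@labels == LBL_CORTEX)

#' @rdname CrossSectionLabeling-class
#' @export
setMethod("marrowMask", "CrossSectionLabeling",
          function(x) x@labels == LBL_MARROW)

#' @rdname BoneProfile-class
#' @export
setMethod("profileData", "BoneProfile", function(x) x@data)

#' @rdname BoneProfile-class
#' @export
setMethod("anchorPoints", "BoneProfile", function(x) x@anchors)

#' @rdname BoneProfile-class
#' @export
setMethod("isNormalized", "BoneProfile", function(x) x@normalized)

#' @rdname SiteModelResult-class
#' @export
setMethod("perSiteResults", "SiteModelResult", function(x) x@perSite)

#' @rdname SiteModelResult-class
#' @export
setMethod("overallP", "SiteModelResult", function(x) x@overallP)

#' @rdname SiteModelResult-class
#' @export
setMethod("interactionP", "SiteModelResult", function(x) x@interactionP)

# ---- show methods ----

setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: %.3g um/px in-plane, %.3g um slice spacing\n",
              object@pixelSize, object@sliceThickness))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@slices[[1L]])
  cat(sprintf("ImageStack '%s': %d slices of %d x %d px (%.3g um/px)\n",
              object@sourceId, length(object@slices), d[1L], d[2L],
              object@geometry@pixelSize))
})

setMethod("show", "CrossSectionLabeling", function(object) {
  cat(sprintf(
    "CrossSectionLabeling%s: %d cortex px, %d marrow px, %s (threshold %.4g)\n",
    if (is.na(object@sitePct)) "" else sprintf(" at %g%% site", object@sitePct),
    sum(object@labels == LBL_CORTEX), sum(object@labels == LBL_MARROW),
    if (object@breached) "breached" else "intact", object@threshold))
})

setMethod("show", "BoneProfile", function(object) {
  d <- object@data
  cat(sprintf("BoneProfile '%s': %d sites (%g--%g%%), %d breached, %s\n",
              object@sourceId, nrow(d), min(d$site_pct), max(d$site_pct),
              sum(d$breached, na.rm = TRUE),
              if (object@normalized)
                sprintf("orientation normalized at %g%% site", object@refSite)
              else "orientation not normalized"))
})

setMethod("show", "CentralAxis", function(object) {
  cat(sprintf(
    "CentralAxis through %g%% (%.2f, %.2f) and %g%% (%.2f, %.2f)\n",
    object@anchorLo[1L], object@anchorLo[2L], object@anchorLo[3L],
    object@anchorHi[1L], object@anchorHi[2L], object@anchorHi[3L]))
})

setMethod("show", "SiteModelResult", function(object) {
  cat(sprintf(
    "SiteModelResult (%s): overall p = %.3g, interaction p = %.3g\n",
    object@meta$model, object@overallP, object@interactionP))
  sig <- object@perSite$significant
  if (all(is.na(sig)))
    cat("  per-site post hoc not applicable (overall effect not significant)\n")
  else
    cat(sprintf("  %d of %d sites significant after Bonferroni\n",
                sum(sig, na.rm = TRUE), object@nSitesTested))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d slices, %d x %d px, blur %.2g px, noise SD %.2g\n",
    object@nSlices, object@imageSize, object@imageSize, object@blurSigma,
    object@noiseSd))
})
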