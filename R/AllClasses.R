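#' @import methods
NULL

# Pixel label codes shared across the package.
LBL_BACKGROUND <- 0L
LBL_CORTEX <- 1L
LBL_MARROW <- 2L

#' In-plane voxel geometry of a reconstructed micro-CT stack
#'
#' Holds the physical size of a pixel (isotropic in-plane) and of a slice,
#' both in micrometres. The defaults correspond to a common high-resolution
#' in vivo mouse-tibia scanning protocol (4.8 um isotropic voxels).
#'
#' @slot pixelSize in-plane pixel edge length, um.
#' @slot sliceThickness slice-to-slice spacing, um.
#' @export
setClass("VoxelGeometry",
  representation(pixelSize = "numeric", sliceThickness = "numeric"),
  prototype(pixelSize = 4.8, sliceThickness = 4.8),
  validity = function(object) {
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    if (length(object@sliceThickness) != 1L ||
        !is.finite(object@sliceThickness) || object@sliceThickness <= 0)
      return("sliceThickness must be a single positive number")
    TRUE
  })

#' Construct a VoxelGeometry
#'
#' @param pixelSize in-plane pixel size in micrometres per pixel.
#' @param sliceThickness slice spacing in micrometres.
#' @return A \linkS4class{VoxelGeometry} object.
#' @examples
#' voxelGeometry()           # 4.8 um defaults
#' voxelGeometry(10.4, 10.4)
#' @export
voxelGeometry <- function(pixelSize = 4.8, sliceThickness = 4.8) {
  new("VoxelGeometry", pixelSize = pixelSize, sliceThickness = sliceThickness)
}

#' Ordered stack of grayscale cross-section images of one bone
#'
#' Slices are stored proximal to distal as integer grayscale matrices
#' (rows = image y, columns = image x). A stack must contain at least 11
#' slices so that 1% sites are distinct, and all slices must share one
#' height x width.
#'
#' @slot slices list of grayscale matrices, one per slice.
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot sourceId free-text identifier of the bone.
#' @export
setClass("ImageStack",
  representation(slices = "list", geometry = "VoxelGeometry",
                 sourceId = "character"),
  validity = function(object) {
    n <- length(object@slices)
    if (n < 11L)
      return("a stack needs at least 11 slices for distinct 1% sites")
    if (!all(vapply(object@slices, is.matrix, logical(1L))))
      return("all slices must be matrices")
    dims <- vapply(object@slices, dim, integer(2L))
    if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
      return("inconsistent slice shape")
    TRUE
  })

#' Construct an ImageStack from a list of slice matrices
#'
#' @param slices list of grayscale matrices, ordered proximal to distal.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @param sourceId free-text bone identifier.
#' @return An \linkS4class{ImageStack}.
#' @export
imageStack <- function(slices, geometry = voxelGeometry(), sourceId = "bone") {
  new("ImageStack", slices = slices, geometry = geometry, sourceId = sourceId)
}

#' Per-slice pixel labeling into background, cortex and marrow
#'
#' The label matrix uses 0 = background, 1 = cortex, 2 = marrow. A slice is
#' breached when the cortex does not enclose a marrow cavity (the interior
#' connects to the image border), in which case marrow and total areas are
#' undefined downstream while cortical area remains reliable.
#'
#' @slot labels integer matrix of pixel labels.
#' @slot breached logical breach flag.
#' @slot threshold the intensity threshold used for binarization.
#' @slot sitePct site along the bone length, percent (NA when standalone).
#' @export
setClass("CrossSectionLabeling",
  representation(labels = "matrix", breached = "logical",
                 threshold = "numeric", sitePct = "numeric"),
  validity = function(object) {
    lv <- unique(as.integer(object@labels))
    if (!all(lv %in% c(LBL_BACKGROUND, LBL_CORTEX, LBL_MARROW)))
      return("labels must be 0 (background), 1 (cortex) or 2 (marrow)")
    if (length(object@breached) != 1L || is.na(object@breached))
      return("breached must be TRUE or FALSE")
    if (object@breached && any(object@labels == LBL_MARROW))
      return("a breached slice cannot contain marrow pixels")
    TRUE
  })

profileColumns <- function() {
  c("site_pct", "slice_index", "ct_ar", "ma_ar", "tt_ar", "cs_th",
    "i_min", "i_max", "pmi", "centroid_x", "centroid_y",
    "feret_max", "feret_min", "feret_angle", "eccentricity",
    "dev_x", "dev_y", "breached")
}

emptyProfileData <- function(sites = integer(0)) {
  d <- data.frame(site_pct = as.numeric(sites), slice_index = NA_real_,
                  ct_ar = NA_real_, ma_ar = NA_real_, tt_ar = NA_real_,
                  cs_th = NA_real_, i_min = NA_real_, i_max = NA_real_,
                  pmi = NA_real_, centroid_x = NA_real_, centroid_y = NA_real_,
                  feret_max = NA_real_, feret_min = NA_real_,
                  feret_angle = NA_real_, eccentricity = NA_real_,
                  dev_x = NA_real_, dev_y = NA_real_, breached = NA)
  d$breached <- as.logical(d$breached)
  d
}

#' Site-by-site morphometric profile of one bone
#'
#' One row per analyzed percent site (default 10--90%), holding all
#' per-slice scalar measures plus the centroid deviations from the central
#' axis. Anchor centroids (default the 5% and 95% sites) used for the
#' central axis are carried alongside so that orientation normalization
#' transforms them consistently.
#'
#' @slot data data.frame with the columns of \code{profileColumns()}.
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot sourceId bone identifier.
#' @slot anchors data.frame (site, x, y) of axis anchor centroids.
#' @slot refSite orientation reference site (NA before normalization).
#' @slot rotation numeric c(theta_deg, cx, cy) applied at normalization.
#' @slot normalized has orientation normalization been applied.
#' @export
setClass("BoneProfile",
  representation(data = "data.frame", geometry = "VoxelGeometry",
                 sourceId = "character", anchors = "data.frame",
                 refSite = "numeric", rotation = "numeric",
                 normalized = "logical"),
  prototype(anchors = data.frame(site = numeric(0), x = numeric(0),
                                 y = numeric(0)),
            refSite = NA_real_, rotation = c(0, 0, 0), normalized = FALSE),
  validity = function(object) {
    miss <- setdiff(profileColumns(), names(object@data))
    if (length(miss))
      return(paste("profile data lacks columns:", paste(miss, collapse = ", ")))
    if (is.unsorted(object@data$site_pct, strictly = TRUE))
      return("site_pct must be strictly increasing")
    if (!all(c("site", "x", "y") %in% names(object@anchors)))
      return("anchors needs columns site, x, y")
    TRUE
  })

#' Construct a BoneProfile
#'
#' @param data data.frame of per-site measures (see
#'   \code{sitespec:::profileColumns()}); missing columns are added as NA.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @param sourceId bone identifier.
#' @param anchors optional data.frame (site, x, y) of axis anchor centroids.
#' @return A \linkS4class{BoneProfile}.
#' @export
boneProfile <- function(data, geometry = voxelGeometry(), sourceId = "bone",
                        anchors = NULL) {
  full <- emptyProfileData(data$site_pct)
  for (nm in intersect(names(data), names(full)))
    full[[nm]] <- if (nm == "breached") as.logical(data[[nm]])
                  else as.numeric(data[[nm]])
  if (is.null(anchors))
    anchors <- data.frame(site = numeric(0), x = numeric(0), y = numeric(0))
  new("BoneProfile", data = full, geometry = geometry, sourceId = sourceId,
      anchors = anchors)
}

#' Straight central axis of a bone
#'
#' The axis is defined independently for x and y as the straight line
#' through the centroids at a proximal and a distal anchor site, extrapolated
#' over the whole length and parameterized by percent site.
#'
#' @slot anchorLo numeric c(site, x, y) of the proximal anchor.
#' @slot anchorHi numeric c(site, x, y) of the distal anchor.
#' @export
setClass("CentralAxis",
  representation(anchorLo = "numeric", anchorHi = "numeric"),
  validity = function(object) {
    if (length(object@anchorLo) != 3L || length(object@anchorHi) != 3L)
      return("anchors must be numeric c(site, x, y)")
    if (object@anchorLo[1L] == object@anchorHi[1L])
      return("anchor sites must be distinct")
    TRUE
  })

#' Result of the site-by-intervention mixed/fixed model
#'
#' @slot overallP p-value of the overall intervention effect.
#' @slot interactionP p-value of the site-by-intervention interaction.
#' @slot perSite data.frame (site_pct, estimate, se, raw_p, bonferroni_p,
#'   significant) of per-site intervention contrasts.
#' @slot nSitesTested number of sites entering the Bonferroni correction.
#' @slot meta list of fit metadata (model type, random effect, method).
#' @export
setClass("SiteModelResult",
  representation(overallP = "numeric", interactionP = "numeric",
                 perSite = "data.frame", nSitesTested = "integer",
                 meta = "list"))

#' Parameter set of the synthetic tibia-like phantom
#'
#' Cross-sections are elliptical annuli whose outer semi-axes, wall
#' thickness, centroid offset and in-plane rotation vary along the bone as
#' piecewise-linear functions of percent site, plus a solid fibula that
#' approaches and merges with the tibia at a junction site. See
#' \code{\link{phantomSpec}}.
#'
#' @slot nSlices number of slices in a generated stack.
#' @slot imageSize image edge length, px (square slices).
#' @slot outerA,outerB,wall,offsetX,offsetY,rotationDeg control-point tables
#'   (site, value) interpolated linearly over percent site.
#' @slot fibula list (a, b, angleDeg, gap control points, junctionSite).
#' @slot blurSigma partial-volume Gaussian blur, px.
#' @slot noiseSd additive Gaussian intensity noise SD (0--255 scale).
#' @slot boneIntensity,backgroundIntensity two-level image intensities.
#' @slot breachSites percent sites at which a wedge-shaped cortical gap is
#'   cut (empty by default).
#' @slot seed RNG seed used when rasterizing a stack.
#' @export
setClass("PhantomSpec",
  representation(nSlices = "integer", imageSize = "integer",
                 outerA = "data.frame", outerB = "data.frame",
                 wall = "data.frame", offsetX = "data.frame",
                 offsetY = "data.frame", rotationDeg = "data.frame",
                 fibula = "list", blurSigma = "numeric", noiseSd = "numeric",
                 boneIntensity = "numeric", backgroundIntensity = "numeric",
                 breachSites = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nSlices < 11L) return("nSlices must be at least 11")
    if (object@imageSize < 32L) return("imageSize must be at least 32 px")
    s <- seq(0, 100, by = 1)
    a <- interpControl(object@outerA, s); b <- interpControl(object@outerB, s)
    w <- interpControl(object@wall, s)
    if (any(w <= 0)) return("wall thickness must be positive everywhere")
    if (any(a - w <= 0) || any(b - w <= 0))
      return("inner semi-axes must stay positive (wall < outer semi-axes)")
    if (object@boneIntensity <= object@backgroundIntensity)
      return("boneIntensity must exceed backgroundIntensity")
    j <- object@fibula$junctionSite
    if (!is.null(j) && (j <= 0 || j >= 100))
      return("junctionSite must lie in (0, 100)")
    TRUE
  })
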