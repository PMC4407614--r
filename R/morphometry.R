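# Per-slice scalar morphometry: areas, centroid, second moments of area,
# local (cross-sectional) thickness, Feret calipers, eccentricity.
#
# Coordinate convention: x = image columns, y = image rows, origin at the
# top-left pixel centre, 0-based pixel centres. After orientation
# normalization x is anterior-posterior and y is medial-lateral.

maskCoords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1, y = idx[, 1L] - 1)
}

#' Cortical, marrow and total cross-sectional areas
#'
#' Ct.Ar is the cortex pixel count, Ma.Ar the enclosed marrow pixel count
#' and Tt.Ar their sum (the tissue area within the periosteal envelope).
#' On a breached slice no enclosed space exists, so Ma.Ar and Tt.Ar are
#' undefined (NA) while Ct.Ar remains reliable.
#'
#' @param labeling a \linkS4class{CrossSectionLabeling}.
#' @param geometry a \linkS4class{VoxelGeometry} for the mm^2 companions.
#' @return named list with \code{ct_ar}, \code{ma_ar}, \code{tt_ar} in px^2
#'   and \code{ct_ar_mm2}, \code{ma_ar_mm2}, \code{tt_ar_mm2}.
#' @export
areaMeasures <- function(labeling, geometry = voxelGeometry()) {
  stopifnot(is(labeling, "CrossSectionLabeling"))
  ct <- sum(labeling@labels == LBL_CORTEX)
  if (labeling@breached) {
    ma <- NA_real_; tt <- NA_real_
  } else {
    ma <- sum(labeling@labels == LBL_MARROW)
    tt <- ct + ma
  }
  f <- (pixelSize(geometry) / 1000)^2
  list(ct_ar = as.numeric(ct), ma_ar = as.numeric(ma), tt_ar = as.numeric(tt),
       ct_ar_mm2 = ct * f, ma_ar_mm2 = ma * f, tt_ar_mm2 = tt * f)
}

#' Centroid of a pixel mask
#'
#' Arithmetic mean of the foreground pixel centre coordinates,
#' x = columns, y = rows (0-based).
#'
#' @param mask logical mask with at least one foreground pixel.
#' @return named numeric c(x, y) in px.
#' @export
maskCentroid <- function(mask) {
  if (!any(mask)) stop("empty mask: centroid undefined")
  xy <- maskCoords(mask)
  c(x = mean(xy[, "x"]), y = mean(xy[, "y"]))
}

#' Principal second moments of area and polar moment of inertia
#'
#' Builds the 2x2 second-moment-of-area tensor about the centroid from
#' unit-area pixel contributions (each pixel contributes its own 1/12
#' square self-moment, so even single-row masks have nonzero minimum
#' moment, matching the continuum closed forms) and eigen-decomposes it.
#' The polar moment of inertia is the tensor trace, identically
#' i_min + i_max.
#'
#' @param mask logical mask of the cross-section (the cortex).
#' @return list with \code{i_min}, \code{i_max}, \code{pmi} (px^4) and
#'   \code{principal_angle}: orientation in degrees [0, 180) of the axis
#'   about which the second moment is maximal.
#' @export
secondMoments <- function(mask) {
  xy <- maskCoords(mask)
  if (nrow(xy) < 1L) stop("empty mask: moments undefined")
  dx <- xy[, "x"] - mean(xy[, "x"])
  dy <- xy[, "y"] - mean(xy[, "y"])
  n <- length(dx)
  ixx <- sum(dy^2) + n / 12        # bending about the x-axis
  iyy <- sum(dx^2) + n / 12        # bending about the y-axis
  ixy <- sum(dx * dy)
  mid <- (ixx + iyy) / 2
  half <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  # I(phi) = mid + (ixx-iyy)/2 cos(2 phi) - ixy sin(2 phi); maximum at
  # 2 phi = atan2(-ixy, (ixx-iyy)/2)
  phi <- atan2(-ixy, (ixx - iyy) / 2) / 2 * 180 / pi
  list(i_min = mid - half, i_max = mid + half, pmi = ixx + iyy,
       principal_angle = phi %% 180)
}

#' Mean cross-sectional (local) thickness of the cortex
#'
#' Local thickness in the largest-inscribed-disk sense: each cortex pixel
#' is assigned the diameter of the largest disk that lies within the
#' cortex and contains it, and Cs.Th is the mean over cortex pixels.
#' Computed from the Euclidean distance transform: every foreground pixel
#' is a candidate disk centre with radius equal to its distance value;
#' centres whose disk is contained in a neighbour's disk are pruned, and
#' the survivors paint their diameter onto the pixels they cover.
#'
#' @param cortexMask logical mask of the cortex.
#' @return mean local thickness in px.
#' @export
localThickness <- function(cortexMask) {
  if (!any(cortexMask)) stop("empty mask: thickness undefined")
  d <- distanceTransform(cortexMask)
  nr <- nrow(cortexMask); nc <- ncol(cortexMask)
  # maximal inscribed disks centre on the medial axis: take as disk centres
  # the pixels whose EDT is an 8-neighbourhood local maximum (plateaus kept)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- d
  nbmax <- matrix(0, nr, nc)
  for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
    nb <- pad[2:(nr + 1L) + s[1L], 2:(nc + 1L) + s[2L]]
    nbmax <- pmax(nbmax, nb)
  }
  ridge <- cortexMask & d >= nbmax
  centers <- which(ridge, arr.ind = TRUE)
  radii <- d[ridge]
  ord <- order(radii, decreasing = TRUE)
  thick <- matrix(0, nr, nc)
  for (k in ord) {
    r <- radii[k]
    ci <- centers[k, 1L]; cj <- centers[k, 2L]
    reach <- r - 0.5                   # pixels whose centre the disk covers
    i0 <- max(1L, ci - floor(reach)); i1 <- min(nr, ci + floor(reach))
    j0 <- max(1L, cj - floor(reach)); j1 <- min(nc, cj + floor(reach))
    di <- (i0:i1) - ci; dj <- (j0:j1) - cj
    cover <- outer(di^2, dj^2, "+") <= reach^2
    sub <- thick[i0:i1, j0:j1, drop = FALSE]
    sub[cover & sub < 2 * r] <- 2 * r
    thick[i0:i1, j0:j1] <- sub
  }
  # every pixel's own disk is a valid lower bound; catches any spot the
  # discrete ridge misses
  thick <- pmax(thick, 2 * d)
  mean(thick[cortexMask])
}

# Convex hull of the pixel *corners* of a mask, as an n x 2 matrix (x, y).
pixelCornerHull <- function(mask) {
  xy <- maskCoords(mask)
  cx <- c(xy[, "x"] - 0.5, xy[, "x"] + 0.5, xy[, "x"] - 0.5, xy[, "x"] + 0.5)
  cy <- c(xy[, "y"] - 0.5, xy[, "y"] - 0.5, xy[, "y"] + 0.5, xy[, "y"] + 0.5)
  h <- grDevices::chull(cx, cy)
  cbind(x = cx[h], y = cy[h])
}

#' Feret caliper diameters and angle
#'
#' Caliper extremes over the convex hull of the foreground pixel corners:
#' the maximum Feret diameter is the largest pairwise distance between hull
#' vertices, the minimum Feret diameter is the smallest projection width
#' over all rotations (rotating calipers: the minimum width is attained
#' flush with a hull edge), and the Feret angle is the orientation of the
#' maximum-diameter chord in degrees [0, 180).
#'
#' @param mask logical mask with at least two foreground pixels.
#' @return list with \code{feret_max}, \code{feret_min} (px) and
#'   \code{feret_angle} (degrees).
#' @export
feretDiameters <- function(mask) {
  n <- sum(mask)
  if (n < 1L) stop("empty mask: Feret diameters undefined")
  if (n == 1L) {
    warning("single-pixel mask: Feret diameters set to the pixel extent")
    return(list(feret_max = 1, feret_min = 1, feret_angle = 0))
  }
  hull <- pixelCornerHull(mask)
  m <- nrow(hull)
  dx <- outer(hull[, "x"], hull[, "x"], "-")
  dy <- outer(hull[, "y"], hull[, "y"], "-")
  d2 <- dx^2 + dy^2
  fmax <- sqrt(max(d2))
  # the max-chord direction is ill-conditioned on smooth sections (chord
  # length is quadratically flat around the major axis), so the angle is the
  # axial mean over all chords within half a pixel of the maximum
  near <- which(sqrt(d2) >= fmax - 0.5, arr.ind = TRUE)
  near <- near[near[, 1L] < near[, 2L], , drop = FALSE]
  dirs <- atan2(hull[near[, 2L], "y"] - hull[near[, 1L], "y"],
                hull[near[, 2L], "x"] - hull[near[, 1L], "x"])
  ang <- atan2(mean(sin(2 * dirs)), mean(cos(2 * dirs))) / 2 * 180 / pi
  # minimum width over hull-edge directions
  nxt <- c(2:m, 1L)
  ex <- hull[nxt, "x"] - hull[, "x"]
  ey <- hull[nxt, "y"] - hull[, "y"]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  fmin <- Inf
  for (e in which(keep)) {
    ux <- ex[e] / len[e]; uy <- ey[e] / len[e]
    w <- max(abs((hull[, "x"] - hull[e, "x"]) * uy -
                 (hull[, "y"] - hull[e, "y"]) * ux))
    if (w < fmin) fmin <- w
  }
  list(feret_max = fmax, feret_min = fmin, feret_angle = ang %% 180)
}

#' Eccentricity from the caliper axes
#'
#' Deviation of a section from circularity, computed from the major
#' (maximum Feret) and minor (minimum Feret) caliper axes as
#' \code{e = sqrt(1 - (feret_min / feret_max)^2)}; 0 for a circle,
#' approaching 1 for elongated sections.
#'
#' @param feretMax,feretMin caliper diameters, px; feretMax >= feretMin > 0.
#' @return eccentricity in [0, 1).
#' @examples
#' feretEccentricity(120, 60)  # sqrt(3)/2
#' @export
feretEccentricity <- function(feretMax, feretMin) {
  if (any(feretMin <= 0)) stop("feretMin must be positive")
  if (any(feretMax < feretMin)) stop("feretMax must be >= feretMin")
  sqrt(1 - (feretMin / feretMax)^2)
}

#' All per-slice scalar measures of a labeled cross-section
#'
#' Composite of the area, centroid, moment, thickness and caliper
#' operations. On breached slices Ma.Ar and Tt.Ar are NA; all other
#' measures are still computed from the cortex.
#'
#' @param labeling a \linkS4class{CrossSectionLabeling}.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @return one-row data.frame with columns site_pct, ct_ar, ma_ar, tt_ar,
#'   cs_th, i_min, i_max, pmi, centroid_x, centroid_y, feret_max,
#'   feret_min, feret_angle, eccentricity, breached (areas in px^2,
#'   moments in px^4, lengths in px).
#' @export
measureSlice <- function(labeling, geometry = voxelGeometry()) {
  stopifnot(is(labeling, "CrossSectionLabeling"))
  cm <- labeling@labels == LBL_CORTEX
  ar <- areaMeasures(labeling, geometry)
  cen <- maskCentroid(cm)
  mom <- secondMoments(cm)
  fer <- feretDiameters(cm)
  data.frame(site_pct = labeling@sitePct,
             ct_ar = ar$ct_ar, ma_ar = ar$ma_ar, tt_ar = ar$tt_ar,
             cs_th = localThickness(cm),
             i_min = mom$i_min, i_max = mom$i_max, pmi = mom$pmi,
             centroid_x = unname(cen["x"]), centroid_y = unname(cen["y"]),
             feret_max = fer$feret_max, feret_min = fer$feret_min,
             feret_angle = fer$feret_angle,
             eccentricity = feretEccentricity(fer$feret_max, fer$feret_min),
             breached = labeling@breached)
}
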