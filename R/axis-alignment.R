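# Orientation normalization to the reference-site Feret angle and
# centroid-deviation curvature against a straight central axis.

rotatePoints <- function(x, y, thetaDeg, cx, cy) {
  th <- thetaDeg * pi / 180
  dx <- x - cx; dy <- y - cy
  list(x = cx + cos(th) * dx + sin(th) * dy,
       y = cy - sin(th) * dx + cos(th) * dy)   # rotation by -theta
}

#' Normalize bone orientation to the reference-site Feret angle
#'
#' Rotates all per-site centroid coordinates (and the axis anchor
#' centroids) about the reference-site centroid so that the Feret angle at
#' the reference site (37% by default, an arbitrary but fixed convention)
#' becomes 0 degrees, i.e. the section's long axis is parallel to x. After
#' normalization x is the anterior-posterior and y the medial-lateral
#' direction. The rotation is applied analytically to coordinates and
#' angles, never by image resampling, so rotation-invariant scalars are
#' untouched and the operation is exactly deterministic and idempotent.
#'
#' @param profile a \linkS4class{BoneProfile}.
#' @param referenceSite percent site whose Feret angle defines 0 degrees;
#'   when unmeasured, the nearest measured site is used with a warning.
#' @return the normalized \linkS4class{BoneProfile}.
#' @export
normalizeOrientation <- function(profile, referenceSite = 37) {
  stopifnot(is(profile, "BoneProfile"))
  d <- profile@data
  row <- which(d$site_pct == referenceSite)
  if (length(row) == 0L || is.na(d$feret_angle[row[1L]])) {
    ok <- which(!is.na(d$feret_angle))
    if (length(ok) == 0L) stop("no site with a measured Feret angle")
    row <- ok[which.min(abs(d$site_pct[ok] - referenceSite))]
    warning(sprintf(
      "reference site %g%% not measured; falling back to nearest site %g%%",
      referenceSite, d$site_pct[row]))
  } else row <- row[1L]
  theta <- d$feret_angle[row]
  cx <- d$centroid_x[row]; cy <- d$centroid_y[row]
  r <- rotatePoints(d$centroid_x, d$centroid_y, theta, cx, cy)
  d$centroid_x <- r$x
  d$centroid_y <- r$y
  d$feret_angle <- (d$feret_angle - theta) %% 180
  if (nrow(profile@anchors)) {
    ra <- rotatePoints(profile@anchors$x, profile@anchors$y, theta, cx, cy)
    profile@anchors$x <- ra$x
    profile@anchors$y <- ra$y
  }
  profile@data <- d
  profile@refSite <- d$site_pct[row]
  profile@rotation <- c(theta, cx, cy)
  profile@normalized <- TRUE
  profile
}

#' Fit the straight central axis of a bone
#'
#' The central axis is the straight line through the cross-sectional
#' centroids at a proximal and a distal anchor site (5% and 95% of the
#' bone length by default), extrapolated over the whole bone and treated
#' independently for x and y as linear functions of percent site. Anchors
#' are taken from the profile's stored anchor centroids when present
#' (the pipeline segments the 5%/95% slices on demand even though they are
#' outside the analyzed 10--90% range); otherwise the fit falls back to the
#' outermost measured sites with a warning.
#'
#' @param profile a \linkS4class{BoneProfile}.
#' @param lo,hi anchor percent sites.
#' @return A \linkS4class{CentralAxis}.
#' @export
fitCentralAxis <- function(profile, lo = 5, hi = 95) {
  stopifnot(is(profile, "BoneProfile"), lo < hi)
  getAnchor <- function(site) {
    a <- profile@anchors
    hit <- which(a$site == site)
    if (length(hit)) return(c(site, a$x[hit[1L]], a$y[hit[1L]]))
    d <- profile@data
    hit <- which(d$site_pct == site & !is.na(d$centroid_x))
    if (length(hit)) return(c(site, d$centroid_x[hit[1L]],
                              d$centroid_y[hit[1L]]))
    NULL
  }
  aLo <- getAnchor(lo); aHi <- getAnchor(hi)
  if (is.null(aLo) || is.null(aHi)) {
    d <- profile@data
    ok <- which(!is.na(d$centroid_x))
    if (length(ok) < 2L) stop("cannot fit central axis: fewer than two ",
                              "measured centroids")
    fLo <- ok[1L]; fHi <- ok[length(ok)]
    warning(sprintf(
      "anchor sites %g%%/%g%% unavailable; falling back to %g%%/%g%%",
      lo, hi, d$site_pct[fLo], d$site_pct[fHi]))
    aLo <- c(d$site_pct[fLo], d$centroid_x[fLo], d$centroid_y[fLo])
    aHi <- c(d$site_pct[fHi], d$centroid_x[fHi], d$centroid_y[fHi])
  }
  new("CentralAxis", anchorLo = unname(aLo), anchorHi = unname(aHi))
}

#' Central-axis position at given percent sites
#'
#' @param axis a \linkS4class{CentralAxis}.
#' @param sitePct percent site(s).
#' @return data.frame (site_pct, x, y) of axis positions.
#' @export
axisPosition <- function(axis, sitePct) {
  stopifnot(is(axis, "CentralAxis"))
  p0 <- axis@anchorLo; p1 <- axis@anchorHi
  t <- (sitePct - p0[1L]) / (p1[1L] - p0[1L])
  data.frame(site_pct = sitePct,
             x = p0[2L] + t * (p1[2L] - p0[2L]),
             y = p0[3L] + t * (p1[3L] - p0[3L]))
}

#' Absolute centroid deviation from the central axis (curvature)
#'
#' Per-site absolute difference between the measured centroid and the
#' straight central axis, componentwise: dev_x is the anterior-posterior
#' and dev_y the medial-lateral deviation (after orientation
#' normalization). Absolute values are reported, so the direction of
#' curvature is deliberately not retained. Because the axis is defined
#' within the bone itself, the deviations are invariant to how the bone
#' was positioned in the scanner.
#'
#' @param profile a \linkS4class{BoneProfile}.
#' @param axis a \linkS4class{CentralAxis} from \code{\link{fitCentralAxis}}.
#' @return data.frame (site_pct, dev_x, dev_y); missing centroids give
#'   missing deviations.
#' @export
centroidDeviation <- function(profile, axis) {
  stopifnot(is(profile, "BoneProfile"))
  d <- profile@data
  ax <- axisPosition(axis, d$site_pct)
  data.frame(site_pct = d$site_pct,
             dev_x = abs(d$centroid_x - ax$x),
             dev_y = abs(d$centroid_y - ax$y))
}
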