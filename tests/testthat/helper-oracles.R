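# Shape rasterizers and independent brute-force oracles used across tests.
# All rasterizers use the pixel-centre-in-region convention with half-open
# inner boundaries, so pixel counts are unbiased estimates of continuum
# areas.

pixelGrid <- function(S) {
  list(x = matrix(rep(0:(S - 1L), each = S), nrow = S),
       y = matrix(rep(0:(S - 1L), times = S), nrow = S))
}

rasterDisk <- function(S, cx, cy, r) {
  g <- pixelGrid(S)
  (g$x - cx)^2 + (g$y - cy)^2 <= r^2
}

rasterAnnulus <- function(S, cx, cy, ro, ri) {
  g <- pixelGrid(S)
  d2 <- (g$x - cx)^2 + (g$y - cy)^2
  d2 <= ro^2 & d2 > ri^2
}

rasterEllipse <- function(S, cx, cy, a, b, phiDeg = 0) {
  g <- pixelGrid(S)
  th <- phiDeg * pi / 180
  dx <- g$x - cx; dy <- g$y - cy
  xr <- cos(th) * dx + sin(th) * dy
  yr <- -sin(th) * dx + cos(th) * dy
  (xr / a)^2 + (yr / b)^2 <= 1
}

# rows r0..r1, cols c0..c1 (1-based), inclusive
rasterRect <- function(S, r0, r1, c0, c1) {
  m <- matrix(FALSE, S, S)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# open ring: annulus with a wedge of half-angle gapDeg cut at angle 0
rasterCShape <- function(S, cx, cy, ro, ri, gapDeg = 5) {
  g <- pixelGrid(S)
  dx <- g$x - cx; dy <- g$y - cy
  d2 <- dx^2 + dy^2
  ang <- atan2(dy, dx)
  d2 <= ro^2 & d2 > ri^2 & abs(ang) > gapDeg * pi / 180
}

# random blob: union of a few random disks, seeded by the caller
randomBlob <- function(S = 60, nDisks = 3, rMax = 12) {
  m <- matrix(FALSE, S, S)
  for (i in seq_len(nDisks)) {
    m <- m | rasterDisk(S, runif(1, rMax, S - 1 - rMax),
                        runif(1, rMax, S - 1 - rMax), runif(1, 3, rMax))
  }
  m
}

# --- independent oracles ---

# exhaustive scan over all split points, recomputing means and WCSS directly
bruteKmeans <- function(x) {
  u <- sort(unique(x))
  best <- Inf; bestTh <- NA_real_
  for (k in seq_len(length(u) - 1L)) {
    g1 <- x[x <= u[k]]; g2 <- x[x > u[k]]
    w <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    if (w < best) {
      best <- w
      bestTh <- (mean(g1) + mean(g2)) / 2
    }
  }
  list(wcss = best, threshold = bestTh)
}

wcssAt <- function(x, th) {
  g1 <- x[x < th]; g2 <- x[x >= th]
  if (!length(g1) || !length(g2)) return(Inf)
  sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
}

# caliper widths by exhaustive rotation of the corner hull at fixed steps
bruteFeret <- function(mask, stepDeg = 0.1) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  cx <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  cy <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  h <- grDevices::chull(cx, cy)
  px <- cx[h]; py <- cy[h]
  ang <- seq(0, 180 - stepDeg, by = stepDeg) * pi / 180
  proj <- outer(px, cos(ang)) + outer(py, sin(ang))
  widths <- apply(proj, 2L, max) - apply(proj, 2L, min)
  list(feret_max = max(widths), feret_min = min(widths))
}

# second moments about the centroid by direct pixel sums; principal values
# by exhaustive rotation of the bending axis
bruteMoments <- function(mask, stepDeg = 0.1) {
  idx <- which(mask, arr.ind = TRUE)
  dx <- (idx[, 2L] - 1) - mean(idx[, 2L] - 1)
  dy <- (idx[, 1L] - 1) - mean(idx[, 1L] - 1)
  n <- length(dx)
  ang <- seq(0, 180 - stepDeg, by = stepDeg) * pi / 180
  # unit-square pixels are isotropic: self-moment n/12 about any axis
  iphi <- vapply(ang, function(a)
    sum((dy * cos(a) - dx * sin(a))^2) + n / 12, numeric(1L))
  list(ixx = sum(dy^2) + n / 12, iyy = sum(dx^2) + n / 12,
       i_min = min(iphi), i_max = max(iphi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_rel <- function(actual, expected, tol, label = NULL) {
  expect_true(abs(actual / expected - 1) <= tol,
              label = paste0(label %||% "value", ": ", format(actual),
                             " vs expected ", format(expected),
                             " (tol ", tol, ")"))
}

rsq <- function(a, b) stats::cor(a, b)^2

# a fully populated synthetic profile table with a few breached sites
emptyProfileDataFilled <- function(sites = 10:90, breachedAt = c(25, 60, 61)) {
  d <- sitespec:::emptyProfileData(sites)
  n <- length(sites)
  d$slice_index <- sites * 5
  d$ct_ar <- runif(n, 9000, 12000)
  d$ma_ar <- runif(n, 5000, 30000)
  d$tt_ar <- d$ct_ar + d$ma_ar
  d$cs_th <- runif(n, 14, 30)
  d$i_min <- runif(n, 2e7, 6e7)
  d$i_max <- d$i_min * runif(n, 1, 2.5)
  d$pmi <- d$i_min + d$i_max
  d$centroid_x <- runif(n, 190, 210)
  d$centroid_y <- runif(n, 190, 210)
  d$feret_max <- runif(n, 150, 260)
  d$feret_min <- d$feret_max * runif(n, 0.6, 1)
  d$feret_angle <- runif(n, 0, 180)
  d$eccentricity <- sqrt(1 - (d$feret_min / d$feret_max)^2)
  d$dev_x <- abs(rnorm(n, 0, 5))
  d$dev_y <- abs(rnorm(n, 0, 5))
  d$breached <- d$site_pct %in% breachedAt
  d$ma_ar[d$breached] <- NA_real_
  d$tt_ar[d$breached] <- NA_real_
  d
}
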