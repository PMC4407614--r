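# Shared phantom fixtures. The default (full-size) stack is expensive, so
# it is generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

getDefaultStack <- function() {
  if (is.null(.fixtureCache$default))
    .fixtureCache$default <- generatePhantomStack(phantomSpec())
  .fixtureCache$default
}

# half-scale tibia-like phantom for fast pipeline/IO tests
smallSpec <- function(nSlices = 101L, imageSize = 200L, ...) {
  phantomSpec(
    nSlices = nSlices, imageSize = imageSize,
    outerA = controlPoints(c(0, 25, 50, 75, 100), c(65, 62.5, 52.5, 42.5, 38)),
    outerB = controlPoints(c(0, 25, 50, 75, 100), c(52, 50, 44, 38.5, 35)),
    wall = controlPoints(c(0, 25, 50, 75, 100), c(7.5, 7.5, 9.5, 13, 15)),
    offsetX = controlPoints(c(0, 25, 50, 75, 100), c(-1, 5, 3, -1, -2)),
    offsetY = controlPoints(c(0, 25, 50, 75, 100), c(0, 3, 1.5, 0, -1)),
    rotationDeg = controlPoints(c(0, 25, 50, 75, 100), c(35, 30, 18, 8, 5)),
    fibula = list(a = 7, b = 6, angleDeg = -40,
                  gap = controlPoints(c(0, 69, 70, 74, 100),
                                      c(15, 1.5, -1, -8, -8)),
                  junctionSite = 72),
    ...)
}

# eccentric straight sections with a sinusoidal anterior-posterior centroid
# path: offset_x(p) = A sin(pi (p - 5) / 90), zero at the 5%/95% anchors
sinusoidSpec <- function(amplitude = 15, ...) {
  s <- 0:100
  cp <- function(v) controlPoints(c(0, 100), c(v, v))
  phantomSpec(
    nSlices = 101L, imageSize = 220L,
    outerA = cp(60), outerB = cp(36), wall = cp(12),
    offsetX = controlPoints(s, amplitude * sin(pi * (s - 5) / 90)),
    offsetY = cp(0), rotationDeg = cp(0),
    fibula = list(a = 0, b = 0, angleDeg = 0, gap = cp(1e6),
                  junctionSite = 50),
    ...)
}

# the same bone rigidly transformed in the scanner: every section rotated
# by phi about the image centre and shifted by (sx, sy)
rigidTransformSpec <- function(base, phiDeg, sx, sy) {
  s <- sort(unique(c(base@offsetX$site, base@offsetY$site, 0:100)))
  ox <- interpControl(base@offsetX, s)
  oy <- interpControl(base@offsetY, s)
  phi <- phiDeg * pi / 180
  base@offsetX <- controlPoints(s, cos(phi) * ox - sin(phi) * oy + sx)
  base@offsetY <- controlPoints(s, sin(phi) * ox + cos(phi) * oy + sy)
  rot <- interpControl(base@rotationDeg, s)
  base@rotationDeg <- controlPoints(s, rot + phiDeg)
  base
}

interpControl <- sitespec:::interpControl

# minimal synthetic (image-free) profile for axis/orientation tests
syntheticProfile <- function(sites = 10:90,
                             cx = function(p) 100 + 0 * p,
                             cy = function(p) 100 + 0 * p,
                             feretAngle = 0,
                             anchorSites = c(5, 95)) {
  d <- data.frame(site_pct = as.numeric(sites),
                  ct_ar = 5000, ma_ar = 3000, tt_ar = 8000, cs_th = 10,
                  i_min = 1e6, i_max = 2e6, pmi = 3e6,
                  centroid_x = cx(sites), centroid_y = cy(sites),
                  feret_max = 120, feret_min = 60,
                  feret_angle = feretAngle %% 180,
                  eccentricity = sqrt(1 - 0.25), breached = FALSE)
  anchors <- data.frame(site = anchorSites, x = cx(anchorSites),
                        y = cy(anchorSites))
  boneProfile(d, anchors = anchors)
}

# apply an in-plane rotation by +phi about (ox, oy) plus a shift to a
# profile's centroids and Feret angles (scanner-placement simulation)
rotateProfile <- function(profile, phiDeg, ox, oy, sx = 0, sy = 0) {
  phi <- phiDeg * pi / 180
  d <- profileData(profile)
  rot <- function(x, y) list(x = ox + cos(phi) * (x - ox) - sin(phi) * (y - oy) + sx,
                             y = oy + sin(phi) * (x - ox) + cos(phi) * (y - oy) + sy)
  r <- rot(d$centroid_x, d$centroid_y)
  d$centroid_x <- r$x; d$centroid_y <- r$y
  d$feret_angle <- (d$feret_angle + phiDeg) %% 180
  a <- anchorPoints(profile)
  ra <- rot(a$x, a$y)
  a$x <- ra$x; a$y <- ra$y
  boneProfile(d, geometry = geometry(profile), sourceId = sourceId(profile),
              anchors = a)
}
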