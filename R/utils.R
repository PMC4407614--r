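# Internal helpers: connected components, natural sorting, small numerics.

# Round half away from zero (base round() is banker's rounding).
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Natural-sort order for filenames: split each name into alternating
# non-digit / digit runs and compare runs pairwise, digits numerically.
naturalOrder <- function(x) {
  tokenize <- function(s) {
    runs <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    runs
  }
  toks <- lapply(x, tokenize)
  maxlen <- max(vapply(toks, length, integer(1L)))
  keys <- vector("list", maxlen)
  for (k in seq_len(maxlen)) {
    run <- vapply(toks, function(t) if (length(t) >= k) t[[k]] else "", "")
    isnum <- grepl("^[0-9]+$", run) & run != ""
    num <- suppressWarnings(as.numeric(run))
    num[!isnum] <- NA_real_
    # numeric runs sort before/within equal text prefixes by value
    keys[[2L * k - 1L]] <- ifelse(isnum, "", run)
    keys[[2L * k]] <- ifelse(isnum, num, -Inf)
  }
  do.call(order, keys)
}

asBinaryMatrix <- function(x) {
  m <- matrix(as.numeric(x) != 0, nrow = dim(x)[1L])
  m
}

# 4-connected integer labeling of a logical mask (EBImage::bwlabel).
labelComponents4 <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow = nrow(mask)))
  matrix(as.integer(lab), nrow = nrow(mask))
}

# 8-connected labeling: 4-connected pass, then union-find merging of labels
# that touch diagonally.
labelComponents8 <- function(mask) {
  lab <- labelComponents4(mask)
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]     # down-right diagonal
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]     # down-left diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pa <- c(a1[keep1], a2[keep2])
  pb <- c(b1[keep1], b2[keep2])
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pa)) {
    pairs <- unique(cbind(pa, pb))
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Dilate a logical mask by one 8-connected layer (3x3 box).
dilate8 <- function(mask) {
  d <- EBImage::dilate(matrix(as.numeric(mask), nrow = nrow(mask)),
                       EBImage::makeBrush(3L, shape = "box"))
  matrix(as.numeric(d) > 0, nrow = nrow(mask))
}

# Dilate by one 4-connected layer (3x3 diamond/cross): one uniform pixel
# layer in the morphological sense, so a peel removes ~one perimeter.
dilate4 <- function(mask) {
  d <- EBImage::dilate(matrix(as.numeric(mask), nrow = nrow(mask)),
                       EBImage::makeBrush(3L, shape = "diamond"))
  matrix(as.numeric(d) > 0, nrow = nrow(mask))
}

# Separable Gaussian blur with replicate boundary handling.
gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(rep(1L, r), seq_len(nr), rep(nr, r)),
             c(rep(1L, r), seq_len(nc), rep(nc, r))]
  f <- stats::filter(pad, k, sides = 2)              # along columns
  f <- t(stats::filter(t(f), k, sides = 2))          # along rows
  matrix(as.numeric(f[(r + 1L):(r + nr), (r + 1L):(r + nc)]), nrow = nr)
}

# Euclidean distance transform (distance of foreground pixels to the
# nearest background pixel centre).
distanceTransform <- function(mask) {
  d <- EBImage::distmap(matrix(as.numeric(mask), nrow = nrow(mask)),
                        metric = "euclidean")
  matrix(as.numeric(d), nrow = nrow(mask))
}

# Area of the convex hull of foreground pixel centres (shoelace).
hullArea <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(0)
  x <- idx[, 2L]; y <- idx[, 1L]
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  j <- c(seq_along(h)[-1L], 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

# Deterministic local RNG scope: run expr under set.seed(seed) and restore
# the caller's RNG state afterwards.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Linear interpolation of a (site, value) control-point table.
interpControl <- function(cp, site) {
  stats::approx(cp$site, cp$value, xout = site, rule = 2)$y
}

#' Piecewise-linear control points over percent site
#'
#' Small helper for \code{\link{phantomSpec}}: a (site, value) table that
#' the phantom interpolates linearly along the bone length.
#'
#' @param site percent sites, non-decreasing.
#' @param value values at those sites.
#' @return data.frame with columns \code{site} and \code{value}.
#' @export
controlPoints <- function(site, value) {
  stopifnot(length(site) == length(value), !is.unsorted(site))
  data.frame(site = as.numeric(site), value = as.numeric(value))
}
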