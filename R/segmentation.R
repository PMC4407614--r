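# Cross-section segmentation: deterministic two-means intensity split,
# largest-component fibula exclusion, enclosed-cavity marrow labeling.

#' Exact 1-D two-means intensity threshold
#'
#' Splits pixel intensities into two clusters minimizing the within-cluster
#' sum of squares. In one dimension the optimal 2-means partition is a
#' split point in sorted order, so the global optimum is found by an
#' exhaustive scan over the sorted unique values; there is no random
#' initialization and the result is fully deterministic. The returned
#' threshold is the midpoint of the two final cluster means.
#'
#' @param intensities numeric vector of pixel values (at least two distinct).
#' @return the scalar intensity threshold.
#' @examples
#' kmeansThreshold(c(0, 0, 0, 100, 100, 100))  # 50
#' kmeansThreshold(c(0, 10, 90, 100))          # 50
#' @export
kmeansThreshold <- function(intensities) {
  x <- as.numeric(intensities)
  x <- sort(x[is.finite(x)])
  r <- rle(x)
  u <- r$values
  w <- as.numeric(r$lengths)
  if (length(u) < 2L) stop("degenerate histogram: all pixel values identical")
  cw <- cumsum(w)
  cs <- cumsum(w * u)
  cs2 <- cumsum(w * u^2)
  n <- cw[length(cw)]
  s <- cs[length(cs)]
  s2 <- cs2[length(cs2)]
  k <- seq_len(length(u) - 1L)
  n1 <- cw[k]; s1 <- cs[k]; q1 <- cs2[k]
  n2 <- n - n1; sR <- s - s1; q2 <- s2 - q1
  wcss <- (q1 - s1^2 / n1) + (q2 - sR^2 / n2)
  best <- which.min(wcss)                      # ties: lowest split point
  (s1[best] / n1[best] + sR[best] / n2[best]) / 2
}

#' Binarize a grayscale slice by its own two-means threshold
#'
#' Each pixel is classified by similarity to the two cluster means, i.e.
#' candidate bone iff intensity >= threshold (or < threshold when the
#' reconstruction has dark bone on a bright background).
#'
#' @param image grayscale matrix.
#' @param darkBone set TRUE for inverted-contrast reconstructions.
#' @return logical candidate-bone mask; all-FALSE with a warning when the
#'   histogram is degenerate.
#' @export
binarizeSlice <- function(image, darkBone = FALSE) {
  stopifnot(is.matrix(image), length(image) > 0L)
  th <- tryCatch(kmeansThreshold(image), error = function(e) NA_real_)
  if (is.na(th)) {
    warning("degenerate histogram: returning all-background mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  if (darkBone) image < th else image >= th
}

#' Keep only the largest connected component of a mask
#'
#' Pixels disconnected from the main bony component (the fibula and any
#' speckle) are classified background by retaining only the 8-connected
#' component of maximal pixel count. Exact ties are resolved toward the
#' component containing the lexicographically smallest (row, col) pixel,
#' with a warning.
#'
#' @param mask logical mask with at least one foreground pixel.
#' @param minSpeck drop components smaller than this many pixels before
#'   choosing (0 disables the pre-cleanup).
#' @return logical mask of the surviving component.
#' @export
isolateLargestComponent <- function(mask, minSpeck = 0L) {
  if (!any(mask)) stop("no bone found: mask has no foreground pixels")
  lab <- labelComponents8(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (minSpeck > 0L) {
    small <- which(sizes < minSpeck)
    if (length(small) < length(sizes)) {
      lab[lab %in% small] <- 0L
      sizes[small] <- 0L
    }
  }
  top <- which(sizes == max(sizes))
  if (length(top) > 1L) {
    warning("tied largest components; keeping the one with the smallest ",
            "(row, col) pixel")
    nc <- ncol(mask)
    firstKey <- vapply(top, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      min((idx[, 1L] - 1) * nc + idx[, 2L])
    }, numeric(1L))
    top <- top[which.min(firstKey)]
  }
  lab == top
}

#' Classify the enclosed cavity of a cortical mask
#'
#' Non-bone pixels reachable from the image border through non-bone pixels
#' (4-connectivity, the standard dual of 8-connected foreground) are
#' background; enclosed non-bone pixels are marrow. A slice with no
#' enclosed marrow is breached when the cortex visibly fails to close (its
#' convex hull contains a substantial non-bone interior); a solid convex
#' section is not breached and simply has zero marrow area.
#'
#' @param cortexMask logical mask of the (single-component) cortex.
#' @param sitePct percent site recorded in the labeling (optional).
#' @param threshold intensity threshold recorded in the labeling (optional).
#' @return A \linkS4class{CrossSectionLabeling}.
#' @export
classifyCavity <- function(cortexMask, sitePct = NA_real_,
                           threshold = NA_real_) {
  stopifnot(is.matrix(cortexMask), is.logical(cortexMask))
  lab <- labelComponents4(!cortexMask)
  borderLabels <- unique(c(lab[1L, ], lab[nrow(lab), ],
                           lab[, 1L], lab[, ncol(lab)]))
  borderLabels <- borderLabels[borderLabels > 0L]
  marrow <- !cortexMask & !(lab %in% borderLabels)
  labels <- matrix(LBL_BACKGROUND, nrow(cortexMask), ncol(cortexMask))
  labels[cortexMask] <- LBL_CORTEX
  labels[marrow] <- LBL_MARROW
  isBreached <- FALSE
  if (!any(marrow) && any(cortexMask)) {
    # distinguish a broken ring (breached) from a genuinely solid section
    ha <- hullArea(cortexMask)
    deficit <- if (ha > 0) (ha - sum(cortexMask)) / ha else 0
    isBreached <- deficit > 0.05
  }
  new("CrossSectionLabeling", labels = labels, breached = isBreached,
      threshold = as.numeric(threshold), sitePct = as.numeric(sitePct))
}

#' Segment one grayscale cross-section
#'
#' Composite of \code{\link{binarizeSlice}},
#' \code{\link{isolateLargestComponent}} and \code{\link{classifyCavity}}:
#' yields the background/cortex/marrow labeling with the breach flag and
#' the intensity threshold used. The whole chain is deterministic, so equal
#' input images give bit-identical labelings across runs.
#'
#' @param image grayscale matrix.
#' @param sitePct percent site to record.
#' @param darkBone inverted-contrast flag (see \code{\link{binarizeSlice}}).
#' @param minSpeck speckle pre-cleanup threshold, px (0 = off).
#' @param minArea warn when the segmented cortex is smaller than this, px
#'   (guards against pure-noise images).
#' @return A \linkS4class{CrossSectionLabeling}.
#' @export
segmentSlice <- function(image, sitePct = NA_real_, darkBone = FALSE,
                         minSpeck = 0L, minArea = 0L) {
  mask <- binarizeSlice(image, darkBone = darkBone)
  if (!any(mask)) stop("no bone found: binarization produced an empty mask")
  th <- kmeansThreshold(image)
  main <- isolateLargestComponent(mask, minSpeck = minSpeck)
  if (minArea > 0L && sum(main) < minArea)
    warning(sprintf("segmented component has only %d px (< minArea = %d)",
                    sum(main), as.integer(minArea)))
  classifyCavity(main, sitePct = sitePct, threshold = th)
}
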