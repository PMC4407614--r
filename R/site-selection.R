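#' Map a percent site to a slice index
#'
#' A bone of \code{nSlices} slices is parameterized so that 0% is the first
#' and 100% the last slice; intermediate sites map to
#' \code{round(pct/100 * (nSlices - 1))} with half rounded away from zero.
#'
#' @param nSlices total number of slices in the stack (at least 11).
#' @param pct percent site(s) along the bone length, in [0, 100].
#' @param zeroBased return 0-based indices (default) or 1-based R indices.
#' @return integer slice index/indices.
#' @examples
#' siteToSliceIndex(101, 50)   # 50
#' siteToSliceIndex(1000, 37)  # 370
#' @export
siteToSliceIndex <- function(nSlices, pct, zeroBased = TRUE) {
  if (nSlices < 11L) stop("need at least 11 slices")
  if (any(pct < 0 | pct > 100)) stop("pct must lie in [0, 100]")
  idx <- as.integer(roundHalfUp(pct / 100 * (nSlices - 1L)))
  if (zeroBased) idx else idx + 1L
}

#' Enumerate the analysis sites of a stack
#'
#' Returns the plan of 1%-spaced percent sites between \code{lo} and
#' \code{hi} inclusive and their slice indices. The defaults (10--90%)
#' yield the standard 81 analysis sites; the extremes of the bone are
#' excluded because proximal trabecular bone and the distal calcaneus make
#' cortical segmentation unreliable there.
#'
#' @param nSlices total slice count.
#' @param lo,hi integer percent bounds of the analyzed range, lo < hi.
#' @return A list with elements \code{nSlices}, \code{sites} (integer
#'   percents) and \code{indexOf} (named integer vector of 0-based slice
#'   indices).
#' @examples
#' plan <- selectAnalysisSites(500)
#' length(plan$sites)  # 81
#' @export
selectAnalysisSites <- function(nSlices, lo = 10L, hi = 90L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo >= hi) stop("site range is empty: lo must be < hi")
  if (lo < 0L || hi > 100L) stop("site bounds must lie in [0, 100]")
  sites <- seq.int(lo, hi, by = 1L)
  idx <- siteToSliceIndex(nSlices, sites)
  names(idx) <- sites
  list(nSlices = as.integer(nSlices), sites = sites, indexOf = idx)
}
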