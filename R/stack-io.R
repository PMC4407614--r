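# Reading slice folders, writing binarized per-site images and the collated
# per-site CSV, and reading profile CSVs back for statistics.

readSliceImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext == "png") png::readPNG(path)
    else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
    else stop(sprintf("unsupported image format '.%s'", ext))
  }, error = function(e) stop(sprintf("cannot read slice '%s': %s",
                                      basename(path), conditionMessage(e)),
                              call. = FALSE))
  if (length(dim(img)) == 3L) {
    # colour image: convert to single channel by Rec.709 luminance
    ch <- dim(img)[3L]
    img <- if (ch >= 3L)
      0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    else img[, , 1L]
  }
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Read a folder of sequential cross-section images as an ImageStack
#'
#' Files matching \code{pattern} are ordered by natural sort on the numeric
#' components of their names (s1, s2, s10 ... not lexicographic) and read as
#' 8-bit grayscale; colour images are collapsed by luminance. By convention
#' ascending file number runs proximal to distal; set \code{reversed} when
#' the reconstruction was exported the other way.
#'
#' @param folder directory containing the slice images (the "in path").
#' @param pattern filename glob, default all PNG/TIFF files.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @param reversed flip the slice order after sorting.
#' @param sourceId bone identifier; defaults to the folder name.
#' @return An \linkS4class{ImageStack}.
#' @export
readStack <- function(folder, pattern = "*", geometry = voxelGeometry(),
                      reversed = FALSE, sourceId = basename(folder)) {
  if (!dir.exists(folder)) stop(sprintf("folder '%s' does not exist", folder))
  files <- Sys.glob(file.path(folder, pattern))
  files <- files[grepl("\\.(png|tif|tiff)$", files, ignore.case = TRUE)]
  if (length(files) == 0L) stop("no slices found")
  files <- files[naturalOrder(basename(files))]
  if (reversed) files <- rev(files)
  slices <- lapply(files, readSliceImage)
  dims <- vapply(slices, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("inconsistent slice shape across files")
  imageStack(slices, geometry = geometry, sourceId = sourceId)
}

#' Write the binarized cortex of a labeled slice
#'
#' Writes a lossless grayscale image with cortex pixels as foreground (255)
#' and everything else background (0), at the same pixel dimensions as the
#' source slice, so downstream tools see the tibia without the fibula.
#'
#' @param labeling a \linkS4class{CrossSectionLabeling}.
#' @param path output file path (written as PNG).
#' @return the path, invisibly.
#' @export
writeBinarizedSlice <- function(labeling, path) {
  stopifnot(is(labeling, "CrossSectionLabeling"))
  m <- matrix(0, nrow(labeling@labels), ncol(labeling@labels))
  m[labeling@labels == LBL_CORTEX] <- 1
  ok <- tryCatch({png::writePNG(m, target = path); TRUE},
                 error = function(e) stop(sprintf(
                   "cannot write '%s': %s", path, conditionMessage(e)),
                   call. = FALSE))
  invisible(path)
}

#' Read a binarized slice back as a logical cortex mask
#'
#' @param path a PNG written by \code{\link{writeBinarizedSlice}}.
#' @return logical matrix, TRUE for cortex.
#' @export
readBinarizedSlice <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

csvColumns <- function() {
  c(profileColumns(), "ct_ar_mm2", "ma_ar_mm2", "tt_ar_mm2")
}

# tiny deterministic checksum of the run configuration, for the CSV header
configHash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    ""), collapse = "|")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xFFFFFFFF)
}

#' Write the collated per-site profile CSV
#'
#' One row per analyzed site with the fixed column order site_pct,
#' slice_index, ct_ar, ma_ar, tt_ar, cs_th, i_min, i_max, pmi, centroid_x,
#' centroid_y, feret_max, feret_min, feret_angle, eccentricity, dev_x,
#' dev_y, breached, followed by mm^2 companions of the areas computed from
#' the voxel geometry. Missing values (breached sites) are written as empty
#' fields. Provenance (package version, source id, voxel size, reference
#' site, axis anchors, config hash) is recorded in leading comment lines
#' prefixed with '#'.
#'
#' @param profile a \linkS4class{BoneProfile}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeProfileCsv <- function(profile, path) {
  stopifnot(is(profile, "BoneProfile"))
  d <- profile@data
  f <- (pixelSize(geometry(profile)) / 1000)^2
  d$ct_ar_mm2 <- d$ct_ar * f
  d$ma_ar_mm2 <- d$ma_ar * f
  d$tt_ar_mm2 <- d$tt_ar * f
  d <- d[, csvColumns()]
  anch <- profile@anchors
  hdr <- c(
    sprintf("# sitespec %s", as.character(utils::packageVersion("sitespec"))),
    sprintf("# source_id: %s", profile@sourceId),
    sprintf("# pixel_size_um: %.10g", pixelSize(geometry(profile))),
    sprintf("# slice_thickness_um: %.10g",
            geometry(profile)@sliceThickness),
    sprintf("# ref_site: %s", format(profile@refSite)),
    sprintf("# normalized: %s", profile@normalized),
    sprintf("# axis_anchors: %s",
            if (nrow(anch)) paste(sprintf("%g:(%.10g,%.10g)", anch$site,
                                          anch$x, anch$y), collapse = " ")
            else "none"),
    sprintf("# config: %s", configHash(profile@sourceId,
                                       pixelSize(geometry(profile)),
                                       profile@refSite, anch$site)))
  fmt <- function(v) {
    out <- if (is.logical(v)) as.character(v)
           else formatC(v, digits = 15, format = "g")
    out[is.na(v)] <- ""          # missing values become empty fields
    out
  }
  dd <- as.data.frame(lapply(d, fmt), optional = TRUE)
  names(dd) <- names(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(dd, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile CSV back into a BoneProfile
#'
#' Inverse of \code{\link{writeProfileCsv}}: empty fields become NA,
#' provenance comments restore the voxel geometry, reference site and axis
#' anchors. Unknown extra columns are tolerated with a warning.
#'
#' @param path CSV path.
#' @return A \linkS4class{BoneProfile}.
#' @export
readProfileCsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  d <- utils::read.csv(text = paste(body, collapse = "\n"),
                       na.strings = c("", "NA"))
  miss <- setdiff(csvColumns(), names(d))
  if (length(miss))
    stop(paste("profile CSV lacks columns:", paste(miss, collapse = ", ")))
  extra <- setdiff(names(d), csvColumns())
  if (length(extra))
    warning(paste("ignoring unknown columns:", paste(extra, collapse = ", ")))
  d <- d[, profileColumns()]
  d$breached <- as.logical(d$breached)
  grab <- function(key, default = NA) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (length(ln)) trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
    else default
  }
  px <- suppressWarnings(as.numeric(grab("pixel_size_um", "4.8")))
  sl <- suppressWarnings(as.numeric(grab("slice_thickness_um", "4.8")))
  srcId <- grab("source_id", "bone")
  refSite <- suppressWarnings(as.numeric(grab("ref_site", "NA")))
  normalized <- identical(grab("normalized", "FALSE"), "TRUE")
  anchors <- data.frame(site = numeric(0), x = numeric(0), y = numeric(0))
  anch <- grab("axis_anchors", "none")
  if (!identical(anch, "none") && !is.na(anch)) {
    m <- regmatches(anch,
      gregexpr("([-0-9.eE+]+):\\(([-0-9.eE+]+),([-0-9.eE+]+)\\)", anch))[[1L]]
    if (length(m)) {
      parts <- do.call(rbind, lapply(m, function(s) {
        v <- regmatches(s, regexec(
          "([-0-9.eE+]+):\\(([-0-9.eE+]+),([-0-9.eE+]+)\\)", s))[[1L]][-1L]
        as.numeric(v)
      }))
      anchors <- data.frame(site = parts[, 1L], x = parts[, 2L],
                            y = parts[, 3L])
    }
  }
  p <- boneProfile(d, geometry = voxelGeometry(ifelse(is.na(px), 4.8, px),
                                               ifelse(is.na(sl), 4.8, sl)),
                   sourceId = srcId, anchors = anchors)
  p@refSite <- refSite
  p@normalized <- normalized
  p
}
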