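#' ROI label maps
#'
#' A `roi_map` is an integer label image on the same `(y, x)` grid as its
#' stack, with 0 marking background and each positive label one region of
#' interest.  Labels may be sparse (gaps in the label sequence are allowed
#' and preserved).  Each label carries a biological class and a persistent
#' cell identity that is stable across repeated recordings of the same field
#' of view, which is what makes trace stitching possible.
#'
#' @param labels integer matrix of non-negative labels.
#' @param class_of named character vector mapping label (as name) to class,
#'   one of `"IHC"`, `"SC"`, `"terminal"`, `"GER-box"`.  Defaults to `"IHC"`
#'   for every label.
#' @param identity_of named character vector mapping label to persistent
#'   identity.  Defaults to `"<class>_<label>"`.  Identities must be unique
#'   within a class.
#' @return an object of class `roi_map`.
#' @export
roi_map <- function(labels, class_of = NULL, identity_of = NULL) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (any(labels < 0)) stop("labels must be non-negative")
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0]))
  nm <- as.character(ids)
  if (is.null(class_of)) class_of <- stats::setNames(rep("IHC", length(ids)), nm)
  class_of <- class_of[nm]
  names(class_of) <- nm
  class_of[is.na(class_of)] <- "IHC"
  if (is.null(identity_of))
    identity_of <- stats::setNames(paste0(class_of, "_", nm), nm)
  identity_of <- identity_of[nm]
  names(identity_of) <- nm
  if (anyNA(identity_of)) identity_of[is.na(identity_of)] <-
      paste0(class_of[is.na(identity_of)], "_", nm[is.na(identity_of)])
  for (cl in unique(class_of)) {
    idc <- identity_of[class_of == cl]
    if (anyDuplicated(idc)) stop("identities must be unique within class ", cl)
  }
  structure(list(labels = labels, class_of = class_of,
                 identity_of = identity_of),
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("roi_map: %d x %d px, %d ROIs (%s)\n",
              nrow(x$labels), ncol(x$labels), length(x$class_of),
              paste(names(table(x$class_of)), table(x$class_of),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

roi_labels <- function(rois) as.integer(names(rois$class_of))

#' Read a ROI label image from a 16-bit TIFF
#'
#' @param path path to a single-page 16-bit label TIFF.
#' @inheritParams roi_map
#' @return a [roi_map()].
#' @export
read_roi_map <- function(path, class_of = NULL, identity_of = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2L) stop("label image must be single-channel")
  if (any(img < 0)) stop("label image with negative values")
  roi_map(img, class_of = class_of, identity_of = identity_of)
}

#' Write a ROI label image as 16-bit TIFF
#'
#' @param rois a [roi_map()].
#' @param path output path.
#' @export
write_roi_map <- function(rois, path) {
  stopifnot(inherits(rois, "roi_map"))
  if (max(rois$labels) > 65535) stop("labels exceed 16-bit range")
  tiff::writeTIFF(rois$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Erode every ROI to reduce cross-contamination between neighbours
#'
#' Each label is eroded independently with a disc structuring element so
#' that erosion can never merge adjacent cells; labels that vanish entirely
#' are dropped and logged.  Eroding by 1-3 px trims the pixels at cell
#' borders where the fluorescence of adjacent cells bleeds in.
#'
#' @param rois a [roi_map()].
#' @param radius erosion radius in pixels, between 1 and 3 (default 2).
#' @return the eroded [roi_map()].
#' @export
erode_rois <- function(rois, radius = 2) {
  stopifnot(inherits(rois, "roi_map"))
  if (radius < 1 || radius > 3) stop("erosion radius must be in [1, 3]")
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- matrix(0L, nrow(rois$labels), ncol(rois$labels))
  kept <- character()
  for (lb in roi_labels(rois)) {
    m <- (rois$labels == lb) * 1
    e <- EBImage::erode(m, brush)
    if (any(e > 0)) {
      out[e > 0] <- lb
      kept <- c(kept, as.character(lb))
    }
  }
  dropped <- setdiff(names(rois$class_of), kept)
  if (length(dropped))
    ca_log("erode_rois: dropped %d ROI(s) that vanished at radius %d: %s",
           length(dropped), radius, paste(dropped, collapse = ", "))
  if (!length(kept)) stop("all ROIs vanished under erosion")
  roi_map(out, class_of = rois$class_of[kept],
          identity_of = rois$identity_of[kept])
}

# per-label pixel index list on the (y, x) grid
roi_pixels <- function(rois) {
  px <- split(seq_along(rois$labels), rois$labels)
  px[names(px) != "0"]
}
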