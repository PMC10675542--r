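# File formats: multilayer (multi-page) TIFF annotation files with the
# preview image on page 1 and the binary tissue mask on page 2, plus plain
# PNG/TIFF image + mask pairs. 8-bit, uncompressed by default.

readRaster <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    raw <- switch(ext,
        png = png::readPNG(path),
        tif = , tiff = tiff::readTIFF(path),
        stop("unsupported image format: ", path))
    raw
}

# [0,1] float page -> integer RGB array (grayscale promoted to 3 channels,
# alpha dropped).
pageToRGB <- function(page) {
    if (is.matrix(page)) page <- array(rep(page, 3L), c(dim(page), 3L))
    if (dim(page)[3] > 3L) page <- page[, , 1:3, drop = FALSE]
    px <- round(page * 255)
    storage.mode(px) <- "integer"
    px
}

# [0,1] float page -> binary mask (first channel if multi-channel).
pageToMask <- function(page) {
    if (!is.matrix(page)) page <- page[, , 1, drop = TRUE]
    binarizeMask(page * 255)
}

#' Read a multilayer TIF annotation file
#'
#' Page 1 is the RGB preview image, page 2 the binary tissue mask (any mask
#' value above the 127 midpoint becomes foreground). Grayscale previews are
#' promoted to three identical channels.
#'
#' @param path path to a multi-page TIFF.
#' @param id sample identifier (defaults to the file name without extension).
#' @return A \linkS4class{SlidePreview} with a binarized mask.
#' @export
readMultilayerTif <- function(path, id = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
        stop(sprintf("multilayer TIF '%s' has %d page(s); expected >= 2",
                     path, length(pages)))
    img <- pageToRGB(pages[[1]])
    mask <- pageToMask(pages[[2]])
    if (!identical(dim(mask), dim(img)[1:2]))
        stop(sprintf(
            "page dimensions differ in '%s': image %d x %d vs mask %d x %d",
            path, dim(img)[1], dim(img)[2], nrow(mask), ncol(mask)))
    if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
    slidePreview(img, mask, id = id)
}

#' Write a multilayer TIF annotation file
#'
#' Writes a two-page baseline TIFF: page 1 the 8-bit RGB preview, page 2 the
#' binary mask (0/255). Uncompressed by default; deflate available.
#'
#' @param sample a \linkS4class{SlidePreview} with a mask.
#' @param path output path.
#' @param compression "none" (default) or "deflate".
#' @return Invisibly, the path.
#' @export
writeMultilayerTif <- function(sample, path, compression = c("none",
                                                             "deflate")) {
    stopifnot(is(sample, "SlidePreview"))
    compression <- match.arg(compression)
    if (is.null(sample@mask))
        stop("sample '", sample@id,
             "' has no tissue mask; a multilayer TIF needs both pages")
    # both pages are written with 3 samples per pixel: libtiff handles a
    # uniform page layout much more robustly than mixed RGB + grayscale
    # directories, and the mask page stays bit-exact (3 identical channels)
    maskPage <- array(rep(sample@mask / 255, 3L), c(dim(sample@mask), 3L))
    pages <- list(sample@image / 255, maskPage)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                              compression = compression), silent = TRUE)
    if (inherits(ok, "try-error"))
        stop("cannot write multilayer TIF to '", path, "': ",
             attr(ok, "condition")$message)
    invisible(path)
}

#' Read a plain image + mask file pair
#'
#' @param imagePath path to a PNG or single-page TIFF image (grayscale is
#'   promoted to RGB).
#' @param maskPath path to the binary mask image of identical dimensions.
#' @param id sample identifier (defaults to the image file name).
#' @return A \linkS4class{SlidePreview}.
#' @export
readImageMaskPair <- function(imagePath, maskPath, id = NULL) {
    img <- pageToRGB(readRaster(imagePath))
    mask <- pageToMask(readRaster(maskPath))
    if (!identical(dim(mask), dim(img)[1:2]))
        stop(sprintf(
            "dimension mismatch: image '%s' is %d x %d but mask '%s' is %d x %d",
            imagePath, dim(img)[1], dim(img)[2], maskPath, nrow(mask),
            ncol(mask)))
    if (is.null(id)) id <- tools::file_path_sans_ext(basename(imagePath))
    slidePreview(img, mask, id = id)
}

writeImagePNG <- function(px, path) {
    if (is.matrix(px)) png::writePNG(px / 255, path)
    else png::writePNG(px / 255, path)
    invisible(path)
}
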