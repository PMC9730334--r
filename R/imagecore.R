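#' @useDynLib veinmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Shared raster conventions
# -------------------------
# A binary mask is a plain integer matrix of {0, 1}, indexed mask[row, col]:
# row 1 is y = 0 (top, y grows downward), col 1 is x = 0 (left, x grows
# rightward) -- the screen/image coordinate system. Foreground (vein) is 1;
# files are written with foreground 255 for viewability. Gray images are
# integer matrices in [0, 255]; RGB images are height x width x 3 integer
# arrays in [0, 255].

assertMask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || nrow(mask) < 1 || ncol(mask) < 1)
    stop(arg, " must be a non-empty matrix")
  if (!all(mask %in% c(0L, 1L)))
    stop(arg, " must contain only 0 and 1")
  invisible(TRUE)
}

assertSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shapes")
  invisible(TRUE)
}

#' Read a binary mask from a PNG or TIFF file
#'
#' Color inputs are converted to gray by the 0.299/0.587/0.114 weighting
#' first; gray levels strictly above \code{threshold} become foreground.
#'
#' @param path path to a PNG or TIFF file.
#' @param threshold gray level in [0, 255]; pixels > threshold map to 1.
#' @return An integer {0,1} matrix (rows = y downward, cols = x rightward).
#' @seealso \code{\link{writeMask}}
#' @examples
#' f <- tempfile(fileext = ".png")
#' writeMask(diag(5L), f)
#' readMask(f)
#' @export
readMask <- function(path, threshold = 127) {
  g <- readGrayImage(path)
  matrix(as.integer(g > threshold), nrow(g), ncol(g))
}

#' Read an 8-bit grayscale image from PNG or TIFF
#'
#' @inheritParams readMask
#' @return An integer matrix with values in [0, 255].
#' @export
readGrayImage <- function(path) {
  px <- readRaster(path)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) {
      px <- toGray(round(px[, , 1:3] * 255))
      return(px)
    }
    px <- px[, , 1]
  }
  matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
}

#' Read an RGB image from PNG or TIFF
#'
#' Grayscale files are replicated across the three channels.
#'
#' @inheritParams readMask
#' @return A height x width x 3 integer array with values in [0, 255].
#' @export
readRgbImage <- function(path) {
  px <- readRaster(path)
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  array(as.integer(round(px * 255)), dim(px))
}

readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)"))
  if (length(px) == 0 || any(dim(px)[1:2] < 1)) stop("zero-size image: ", path)
  px
}

#' Write a binary mask to a PNG or TIFF file
#'
#' Foreground is written as 255 so masks are viewable; the round trip
#' through \code{\link{readMask}} is bit-exact.
#'
#' @param mask integer {0,1} matrix.
#' @param path output path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  assertMask(mask)
  writeRaster(mask * 1.0, path)
}

#' Write a gray (matrix, [0,255]) or RGB (h x w x 3) image
#'
#' @param img integer matrix or array with values in [0, 255].
#' @param path output path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
writeImageFile <- function(img, path) {
  writeRaster(img / 255, path)
}

writeRaster <- function(px, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)"))
  invisible(path)
}

#' Bitwise mask algebra
#'
#' \code{bitwiseNot} flips every pixel; \code{bitwiseOr} and
#' \code{bitwiseAnd} are the elementwise maximum and minimum of two masks of
#' identical shape. These are the NOT/OR used by hole filling and the AND
#' used to fuse contour and skeleton rasters.
#'
#' @param mask,a,b integer {0,1} matrices.
#' @return An integer {0,1} matrix of the same shape.
#' @examples
#' m <- diag(3L)
#' bitwiseAnd(m, bitwiseNot(m))   # all zero
#' @export
bitwiseNot <- function(mask) {
  assertMask(mask)
  1L - mask
}

#' @rdname bitwiseNot
#' @export
bitwiseOr <- function(a, b) {
  assertMask(a, "a"); assertMask(b, "b"); assertSameShape(a, b)
  pmax(a, b)
}

#' @rdname bitwiseNot
#' @export
bitwiseAnd <- function(a, b) {
  assertMask(a, "a"); assertMask(b, "b"); assertSameShape(a, b)
  pmin(a, b)
}

#' Connected-component labeling
#'
#' Labels foreground components under 4- or 8-connectivity; the background
#' is labeled 0. 8-connectivity is the package default for vein content so
#' thin diagonal strokes do not fragment.
#'
#' @param mask integer {0,1} matrix.
#' @param connectivity 4 or 8.
#' @return A list with \code{labels} (integer matrix, background 0) and
#'   \code{nComponents}.
#' @examples
#' m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L
#' connectedComponents(m, 4)$nComponents   # 2
#' connectedComponents(m, 8)$nComponents   # 1
#' @export
connectedComponents <- function(mask, connectivity = 8) {
  assertMask(mask)
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8")
  lab <- cpp_label(storage.mode2int(mask), as.integer(connectivity))
  list(labels = lab, nComponents = max(lab))
}

storage.mode2int <- function(m) {
  storage.mode(m) <- "integer"
  m
}
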