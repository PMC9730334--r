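# F-3MS refinement pipeline
# -------------------------
# Flood-fill hole closing, opening, weighted grayscale, median filtering,
# Otsu binarization and Lantuejoul morphological skeletonization, composed
# in that order. The preprocessing is what suppresses skeleton burrs: holes
# and rough contours, not the skeleton operator, are the source of spurs.

skeletonBrush <- function(element = c("cross", "square")) {
  element <- match.arg(element)
  if (element == "cross")
    matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L), 3, 3)
  else
    matrix(1L, 3, 3)
}

squareBrush <- function(side) matrix(1L, side, side)

#' Binary erosion and dilation
#'
#' Flat binary morphology with an explicit 0/1 structuring element (odd
#' sides, origin at the center). Pixels outside the raster count as
#' background, so erosion removes foreground touching the border and the
#' skeleton iteration always terminates.
#'
#' @param mask integer {0,1} matrix.
#' @param elem 0/1 structuring-element matrix; see
#'   \code{\link{structuringElement}}.
#' @return The transformed integer {0,1} matrix.
#' @export
binaryErode <- function(mask, elem = structuringElement("square")) {
  assertMask(mask)
  cpp_morph(storage.mode2int(mask), storage.mode2int(elem), TRUE)
}

#' @rdname binaryErode
#' @export
binaryDilate <- function(mask, elem = structuringElement("square")) {
  assertMask(mask)
  cpp_morph(storage.mode2int(mask), storage.mode2int(elem), FALSE)
}

#' Structuring elements for binary morphology
#'
#' @param shape \code{"cross"} (the 4-neighborhood plus center) or
#'   \code{"square"} (full box).
#' @param side odd element side.
#' @return A 0/1 integer matrix.
#' @export
structuringElement <- function(shape = c("cross", "square"), side = 3) {
  shape <- match.arg(shape)
  if (side %% 2 == 0) stop("side must be odd")
  if (shape == "square") return(matrix(1L, side, side))
  h <- side %/% 2
  m <- matrix(0L, side, side)
  m[abs(row(m) - h - 1) + abs(col(m) - h - 1) <= h] <- 1L
  m
}

erodeMask <- function(mask, elem) cpp_morph(storage.mode2int(mask), elem, TRUE)
dilateMask <- function(mask, elem) cpp_morph(storage.mode2int(mask), elem, FALSE)

#' Fill interior holes of a binary mask
#'
#' Three-step flood-fill identity: flood-fill the background from every
#' border seed (4-connectivity for background), take the NOT of the flood
#' fill, and OR it with the original. Every background region not connected
#' to the border becomes foreground; border-connected background is
#' untouched. Extensive and idempotent.
#'
#' @param mask integer {0,1} matrix.
#' @return The hole-free integer {0,1} matrix.
#' @examples
#' ring <- matrix(0L, 7, 7); ring[2:6, 2:6] <- 1L; ring[3:5, 3:5] <- 0L
#' sum(fillHoles(ring))   # 25: the ring becomes a solid square
#' @export
fillHoles <- function(mask) {
  assertMask(mask)
  bg <- bitwiseNot(storage.mode2int(mask))
  lab <- cpp_label(bg, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  flooded <- matrix(as.integer(lab %in% border), nrow(mask), ncol(mask))
  bitwiseOr(storage.mode2int(mask), bitwiseNot(bitwiseOr(storage.mode2int(mask), flooded)))
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a square structuring element; isolated
#' specks smaller than the element vanish. Anti-extensive: the output is a
#' subset of the input. Pixels outside the raster count as background.
#'
#' @param mask integer {0,1} matrix.
#' @param kernelSide odd side of the square element.
#' @return The opened integer {0,1} matrix.
#' @export
openMask <- function(mask, kernelSide = 3) {
  assertMask(mask)
  if (kernelSide %% 2 == 0) stop("kernelSide must be odd")
  elem <- squareBrush(kernelSide)
  dilateMask(erodeMask(mask, elem), elem)
}

#' Weighted grayscale conversion
#'
#' Gray = 0.299 R + 0.587 G + 0.114 B, rounded half away from zero and
#' clipped to [0, 255].
#'
#' @param img height x width x 3 integer array in [0, 255].
#' @return An integer matrix in [0, 255].
#' @examples
#' toGray(array(c(255, 0, 0), c(1, 1, 3)))   # 76
#' @export
toGray <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("img must be a height x width x 3 array")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  g <- floor(g + 0.5)                     # round half away from zero (g >= 0)
  matrix(as.integer(pmin(pmax(g, 0), 255)), dim(img)[1], dim(img)[2])
}

#' Square median filter with edge replication
#'
#' @param img integer gray matrix in [0, 255].
#' @param kernelSide odd window side.
#' @return The filtered integer matrix.
#' @export
medianFilterImage <- function(img, kernelSide = 5) {
  if (!is.matrix(img)) stop("img must be a matrix")
  if (kernelSide %% 2 == 0) stop("kernelSide must be odd")
  cpp_median_filter(storage.mode2int(img), as.integer(kernelSide))
}

#' Otsu threshold (maximum between-class variance)
#'
#' Selects the threshold k* maximizing the between-class variance
#' w0 w1 (u0 - u1)^2 over all gray levels, where w0/w1 are the class
#' probability masses of levels [0..k] and [k+1..255] and u0/u1 their
#' means; ties are broken by the smallest k. These satisfy
#' w0 + w1 = 1 and w0 u0 + w1 u1 = uT (the global mean). Pixels strictly
#' above k* become foreground.
#'
#' @param img integer gray matrix in [0, 255].
#' @return A list with \code{threshold} (gray level k*) and \code{mask}
#'   (integer {0,1} matrix of \code{img > threshold}). A constant image
#'   yields its own level as threshold, an all-0 mask, and a warning.
#' @export
otsuThreshold <- function(img) {
  if (!is.matrix(img) || length(img) < 1) stop("img must be a non-empty matrix")
  if (min(img) == max(img)) {
    warning("constant image: Otsu threshold is degenerate")
    return(list(threshold = as.integer(img[1]),
                mask = matrix(0L, nrow(img), ncol(img))))
  }
  counts <- tabulate(as.integer(img) + 1L, 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  uT <- mu[256]
  w1 <- 1 - w0
  u0 <- ifelse(w0 > 0, mu / w0, 0)
  u1 <- ifelse(w1 > 0, (uT - mu) / w1, 0)
  sigmaB <- w0 * w1 * (u0 - u1)^2
  sigmaB[256] <- -Inf                      # k = 255 leaves class 1 empty
  k <- which.max(sigmaB) - 1L              # which.max takes the smallest tie
  list(threshold = as.integer(k),
       mask = matrix(as.integer(img > k), nrow(img), ncol(img)))
}

#' Lantuejoul morphological skeleton
#'
#' S(A) = union over k of [ (A erode kB) minus opening(A erode kB, B) ],
#' iterating until the k-fold erosion is empty. The output is a subset of
#' the input and satisfies the exact reconstruction identity
#' A = union over k of (S_k dilate kB). The skeleton is thin but, as is
#' characteristic of this operator, not guaranteed to be 1-px connected.
#'
#' @param mask integer {0,1} matrix.
#' @param element \code{"cross"} (default; thinner skeletons on elongated
#'   shapes) or \code{"square"}.
#' @param partials if TRUE, return the list of residuals S_k instead of
#'   their union (used by the reconstruction identity).
#' @return The skeleton mask, or a list of S_k matrices if
#'   \code{partials = TRUE}.
#' @export
morphSkeleton <- function(mask, element = c("cross", "square"),
                          partials = FALSE) {
  assertMask(mask)
  elem <- skeletonBrush(match.arg(element))
  E <- storage.mode2int(mask)
  res <- list()
  S <- matrix(0L, nrow(mask), ncol(mask))
  while (sum(E) > 0) {
    opened <- dilateMask(erodeMask(E, elem), elem)
    Sk <- matrix(as.integer(E == 1L & opened == 0L), nrow(E), ncol(E))
    res[[length(res) + 1L]] <- Sk
    S <- bitwiseOr(S, Sk)
    E <- erodeMask(E, elem)
  }
  if (partials) res else S
}

#' Count skeleton endpoints
#'
#' Endpoints are skeleton pixels with at most one 8-neighbor in the
#' skeleton; their count is the burr (spur) indicator used to compare
#' refinement pipelines.
#'
#' @param skeleton integer {0,1} matrix.
#' @return Integer endpoint count.
#' @export
countEndpoints <- function(skeleton) {
  assertMask(skeleton)
  p <- padZero(skeleton, 1)
  nb <- matrix(0L, nrow(skeleton), ncol(skeleton))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + p[2:(nrow(p) - 1) + dr, 2:(ncol(p) - 1) + dc]
  }
  sum(skeleton == 1L & nb <= 1L)
}

padZero <- function(m, k) {
  out <- matrix(0L, nrow(m) + 2 * k, ncol(m) + 2 * k)
  out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))] <- m
  out
}

renderMaskRgb <- function(mask, fg = c(255L, 0L, 0L)) {
  arr <- array(0L, c(dim(mask), 3))
  for (ch in 1:3) arr[, , ch] <- mask * fg[ch]
  arr
}

#' The F-3MS refinement pipeline
#'
#' Composition of \code{\link{fillHoles}}, \code{\link{openMask}}, a
#' red-on-black RGB rendering followed by \code{\link{toGray}} (so the
#' stage order of the original protocol is preserved for binary input),
#' \code{\link{medianFilterImage}}, \code{\link{otsuThreshold}} and
#' \code{\link{morphSkeleton}}. RGB input is first binarized by
#' grayscale + Otsu, then follows the same path.
#'
#' @param x integer {0,1} mask matrix, or height x width x 3 RGB array in
#'   [0, 255].
#' @param cfg a \code{\link{F3msConfig}}.
#' @param keepStages if TRUE, return all intermediate stages.
#' @return The skeleton mask, or (with \code{keepStages}) a list with
#'   \code{filled}, \code{opened}, \code{gray}, \code{threshold},
#'   \code{binary} and \code{skeleton}.
#' @export
f3msPipeline <- function(x, cfg = F3msConfig(), keepStages = FALSE) {
  if (length(dim(x)) == 3) {
    mask <- otsuThreshold(toGray(x))$mask
  } else {
    assertMask(x)
    mask <- storage.mode2int(x)
  }
  filled <- fillHoles(mask)
  opened <- openMask(filled, cfg@openKernel)
  if (sum(opened) == 0) {
    empty <- matrix(0L, nrow(mask), ncol(mask))
    if (keepStages)
      return(list(filled = filled, opened = opened, gray = empty,
                  threshold = 0L, binary = empty, skeleton = empty))
    return(empty)
  }
  gray <- toGray(renderMaskRgb(opened))
  gray <- medianFilterImage(gray, cfg@medianKernel)
  ot <- otsuThreshold(gray)
  skel <- morphSkeleton(ot$mask, cfg@skeletonElement)
  if (keepStages)
    list(filled = filled, opened = opened, gray = gray,
         threshold = ot$threshold, binary = ot$mask, skeleton = skel)
  else skel
}
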