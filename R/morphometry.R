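# Vein length and true-width measurement
# --------------------------------------
# Length is the skeleton pixel count times the scale bar. Width uses the
# angle-corrected geometric model: per column x, the upper/lower contour
# rows u(x), v(x) give a half-separation (v - u)/2; the local skeleton
# inclination theta (from central differences of the ordinate sequence)
# corrects it to the true width (v - u)/2 * cos(theta). Measurements are
# taken in the axis-normalized frame: the binarized vein is rotated so its
# principal axis is horizontal before contours and skeleton are extracted,
# which keeps the per-column contour functions single-valued and makes the
# pixel-count length estimate tilt-invariant.

#' Binary boundary ("Canny on a binary image")
#'
#' The exact edge set of a binary raster: foreground pixels with at least
#' one background 4-neighbor (pixels outside the raster count as
#' background). On binary input this is what a gradient edge detector
#' reduces to, with no thresholds needed.
#'
#' @param mask integer {0,1} matrix.
#' @return An integer {0,1} contour matrix.
#' @examples
#' sq <- matrix(0L, 7, 7); sq[2:6, 2:6] <- 1L
#' sum(cannyContour(sq))   # 16 border pixels of the 5x5 square
#' @export
cannyContour <- function(mask) {
  assertMask(mask)
  p <- padZero(storage.mode2int(mask), 1)
  nr <- nrow(mask); nc <- ncol(mask)
  core <- p[2:(nr + 1), 2:(nc + 1)]
  nmin <- pmin(p[1:nr, 2:(nc + 1)], p[3:(nr + 2), 2:(nc + 1)],
               p[2:(nr + 1), 1:nc], p[2:(nr + 1), 3:(nc + 2)])
  matrix(as.integer(core == 1L & nmin == 0L), nr, nc)
}

#' Rotate a binary raster by an angle (nearest neighbor)
#'
#' Rotates about the raster center, expanding the canvas to contain the
#' rotated content; nearest-neighbor resampling keeps the raster binary.
#' Positive angles rotate from +x toward +y (clockwise on screen).
#'
#' @param mask integer {0,1} matrix.
#' @param angleRad rotation angle in radians.
#' @return The rotated integer {0,1} matrix.
#' @export
rotateMask <- function(mask, angleRad) {
  assertMask(mask)
  h <- nrow(mask); w <- ncol(mask)
  ca <- cos(angleRad); sa <- sin(angleRad)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  rx <- ca * (corners[, 1] - cx) - sa * (corners[, 2] - cy)
  ry <- sa * (corners[, 1] - cx) + ca * (corners[, 2] - cy)
  w2 <- ceiling(max(rx) - min(rx)) + 1
  h2 <- ceiling(max(ry) - min(ry)) + 1
  cx2 <- (w2 - 1) / 2; cy2 <- (h2 - 1) / 2
  xo <- rep(0:(w2 - 1), each = h2) - cx2
  yo <- rep(0:(h2 - 1), times = w2) - cy2
  xs <- round(ca * xo + sa * yo + cx)      # inverse rotation
  ys <- round(-sa * xo + ca * yo + cy)
  ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
  out <- matrix(0L, h2, w2)
  out[cbind(yo + cy2 + 1, xo + cx2 + 1)[ok, , drop = FALSE]] <-
    mask[cbind(ys + 1, xs + 1)[ok, , drop = FALSE]]
  out
}

#' Principal-axis orientation of a skeletonized vein
#'
#' Estimates the orientation of the skeleton's principal axis from its
#' second-order central moments and rotates both rasters by the negative
#' angle so the skeleton becomes horizontal (within about a degree for
#' elongated content).
#'
#' @param mask integer {0,1} matrix (typically the binarized vein).
#' @param skeleton integer {0,1} skeleton matrix; must be non-empty.
#' @return A list with rotated \code{mask}, rotated \code{skeleton} and
#'   the removed \code{angleDeg}.
#' @export
orientPrincipalAxis <- function(mask, skeleton) {
  assertMask(mask); assertMask(skeleton)
  if (sum(skeleton) == 0) stop("empty skeleton")
  phi <- principalAngle(skeleton)
  list(mask = rotateMask(mask, -phi),
       skeleton = rotateMask(skeleton, -phi),
       angleDeg = phi * 180 / pi)
}

principalAngle <- function(mask) {
  idx <- which(mask == 1L)
  x <- (idx - 1) %/% nrow(mask)
  y <- (idx - 1) %% nrow(mask)
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  0.5 * atan2(2 * mu11, mu20 - mu02)
}

#' Upper and lower contour functions of a horizontal band
#'
#' Per column with at least 2 contour pixels, u(x) is the minimal and v(x)
#' the maximal contour row; columns with fewer pixels are omitted.
#'
#' @param contour integer {0,1} contour matrix of a horizontally oriented
#'   band (see \code{\link{cannyContour}}).
#' @return A data.frame with 0-based columns \code{x}, \code{upper} and
#'   \code{lower} (rows, \code{lower >= upper}).
#' @export
contourFunctions <- function(contour) {
  assertMask(contour)
  idx <- which(contour == 1L)
  if (!length(idx)) stop("no contour pixels")
  x <- (idx - 1) %/% nrow(contour)
  y <- (idx - 1) %% nrow(contour)
  n <- tapply(y, x, length)
  u <- tapply(y, x, min)
  v <- tapply(y, x, max)
  keep <- n >= 2
  if (!any(keep)) stop("no column has >= 2 contour pixels")
  data.frame(x = as.numeric(names(u))[keep], upper = as.numeric(u[keep]),
             lower = as.numeric(v[keep]))
}

#' Cosine of the local skeleton inclination
#'
#' Central differences over (x, ordinate) samples:
#' cos(theta_i) = (x_{i+1} - x_{i-1}) /
#' sqrt((x_{i+1} - x_{i-1})^2 + (o_{i+1} - o_{i-1})^2); the endpoints copy
#' their nearest interior value. Always in (0, 1] for increasing x.
#'
#' @param xs strictly increasing column positions (>= 3 of them).
#' @param ordinates ordinate per column (same length).
#' @return Numeric vector of cosines, one per sample.
#' @examples
#' cosThetaProfile(0:4, rep(2, 5))       # all 1: horizontal skeleton
#' cosThetaProfile(0:4, 0:4)[3]          # 0.7071...: a 45-degree line
#' @export
cosThetaProfile <- function(xs, ordinates) {
  n <- length(xs)
  if (n < 3) stop("need at least 3 points")
  if (length(ordinates) != n) stop("xs and ordinates must have equal length")
  i <- 2:(n - 1)
  dx <- xs[i + 1] - xs[i - 1]
  do <- ordinates[i + 1] - ordinates[i - 1]
  ct <- dx / sqrt(dx^2 + do^2)
  c(ct[1], ct, ct[length(ct)])
}

#' Angle-corrected true-width profile
#'
#' For every column that carries both a skeleton pixel and a contour pair,
#' the half-separation (v - u)/2 is corrected by the cosine of the local
#' inclination. The ordinate entering the angle is either the skeleton
#' midline (mean skeleton row per column; default) or the half-separation
#' itself (\code{"half_separation"}, the literal reading of the geometric
#' model, under which a tilted constant-width band receives no correction).
#'
#' The half-separation is computed as (v - u + 1)/2: the physical band
#' boundary lies half a pixel outside the outermost foreground centers on
#' each side, so the raw row difference v - u underestimates the span by
#' one pixel (a systematic -1/T relative bias for a band of thickness T).
#' Likewise, the discrete ordinate carries half-pixel quantization noise
#' that a two-column derivative baseline amplifies into a downward cosine
#' bias, so the ordinate is smoothed with a short running mean (window
#' \code{smoothWindow}) before the angle is formed; the half-separation
#' itself is never smoothed.
#'
#' @param cf contour functions as returned by \code{\link{contourFunctions}}.
#' @param skeleton integer {0,1} skeleton matrix in the same oriented frame.
#' @param mode \code{"midline"} or \code{"half_separation"}.
#' @param smoothWindow odd running-mean window (columns) applied to the
#'   angle ordinate; 1 disables smoothing.
#' @return A \code{\link{WidthProfile}}.
#' @export
trueWidthProfile <- function(cf, skeleton,
                             mode = c("midline", "half_separation"),
                             smoothWindow = 9) {
  mode <- match.arg(mode)
  assertMask(skeleton)
  if (smoothWindow < 1 || smoothWindow %% 2 == 0)
    stop("smoothWindow must be odd and >= 1")
  idx <- which(skeleton == 1L)
  if (!length(idx)) stop("empty skeleton")
  sx <- (idx - 1) %/% nrow(skeleton)
  sy <- (idx - 1) %% nrow(skeleton)
  srow <- tapply(sy, sx, mean)
  scols <- as.numeric(names(srow))
  common <- intersect(scols, cf$x)
  if (length(common) < 3)
    stop("skeleton and contour share fewer than 3 columns")
  common <- sort(common)
  u <- cf$upper[match(common, cf$x)]
  v <- cf$lower[match(common, cf$x)]
  halfSep <- (v - u + 1) / 2
  ordinate <- if (mode == "midline") as.numeric(srow[match(common, scols)])
              else halfSep
  ct <- cosThetaProfile(common, runningMean(ordinate, smoothWindow))
  new("WidthProfile", columns = common, skeletonOrdinate = ordinate,
      halfSep = halfSep, cosTheta = ct, trueWidth = halfSep * ct)
}

runningMean <- function(v, k) {
  if (k <= 1) return(v)
  n <- length(v)
  h <- k %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(1, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Reduce a morphological skeleton to a single-pixel skeleton line
#'
#' The measured object of the geometric model is a single-valued skeleton
#' line y_s(x) (one ordinate per column). The raw morphological skeleton
#' of a discrete band can be locally two pixels thick (the final erosion of
#' an even-height band has an empty opening, leaving a two-row residual),
#' which would double-count length; collapsing each column to its rounded
#' mean skeleton row restores the single-pixel line the model assumes --
#' the same per-column reduction the width profile applies.
#'
#' @param skeleton integer {0,1} skeleton matrix (near-horizontal frame).
#' @return An integer {0,1} matrix with at most one pixel per column.
#' @export
skeletonLine <- function(skeleton) {
  assertMask(skeleton)
  idx <- which(skeleton == 1L)
  if (!length(idx)) return(matrix(0L, nrow(skeleton), ncol(skeleton)))
  sx <- (idx - 1) %/% nrow(skeleton)
  sy <- (idx - 1) %% nrow(skeleton)
  srow <- round(tapply(sy, sx, mean))
  out <- matrix(0L, nrow(skeleton), ncol(skeleton))
  out[cbind(as.numeric(srow) + 1, as.numeric(names(srow)) + 1)] <- 1L
  out
}

#' Vein length from a skeleton and a scale bar
#'
#' Length is measured indirectly through the number of skeleton pixel
#' points: every foreground pixel counts once (no diagonal weighting), and
#' the pixel count times the scale bar gives millimetres. The numeric
#' method converts a precomputed (possibly fractional, e.g. group-mean)
#' pixel count.
#'
#' @param skeleton integer {0,1} skeleton matrix, or a numeric pixel count.
#' @param mmPerPixel scale bar in mm per pixel (> 0).
#' @return A list with \code{pixels} and \code{lengthMm}.
#' @examples
#' measureLength(461.625, 0.2645)$lengthMm    # 122.0998
#' @export
setGeneric("measureLength",
           function(skeleton, mmPerPixel) standardGeneric("measureLength"))

#' @rdname measureLength
#' @export
setMethod("measureLength", "matrix", function(skeleton, mmPerPixel) {
  assertMask(skeleton)
  measureLength(as.numeric(sum(skeleton)), mmPerPixel)
})

#' @rdname measureLength
#' @export
setMethod("measureLength", "numeric", function(skeleton, mmPerPixel) {
  assertScale(mmPerPixel)
  if (skeleton < 0) stop("pixel count must be non-negative")
  list(pixels = skeleton, lengthMm = skeleton * mmPerPixel)
})

assertScale <- function(mmPerPixel) {
  if (!is.numeric(mmPerPixel) || length(mmPerPixel) != 1 ||
      !is.finite(mmPerPixel) || mmPerPixel <= 0)
    stop("mmPerPixel must be a strictly positive scalar")
  invisible(TRUE)
}

#' Vein width from a width profile and a scale bar
#'
#' The mean of the per-column true widths, converted to millimetres. The
#' numeric method converts a precomputed mean pixel width.
#'
#' @param profile a \code{\link{WidthProfile}}, or a numeric mean pixel
#'   width.
#' @param mmPerPixel scale bar in mm per pixel (> 0).
#' @return A list with \code{meanWidthPx} and \code{widthMm}.
#' @examples
#' measureWidth(16.81806469, 0.2645)$widthMm    # 4.448378111
#' @export
setGeneric("measureWidth",
           function(profile, mmPerPixel) standardGeneric("measureWidth"))

#' @rdname measureWidth
#' @export
setMethod("measureWidth", "WidthProfile", function(profile, mmPerPixel) {
  if (length(profile) == 0) stop("empty width profile")
  measureWidth(mean(trueWidth(profile)), mmPerPixel)
})

#' @rdname measureWidth
#' @export
setMethod("measureWidth", "numeric", function(profile, mmPerPixel) {
  assertScale(mmPerPixel)
  list(meanWidthPx = profile, widthMm = profile * mmPerPixel)
})

#' End-to-end vein measurement from a segmentation mask
#'
#' Composition of the full toolchain: hull-scan repair, the F-3MS pipeline
#' down to the binarized vein and its skeleton, principal-axis
#' normalization (the binarized vein is rotated to horizontal and the
#' skeleton recomputed in that frame, so the pixel-count length and the
#' per-column contour model are tilt-invariant), binary contour extraction
#' and the angle-corrected width profile.
#'
#' @param mask integer {0,1} segmentation mask (foreground = vein).
#' @param mmPerPixel scale bar in mm per pixel.
#' @param repair a \code{\link{RepairParams}}.
#' @param cfg a \code{\link{F3msConfig}}.
#' @param mode width angle-ordinate mode, \code{"midline"} (default) or
#'   \code{"half_separation"}.
#' @param fullWidth if TRUE, report twice the half-separation-based width
#'   (the full anatomical thickness); default FALSE, matching the
#'   half-separation convention of the geometric model.
#' @return A \code{\link{VeinMeasurement}}.
#' @export
measureVein <- function(mask, mmPerPixel, repair = RepairParams(),
                        cfg = F3msConfig(),
                        mode = c("midline", "half_separation"),
                        fullWidth = FALSE) {
  mode <- match.arg(mode)
  assertMask(mask); assertScale(mmPerPixel)
  if (sum(mask) == 0) stop("mask has no foreground")
  repaired <- repairMask(mask, repair)
  st <- f3msPipeline(repaired, cfg, keepStages = TRUE)
  if (sum(st$skeleton) == 0) stop("skeletonization produced an empty result")
  ori <- orientPrincipalAxis(st$binary, st$skeleton)
  # nearest-neighbor rotation roughens the band edges; re-running the
  # refinement in the normalized frame keeps the skeleton burr-free there
  st2 <- f3msPipeline(ori$mask, cfg, keepStages = TRUE)
  binary <- st2$binary
  skel <- st2$skeleton
  if (sum(skel) == 0) stop("skeletonization produced an empty result")
  contour <- cannyContour(binary)
  cf <- contourFunctions(contour)
  wp <- trueWidthProfile(cf, skel, mode)
  len <- measureLength(skeletonLine(skel), mmPerPixel)
  widthPx <- mean(trueWidth(wp)) * if (fullWidth) 2 else 1
  wid <- measureWidth(widthPx, mmPerPixel)
  new("VeinMeasurement", skeletonPixels = len$pixels,
      lengthMm = len$lengthMm, meanWidthPx = wid$meanWidthPx,
      widthMm = wid$widthMm, mmPerPixel = mmPerPixel,
      angleDeg = ori$angleDeg, mode = mode, profile = wp)
}
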