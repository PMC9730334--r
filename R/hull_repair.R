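# Convex hull-scan mask repair
# ----------------------------
# Fragmented vein masks are repaired locally: for every pair of mask
# components whose boundaries come within maxGapPx of each other, the
# boundary points of both components around the gap (plus any noise specks
# inside the local window) are wrapped in their minimum convex polygon
# (Graham scan), the polygon is filled, and the fill is unioned with the
# mask. Points are (x, y) in the 0-based screen coordinate system.

#' Signed turn of three points
#'
#' The 2D cross product (b - a) x (c - a). In the screen coordinate system
#' a positive value means the polar-angle sweep keeps c as a hull candidate
#' ("deposit"), a negative value pops the stack, zero means collinear.
#'
#' @param a,b,c length-2 numeric vectors c(x, y).
#' @return A signed scalar.
#' @examples
#' crossTurn(c(0, 0), c(1, 0), c(1, 1))   #  1  (deposit)
#' crossTurn(c(0, 0), c(2, 0), c(1, -1))  # -2  (pop)
#' @export
crossTurn <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

#' Minimum convex polygon by Graham scan
#'
#' Anchor P1 is the point of minimal x (ties broken by minimal y); the
#' remaining points are sorted by polar angle about the anchor (nearer point
#' first on ties) and swept with the \code{\link{crossTurn}} test, popping
#' on non-positive turns so collinear points never survive as vertices. The
#' result is the minimal vertex set: every input point lies inside or on
#' the polygon.
#'
#' @param points n x 2 matrix (or data.frame) of (x, y) coordinates, at
#'   least 2 distinct points.
#' @return An m x 2 matrix of hull vertices in sweep (counterclockwise)
#'   order starting at the anchor. Degenerate (all-collinear) input yields
#'   the 2 extreme endpoints.
#' @examples
#' pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
#' grahamHull(pts)   # the four corners
#' @export
grahamHull <- function(points) {
  pts <- unique(as.matrix(points))
  if (!is.numeric(pts) || ncol(pts) != 2)
    stop("points must be an n x 2 numeric matrix")
  if (nrow(pts) < 2)
    stop("need at least 2 distinct points")
  ord <- order(pts[, 1], pts[, 2])
  anchor <- pts[ord[1], ]
  rest <- pts[ord[-1], , drop = FALSE]
  dx <- rest[, 1] - anchor[1]
  dy <- rest[, 2] - anchor[2]
  ang <- atan2(dy, dx)
  rest <- rest[order(ang, dx * dx + dy * dy), , drop = FALSE]
  stack <- list(anchor, rest[1, ])
  if (nrow(rest) > 1) {
    for (i in 2:nrow(rest)) {
      cand <- rest[i, ]
      while (length(stack) >= 2 &&
             crossTurn(stack[[length(stack) - 1]], stack[[length(stack)]],
                       cand) <= 0) {
        stack[[length(stack)]] <- NULL
      }
      stack[[length(stack) + 1L]] <- cand
    }
  }
  # the closing edge back to the anchor can leave a collinear last vertex
  while (length(stack) > 2 &&
         crossTurn(stack[[length(stack) - 1]], stack[[length(stack)]],
                   anchor) <= 0) {
    stack[[length(stack)]] <- NULL
  }
  hull <- do.call(rbind, stack)
  dimnames(hull) <- list(NULL, c("x", "y"))
  hull
}

#' Rasterize a line segment (Bresenham)
#'
#' @param p,q integer (x, y) endpoints.
#' @return Matrix of (x, y) pixels on the segment, endpoints included.
#' @keywords internal
rasterSegment <- function(p, q) {
  x0 <- round(p[1]); y0 <- round(p[2]); x1 <- round(q[1]); y1 <- round(q[2])
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1 else -1
  sy <- if (y0 < y1) 1 else -1
  n <- max(dx, dy) + 1
  out <- matrix(0, n, 2)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    out[i, ] <- c(x, y)
    if (x == x1 && y == y1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  out
}

#' Fill a convex polygon into a raster
#'
#' Pixels on the rasterized edges between consecutive vertices and pixels
#' strictly inside the polygon are set to 1. A 2-vertex (degenerate) hull
#' fills only the rasterized segment.
#'
#' @param hull m x 2 matrix of convex-polygon vertices (x, y), 0-based, as
#'   produced by \code{\link{grahamHull}}.
#' @param shape c(height, width) of the output raster.
#' @return An integer {0,1} matrix of dimension \code{shape}.
#' @examples
#' sum(fillPolygon(rbind(c(0, 0), c(9, 0), c(9, 4), c(0, 4)), c(5, 10)))  # 50
#' @export
fillPolygon <- function(hull, shape) {
  hull <- as.matrix(hull)
  h <- shape[1]; w <- shape[2]
  if (any(hull[, 1] < 0) || any(hull[, 1] > w - 1) ||
      any(hull[, 2] < 0) || any(hull[, 2] > h - 1))
    stop("hull vertex outside raster")
  out <- matrix(0L, h, w)
  n <- nrow(hull)
  setPix <- function(pts) {
    idx <- cbind(round(pts[, 2]) + 1, round(pts[, 1]) + 1)
    out[idx] <<- 1L
  }
  if (n == 2) {
    setPix(rasterSegment(hull[1, ], hull[2, ]))
    return(out)
  }
  # orient counterclockwise (positive signed area in this convention)
  area2 <- sum(hull[, 1] * hull[c(2:n, 1), 2] - hull[c(2:n, 1), 1] * hull[, 2])
  if (area2 < 0) hull <- hull[n:1, , drop = FALSE]
  # edges
  for (i in seq_len(n)) setPix(rasterSegment(hull[i, ], hull[i %% n + 1, ]))
  # strict interior of the convex polygon by half-plane test over the bbox
  xs <- floor(min(hull[, 1])):ceiling(max(hull[, 1]))
  ys <- floor(min(hull[, 2])):ceiling(max(hull[, 2]))
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  inside <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[i %% n + 1, ]
    inside <- inside &
      ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])) > 0
  }
  if (any(inside)) out[cbind(py[inside] + 1, px[inside] + 1)] <- 1L
  out
}

#' Locate bridgeable gap regions in a fragmented mask
#'
#' Components are labeled (8-connectivity); components smaller than
#' \code{minFragmentPx} are noise. For each pair of substantive components
#' whose boundary-to-boundary Euclidean distance is at most \code{maxGapPx},
#' the bounding window of the two nearest boundary points is expanded by
#' \code{windowMarginPx}, and the region collects the boundary pixels of
#' both components inside that window plus every pixel of noise components
#' inside it.
#'
#' @param mask integer {0,1} matrix.
#' @param params a \code{\link{RepairParams}} object.
#' @return A list of k x 2 point matrices (x, y), one per bridgeable gap;
#'   empty list when nothing needs repair.
#' @export
findRepairRegions <- function(mask, params = RepairParams()) {
  assertMask(mask)
  cc <- connectedComponents(mask, 8)
  if (cc$nComponents < 2) return(list())
  areas <- tabulate(cc$labels[cc$labels > 0], cc$nComponents)
  noise <- which(areas < params@minFragmentPx)
  subst <- which(areas >= params@minFragmentPx)
  if (length(subst) < 2) return(list())
  contour <- cannyContour(mask)
  bidx <- which(contour == 1L)
  blab <- cc$labels[bidx]
  bxy <- cbind(x = (bidx - 1) %/% nrow(mask), y = (bidx - 1) %% nrow(mask))
  bpts <- lapply(seq_len(cc$nComponents),
                 function(l) bxy[blab == l, , drop = FALSE])
  noiseIdx <- which(matrix(cc$labels %in% noise, nrow(mask), ncol(mask)))
  noiseXY <- cbind(x = (noiseIdx - 1) %/% nrow(mask),
                   y = (noiseIdx - 1) %% nrow(mask))
  noiseLab <- cc$labels[noiseIdx]
  regions <- list()
  for (i in seq_along(subst)) {
    for (j in seq_along(subst)) {
      if (j <= i) next
      a <- bpts[[subst[i]]]; b <- bpts[[subst[j]]]
      cp <- cpp_closest_pair(a, b)
      if (sqrt(cp[1]) > params@maxGapPx) next
      pa <- a[cp[2], ]; pb <- b[cp[3], ]
      m <- params@windowMarginPx
      x0 <- min(pa[1], pb[1]) - m; x1 <- max(pa[1], pb[1]) + m
      y0 <- min(pa[2], pb[2]) - m; y1 <- max(pa[2], pb[2]) + m
      inWin <- function(p) p[, 1] >= x0 & p[, 1] <= x1 &
                           p[, 2] >= y0 & p[, 2] <= y1
      pts <- rbind(a[inWin(a), , drop = FALSE], b[inWin(b), , drop = FALSE])
      if (length(noiseIdx)) {
        keepLab <- unique(noiseLab[inWin(noiseXY)])
        pts <- rbind(pts,
                     noiseXY[noiseLab %in% keepLab, , drop = FALSE])
      }
      if (nrow(pts) >= 2) regions[[length(regions) + 1L]] <- pts
    }
  }
  regions
}

#' Repair a fragmented vein mask by the convex hull-scan method
#'
#' Every gap region found by \code{\link{findRepairRegions}} is wrapped in
#' its minimum convex polygon, the polygon is filled and unioned with the
#' input. The output is always a superset of the input, every bridged
#' component pair is 8-connected afterwards, and the number of connected
#' components never increases.
#'
#' @inheritParams findRepairRegions
#' @return The repaired integer {0,1} matrix.
#' @export
repairMask <- function(mask, params = RepairParams()) {
  regions <- findRepairRegions(mask, params)
  out <- storage.mode2int(mask)
  for (pts in regions) {
    pts <- unique(pts)
    if (nrow(pts) < 2) next
    hull <- grahamHull(pts)
    out <- bitwiseOr(out, fillPolygon(hull, dim(mask)))
  }
  out
}
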