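# Synthetic vein phantoms with exact ground truth
# -----------------------------------------------
# A phantom is a capsule: every pixel whose center lies within T/2 of a
# centerline polyline. Because pixel centers sit on the integer lattice and
# the centerline runs through lattice points, a horizontal band of even
# thickness T spans exactly T+1 rows, so the discrete contour separation
# v(x) - u(x) equals T and the half-separation equals the T/2 half-width
# ground truth with no half-pixel correction. Degradation (transverse
# occlusion gaps, interior pinholes, isolated background speckle) is fully
# seeded and recorded in the truth object.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so package randomness never
#' leaks into (or depends on) the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

polylineArcLength <- function(cl) {
  segs <- diff(cl)
  sum(sqrt(rowSums(segs^2)))
}

# Distance from points (n x 2, 0-based x/y) to a polyline, plus the
# arc-length position of the nearest point on the polyline.
distanceToPolyline <- function(pts, cl) {
  nseg <- nrow(cl) - 1
  segLen <- sqrt(rowSums(diff(cl)^2))
  cum <- c(0, cumsum(segLen))
  best <- rep(Inf, nrow(pts))
  arc <- numeric(nrow(pts))
  for (s in seq_len(nseg)) {
    a <- cl[s, ]; b <- cl[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    d <- dx^2 + dy^2
    upd <- d < best
    best[upd] <- d[upd]
    arc[upd] <- cum[s] + t[upd] * segLen[s]
  }
  list(dist = sqrt(best), arc = arc)
}

#' Convenience spec for a straight or gently curved band phantom
#'
#' Builds a \code{\link{PhantomSpec}} whose centerline is a straight
#' segment of the given length tilted by \code{tiltDeg} (optionally with a
#' shallow sine deflection), on a canvas sized to hold the band plus a
#' margin of one thickness on every side.
#'
#' @param lengthPx centerline length in pixels.
#' @param thicknessPx full band thickness T in pixels.
#' @param tiltDeg tilt of the band axis in degrees (0 = horizontal).
#' @param sineAmp,sinePeriods amplitude (pixels) and period count of an
#'   optional sine deflection of the centerline (0 = straight).
#' @param ... further arguments passed to \code{\link{PhantomSpec}}
#'   (nGaps, gapLenPx, nHoles, speckleDensity, seed).
#' @return A \code{\link{PhantomSpec}}.
#' @export
bandPhantomSpec <- function(lengthPx = 400, thicknessPx = 20, tiltDeg = 0,
                            sineAmp = 0, sinePeriods = 1, ...) {
  phi <- tiltDeg * pi / 180
  ts <- if (sineAmp > 0) seq(0, 1, length.out = 65) else c(0, 1)
  ax <- ts * lengthPx
  ay <- sineAmp * sin(2 * pi * sinePeriods * ts)
  x <- ax * cos(phi) - ay * sin(phi)
  y <- ax * sin(phi) + ay * cos(phi)
  margin <- thicknessPx + 2
  x <- x - min(x) + margin
  # the +0.5 keeps the centerline between pixel rows (the generic position):
  # a lattice-aligned centerline is a measure-zero special case whose closed
  # capsule inequality would cover one extra row
  y <- y - min(y) + margin + 0.5
  canvas <- c(ceiling(max(y)) + margin + 1, ceiling(max(x)) + margin + 1)
  PhantomSpec(canvas = canvas, centerline = cbind(x, y),
              thickness = thicknessPx, ...)
}

#' Generate a vein phantom with exact ground truth
#'
#' Rasterizes the capsule of radius thickness/2 around the centerline
#' polyline and renders it as a red-on-black RGB image (the annotation
#' color convention for vein masks). Deterministic: the same spec always
#' produces bit-identical output.
#'
#' @param spec a \code{\link{PhantomSpec}}; the centerline must keep a
#'   margin of at least one thickness from the canvas border.
#' @return A list with \code{image} (h x w x 3 RGB array), \code{mask}
#'   (integer {0,1} matrix) and \code{truth} (a \code{\link{PhantomTruth}}
#'   with the exact centerline arc length and thickness).
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  cl <- spec@centerline
  h <- spec@canvas[1]; w <- spec@canvas[2]
  if (polylineArcLength(cl) <= 0) stop("zero-length centerline")
  if (min(cl[, 1]) < spec@thickness / 2 + 1 ||
      min(cl[, 2]) < spec@thickness / 2 + 1 ||
      max(cl[, 1]) > w - 1 - spec@thickness / 2 - 1 ||
      max(cl[, 2]) > h - 1 - spec@thickness / 2 - 1)
    stop("centerline too close to canvas border")
  pts <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), times = w))
  d <- distanceToPolyline(pts, cl)
  mask <- matrix(as.integer(d$dist <= spec@thickness / 2), h, w)
  truth <- new("PhantomTruth", centerlineLenPx = polylineArcLength(cl),
               thicknessPx = spec@thickness,
               halfWidthPx = spec@thickness / 2,
               gapSpans = matrix(numeric(0), 0, 2), cleanMask = mask)
  list(image = renderMaskRgb(mask), mask = mask, truth = truth)
}

#' Degrade a phantom mask with gaps, pinholes and speckle
#'
#' Removes \code{nGaps} transverse slabs of length \code{gapLenPx} along
#' the band (splitting it into fragments), punches \code{nHoles} interior
#' 1-2 px pinholes, and sprinkles isolated background specks at
#' \code{speckleDensity}; specks keep a distance of at least 3 px from the
#' band and from each other, so a 3x3 opening removes them all. All
#' randomness is drawn under the spec's seed.
#'
#' @param mask the clean phantom mask.
#' @param spec the \code{\link{PhantomSpec}} that produced it.
#' @param truth optional \code{\link{PhantomTruth}} to update with the gap
#'   spans.
#' @return A list with the degraded \code{mask}, the \code{gapSpans}
#'   matrix (arc-length intervals removed) and, when given, the updated
#'   \code{truth}.
#' @export
degradePhantom <- function(mask, spec, truth = NULL) {
  assertMask(mask)
  cl <- spec@centerline
  L <- polylineArcLength(cl)
  if (spec@nGaps > 0 && spec@gapLenPx >= L)
    stop("gap length must be smaller than the band length")
  idx <- which(mask == 1L)
  px <- cbind((idx - 1) %/% nrow(mask), (idx - 1) %% nrow(mask))
  d <- distanceToPolyline(px, cl)
  out <- storage.mode2int(mask)
  gapSpans <- matrix(numeric(0), 0, 2)
  withSeed(spec@seed, {
    if (spec@nGaps > 0) {
      lo <- 0.15 * L; hi <- 0.85 * L
      minSep <- spec@gapLenPx + spec@thickness + 10
      centers <- c()
      tries <- 0
      while (length(centers) < spec@nGaps && tries < 1000) {
        cand <- stats::runif(1, lo, hi)
        if (!length(centers) || min(abs(centers - cand)) >= minSep)
          centers <- c(centers, cand)
        tries <- tries + 1
      }
      for (cc in centers) {
        span <- c(cc - spec@gapLenPx / 2, cc + spec@gapLenPx / 2)
        gapSpans <- rbind(gapSpans, span)
        out[idx[d$arc >= span[1] & d$arc <= span[2]]] <- 0L
      }
    }
    if (spec@nHoles > 0) {
      interior <- d$dist <= spec@thickness / 2 - 2.5
      if (nrow(gapSpans) > 0)
        for (r in seq_len(nrow(gapSpans)))
          interior <- interior & (d$arc < gapSpans[r, 1] - 4 |
                                  d$arc > gapSpans[r, 2] + 4)
      candIdx <- which(interior)
      chosen <- c()
      tries <- 0
      while (length(chosen) < spec@nHoles && tries < 5000 && length(candIdx)) {
        cand <- sample(candIdx, 1)
        ok <- TRUE
        if (length(chosen)) {
          dx <- px[cand, 1] - px[chosen, 1]
          dy <- px[cand, 2] - px[chosen, 2]
          ok <- min(dx^2 + dy^2) >= 36
        }
        if (ok) chosen <- c(chosen, cand)
        tries <- tries + 1
      }
      for (ci in chosen) {
        out[idx[ci]] <- 0L
        if (stats::runif(1) < 0.5) {      # occasionally a 2-px hole
          r <- px[ci, 2] + 1; c2 <- px[ci, 1] + 2
          if (c2 <= ncol(out)) out[r, c2] <- 0L
        }
      }
    }
    if (spec@speckleDensity > 0) {
      far <- dilateMask(storage.mode2int(mask), squareBrush(7))
      bg <- which(far == 0L)
      k <- round(spec@speckleDensity * length(bg))
      if (k > 0) {
        cand <- sample(bg, min(k * 3, length(bg)))
        sx <- (cand - 1) %/% nrow(mask); sy <- (cand - 1) %% nrow(mask)
        keep <- c()
        for (i in seq_along(cand)) {
          if (length(keep) >= k) break
          if (!length(keep) ||
              min((sx[i] - sx[keep])^2 + (sy[i] - sy[keep])^2) >= 16)
            keep <- c(keep, i)
        }
        out[cand[keep]] <- 1L
      }
    }
  })
  res <- list(mask = out, gapSpans = gapSpans)
  if (!is.null(truth)) {
    truth@gapSpans <- gapSpans
    res$truth <- truth
  }
  res
}

rotate90k <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])  # 90 deg CW
  m
}

nnResample <- function(m, hw) {
  h2 <- hw[1]; w2 <- hw[2]
  ri <- pmin(pmax(floor((0:(h2 - 1) + 0.5) * nrow(m) / h2) + 1, 1), nrow(m))
  ci <- pmin(pmax(floor((0:(w2 - 1) + 0.5) * ncol(m) / w2) + 1, 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

applyChannels <- function(img, f) {
  if (length(dim(img)) == 2) return(f(img))
  out <- NULL
  for (ch in seq_len(dim(img)[3])) {
    r <- f(img[, , ch])
    if (is.null(out)) out <- array(0L, c(dim(r), dim(img)[3]))
    out[, , ch] <- r
  }
  out
}

#' Read a PASCAL-VOC segmentation dataset layout
#'
#' Resolves the ids of one split (from ImageSets/Segmentation/) to image
#' and mask paths, verifying both exist.
#'
#' @param dir dataset root containing JPEGImages/, SegmentationClass/ and
#'   ImageSets/Segmentation/.
#' @param split one of "train", "val", "test".
#' @return A data.frame with \code{id}, \code{image} and \code{mask}
#'   absolute paths.
#' @export
readVocDataset <- function(dir, split = c("train", "val", "test")) {
  split <- match.arg(split)
  listFile <- file.path(dir, "ImageSets", "Segmentation",
                        paste0(split, ".txt"))
  if (!file.exists(listFile)) stop("no such split list: ", listFile)
  ids <- readLines(listFile)
  img <- file.path(dir, "JPEGImages", paste0(ids, ".jpg"))
  msk <- file.path(dir, "SegmentationClass", paste0(ids, ".png"))
  missing <- c(img[!file.exists(img)], msk[!file.exists(msk)])
  if (length(missing))
    stop("dataset items missing on disk: ", paste(missing, collapse = ", "))
  data.frame(id = ids, image = img, mask = msk)
}

#' Geometric augmentation of an image/mask pair
#'
#' Applies the identical geometric transform to image and mask; masks are
#' resampled nearest-neighbor so they stay binary. Supported ops:
#' \code{"scale"} (params: \code{factor}), \code{"translate"} (params:
#' \code{dx}, \code{dy}, pixels, zero fill), \code{"mirror"} (horizontal
#' flip), \code{"rotate"} (params: \code{angleDeg}; multiples of 90 are
#' exact lattice permutations).
#'
#' @param image gray matrix or h x w x 3 array.
#' @param mask integer {0,1} matrix of the same height/width.
#' @param op one of "scale", "translate", "mirror", "rotate".
#' @param params named list of transform parameters.
#' @return A list with transformed \code{image} and \code{mask}.
#' @export
augmentPair <- function(image, mask, op, params = list()) {
  assertMask(mask)
  f <- switch(op,
    mirror = function(m) m[, ncol(m):1, drop = FALSE],
    translate = function(m) {
      dx <- params$dx %||% 0; dy <- params$dy %||% 0
      out <- matrix(0L, nrow(m), ncol(m))
      storage.mode(out) <- storage.mode(m)
      srcR <- seq_len(nrow(m)) - dy
      srcC <- seq_len(ncol(m)) - dx
      okR <- srcR >= 1 & srcR <= nrow(m)
      okC <- srcC >= 1 & srcC <= ncol(m)
      out[which(okR), which(okC)] <- m[srcR[okR], srcC[okC], drop = FALSE]
      out
    },
    scale = function(m) {
      fac <- params$factor %||% 1
      nnResample(m, c(max(1, round(nrow(m) * fac)),
                      max(1, round(ncol(m) * fac))))
    },
    rotate = function(m) {
      ang <- params$angleDeg %||% 90
      if (ang %% 90 == 0) rotate90k(m, ang %/% 90)
      else nnRotate(m, ang * pi / 180)
    },
    stop("unknown augmentation op: ", op))
  list(image = applyChannels(image, f), mask = applyChannels(mask, f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nnRotate <- function(m, angleRad) {
  bin <- all(m %in% c(0L, 1L))
  if (bin) return(rotateMask(storage.mode2int(m), angleRad))
  h <- nrow(m); w <- ncol(m)
  ca <- cos(angleRad); sa <- sin(angleRad)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xo <- rep(0:(w - 1), each = h) - cx
  yo <- rep(0:(h - 1), times = w) - cy
  xs <- round(ca * xo + sa * yo + cx)
  ys <- round(-sa * xo + ca * yo + cy)
  ok <- xs >= 0 & xs < w & ys >= 0 & ys < h
  out <- matrix(0, h, w)
  out[cbind(yo + cy + 1, xo + cx + 1)[ok, , drop = FALSE]] <-
    m[cbind(ys + 1, xs + 1)[ok, , drop = FALSE]]
  out
}

#' Write an image/mask collection as a PASCAL-VOC segmentation dataset
#'
#' Lays out JPEGImages/ (JPEG photographs), SegmentationClass/ (PNG label
#' masks) and ImageSets/Segmentation/{train,val,test}.txt. The split is a
#' seeded shuffle partitioned by the largest-remainder rounding of the
#' ratios (default 8:1:1).
#'
#' @param items list of lists, each with \code{image} (h x w x 3 array in
#'   [0, 255]) and \code{mask} (integer {0,1} matrix).
#' @param outDir output directory (created if needed).
#' @param splitRatio train/val/test fractions summing to 1.
#' @param seed shuffle seed.
#' @return The manifest data.frame (id, split, image path, mask path),
#'   invisibly written as \code{manifest.csv} too.
#' @export
writeVocDataset <- function(items, outDir, splitRatio = c(0.8, 0.1, 0.1),
                            seed = 1) {
  if (!length(items)) stop("no items to write")
  if (abs(sum(splitRatio) - 1) > 1e-9) stop("split ratios must sum to 1")
  n <- length(items)
  dirs <- file.path(outDir, c("JPEGImages", "SegmentationClass",
                              file.path("ImageSets", "Segmentation")))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  ids <- sprintf("img_%04d", seq_len(n))
  sizes <- floor(n * splitRatio)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * splitRatio - sizes
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- withSeed(seed, sample(n))
  split <- character(n)
  split[perm] <- rep(c("train", "val", "test"), times = sizes)
  for (i in seq_len(n)) {
    img <- items[[i]]$image
    jp <- file.path(outDir, "JPEGImages", paste0(ids[i], ".jpg"))
    ebi <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
    EBImage::writeImage(ebi, jp, quality = 95)
    writeMask(items[[i]]$mask,
              file.path(outDir, "SegmentationClass", paste0(ids[i], ".png")))
  }
  for (s in c("train", "val", "test"))
    writeLines(ids[split == s],
               file.path(outDir, "ImageSets", "Segmentation",
                         paste0(s, ".txt")))
  manifest <- data.frame(
    id = ids, split = split,
    image = file.path("JPEGImages", paste0(ids, ".jpg")),
    mask = file.path("SegmentationClass", paste0(ids, ".png")))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
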