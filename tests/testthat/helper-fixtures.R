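# Fixtures are built in code: small hand masks plus seeded phantoms.

# a solid rectangle of `rows` x `cols` foreground centered in a canvas
solidBlock <- function(canvas, rows, cols, at = NULL) {
  m <- matrix(0L, canvas[1], canvas[2])
  if (is.null(at)) at <- c((canvas[1] - rows) %/% 2, (canvas[2] - cols) %/% 2)
  m[at[1] + seq_len(rows), at[2] + seq_len(cols)] <- 1L
  m
}

randomMask <- function(h, w, p = 0.4) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# two collinear horizontal bars of `rows` x `cols` separated by `gap` columns
twoBars <- function(rows = 5, cols = 20, gap = 6, margin = 8) {
  h <- rows + 2 * margin
  w <- 2 * cols + gap + 2 * margin
  m <- matrix(0L, h, w)
  m[margin + seq_len(rows), margin + seq_len(cols)] <- 1L
  m[margin + seq_len(rows), margin + cols + gap + seq_len(cols)] <- 1L
  m
}

degradedPhantom <- function(seed, lengthPx = NULL, thicknessPx = NULL,
                            tiltDeg = NULL, nGaps = 2, nHoles = 5,
                            speckleDensity = 5e-4, gapLenPx = 8) {
  withr::with_seed(seed, {
    spec <- bandPhantomSpec(
      lengthPx = lengthPx %||% round(stats::runif(1, 300, 500)),
      thicknessPx = thicknessPx %||% round(stats::runif(1, 12, 24)),
      tiltDeg = tiltDeg %||% stats::runif(1, 0, 30),
      nGaps = nGaps, gapLenPx = gapLenPx, nHoles = nHoles,
      speckleDensity = speckleDensity, seed = seed)
    ph <- generatePhantom(spec)
    deg <- degradePhantom(ph$mask, spec, ph$truth)
    list(spec = spec, clean = ph$mask, mask = deg$mask, truth = deg$truth,
         image = ph$image)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^3) convex-hull oracle: an ordered pair (a, b) is a hull edge iff all
# other points lie strictly on its positive side or on the segment between
# a and b; hull vertices are the endpoints of such edges.
bruteHullVertices <- function(pts) {
  pts <- unname(unique(as.matrix(pts)))
  n <- nrow(pts)
  if (n == 2) return(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  isV <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- pts[i, ]; b <- pts[j, ]
      cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
            (b[2] - a[2]) * (pts[, 1] - a[1])
      if (any(cr < 0)) next
      col <- which(abs(cr) == 0)
      # collinear points must lie within the segment [a, b]
      t <- ((pts[col, 1] - a[1]) * (b[1] - a[1]) +
            (pts[col, 2] - a[2]) * (b[2] - a[2])) / sum((b - a)^2)
      if (all(t >= 0 & t <= 1)) isV[c(i, j)] <- TRUE
    }
  }
  v <- pts[isV, , drop = FALSE]
  v[order(v[, 1], v[, 2]), , drop = FALSE]
}

sortedVertices <- function(hull) {
  hull <- unname(as.matrix(hull))
  hull[order(hull[, 1], hull[, 2]), , drop = FALSE]
}

# exhaustive Otsu oracle evaluating the class definitions directly
otsuOracle <- function(img) {
  lv <- 0:255
  counts <- tabulate(as.integer(img) + 1L, 256L)
  p <- counts / sum(counts)
  best <- -Inf; bestK <- 0L
  for (k in 0:254) {
    w0 <- sum(p[lv <= k]); w1 <- sum(p[lv > k])
    if (w0 == 0 || w1 == 0) next
    u0 <- sum(lv[lv <= k] * p[lv <= k]) / w0
    u1 <- sum(lv[lv > k] * p[lv > k]) / w1
    s <- w0 * w1 * (u0 - u1)^2
    if (s > best + 1e-12) { best <- s; bestK <- k }
  }
  bestK
}

crossElem <- matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L), 3, 3)

dilateK <- function(mask, elem, k) {
  for (i in seq_len(k)) mask <- binaryDilate(mask, elem)
  mask
}

# interior background cavities: background components not touching border
interiorCavities <- function(mask) {
  lab <- connectedComponents(bitwiseNot(mask), 4)$labels
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  setdiff(unique(lab[lab > 0]), border)
}
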