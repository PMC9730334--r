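test_that("cannyContour equals the binary boundary oracle", {
  sq <- matrix(0L, 7, 7); sq[2:6, 2:6] <- 1L
  expect_identical(sum(cannyContour(sq)), 16L)
  expect_identical(sum(cannyContour(matrix(0L, 5, 5))), 0L)
  boundaryOracle <- function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] == 0) next
      nb <- c(if (i > 1) m[i - 1, j] else 0L,
              if (i < nrow(m)) m[i + 1, j] else 0L,
              if (j > 1) m[i, j - 1] else 0L,
              if (j < ncol(m)) m[i, j + 1] else 0L)
      if (any(nb == 0) || i == 1 || i == nrow(m) || j == 1 || j == ncol(m))
        out[i, j] <- 1L
    }
    out
  }
  withr::with_seed(23, {
    for (i in 1:5) {
      m <- openMask(randomMask(15, 15, 0.6), 3)   # blob-like
      expect_identical(cannyContour(m), boundaryOracle(m))
    }
  })
})

test_that("orientPrincipalAxis recovers tilt and handles vertical bands", {
  horiz <- generatePhantom(bandPhantomSpec(150, 11, 0, seed = 1))
  skel <- f3msPipeline(horiz$mask)
  ori <- orientPrincipalAxis(horiz$mask, skel)
  expect_lt(abs(ori$angleDeg), 1)
  tilted <- generatePhantom(bandPhantomSpec(200, 13, 30, seed = 2))
  skel30 <- f3msPipeline(tilted$mask)
  ori30 <- orientPrincipalAxis(tilted$mask, skel30)
  expect_lt(abs(ori30$angleDeg - 30), 1.5)
  after <- veinmorph:::principalAngle(ori30$skeleton) * 180 / pi
  expect_lt(abs(after), 1)
  # vertical band rotates to horizontal
  vert <- augmentPair(tilted$mask * 0L, horiz$mask, "rotate",
                      list(angleDeg = 90))$mask
  skelV <- f3msPipeline(vert)
  oriV <- orientPrincipalAxis(vert, skelV)
  expect_lt(abs(veinmorph:::principalAngle(oriV$skeleton)) * 180 / pi, 1)
  expect_error(orientPrincipalAxis(horiz$mask, horiz$mask * 0L), "empty")
})

test_that("contourFunctions extracts single-valued upper/lower contours", {
  band <- matrix(0L, 30, 12); band[11:21, ] <- 1L
  cf <- contourFunctions(cannyContour(band))
  expect_true(all(cf$upper == 10))
  expect_true(all(cf$lower == 20))
  # single-pixel columns are omitted
  c1 <- matrix(0L, 10, 5); c1[4, 2] <- 1L; c1[c(3, 7), 4] <- 1L
  cf1 <- contourFunctions(c1)
  expect_identical(cf1$x, 3)
  expect_error(contourFunctions(matrix(c(0L, 1L, 0L, 0L), 2, 2)), "2 contour")
  # wedge: separation grows with the construction slope
  wedge <- matrix(0L, 40, 60)
  for (x in 0:59) wedge[(20 - x %/% 6):(20 + x %/% 6), x + 1] <- 1L
  cfw <- contourFunctions(cannyContour(wedge))
  sep <- cfw$lower - cfw$upper
  fit <- stats::coef(stats::lm(sep ~ cfw$x))[2]
  expect_equal(as.numeric(fit), 2 / 6, tolerance = 0.05)
})

test_that("cosThetaProfile matches hand-evaluated central differences", {
  expect_equal(cosThetaProfile(0:4, rep(2, 5)), rep(1, 5))
  ct45 <- cosThetaProfile(0:4, 0:4)
  expect_equal(ct45[3], 2 / sqrt(8))                 # 0.7071
  expect_equal(ct45[1], ct45[2])                     # endpoint copies interior
  expect_error(cosThetaProfile(0:1, 0:1), "3 points")
  withr::with_seed(2, {
    o <- cumsum(stats::rnorm(30))
    ct <- cosThetaProfile(seq_along(o), o)
    expect_true(all(ct > 0 & ct <= 1))
  })
})

test_that("trueWidthProfile recovers half-width with and without tilt", {
  # horizontal band of thickness T: exactly T/2 at every point
  ph <- generatePhantom(bandPhantomSpec(200, 16, 0, seed = 4))
  skel <- f3msPipeline(ph$mask)
  cf <- contourFunctions(cannyContour(ph$mask))
  wp <- trueWidthProfile(cf, skel, "midline")
  # exactly T/2 at every point of the band interior (the rounded end caps
  # taper, so trim one thickness at each extremity)
  interior <- wp@columns > min(cf$x) + 16 & wp@columns < max(cf$x) - 16
  expect_true(all(abs(trueWidth(wp)[interior] - 8) < 1e-9))
  expect_true(all(trueWidth(wp) <= wp@halfSep + 1e-9))
  # tilted band, no re-orientation: midline mode corrects by cos(tilt)
  ph20 <- generatePhantom(bandPhantomSpec(300, 16, 20, seed = 4))
  skel20 <- f3msPipeline(ph20$mask)
  cf20 <- contourFunctions(cannyContour(ph20$mask))
  wpM <- trueWidthProfile(cf20, skel20, "midline")
  expect_lt(abs(mean(trueWidth(wpM)) - 8) / 8, 0.03)
  # literal half-separation ordinate: constant -> no correction, width
  # overestimated by 1/cos(tilt)
  wpH <- trueWidthProfile(cf20, skel20, "half_separation")
  expect_lt(abs(mean(trueWidth(wpH)) - 8 / cos(20 * pi / 180)) / 8, 0.03)
})

test_that("measureLength and measureWidth convert printed group means", {
  # length rows: average pixels at scale 0.2645 mm/px
  expect_equal(round(measureLength(461.62500, 0.2645)$lengthMm, 4), 122.0998)
  expect_equal(round(measureLength(551.59375, 0.2645)$lengthMm, 4), 145.8965)
  expect_identical(measureLength(matrix(0L, 4, 4), 0.5)$lengthMm, 0)
  # width rows
  expect_equal(measureWidth(16.81806469, 0.2645)$widthMm, 4.448378111,
               tolerance = 1e-9)
  expect_equal(measureWidth(15.86600711, 0.2645)$widthMm, 4.196558881,
               tolerance = 1e-9)
  # exact linearity in the scale bar
  withr::with_seed(12, {
    skel <- randomMask(10, 20, 0.2)
    for (s in c(0.1, 0.2645, 2)) {
      expect_identical(measureLength(skel, s)$lengthMm, sum(skel) * s)
    }
  })
  expect_error(measureLength(10, -1), "positive")
})

test_that("measureVein recovers phantom truth end to end", {
  scale <- 0.25
  # clean horizontal phantom: L = 400, T = 20
  spec <- bandPhantomSpec(400, 20, 0, nGaps = 0, nHoles = 0,
                          speckleDensity = 0, seed = 10)
  ph <- generatePhantom(spec)
  m <- measureVein(ph$mask, scale)
  expect_lt(abs(lengthMm(m) - 100) / 100, 0.05)
  expect_lt(abs(widthMm(m) - 2.5) / 2.5, 0.05)
  expect_identical(lengthMm(m), skeletonPixels(m) * scale)
  # same phantom with gaps: same tolerances after repair
  d <- degradedPhantom(10, lengthPx = 400, thicknessPx = 20, tiltDeg = 0,
                       nGaps = 2, nHoles = 0, speckleDensity = 0)
  m2 <- measureVein(d$mask, scale)
  expect_lt(abs(lengthMm(m2) - 100) / 100, 0.05)
  expect_lt(abs(widthMm(m2) - 2.5) / 2.5, 0.05)
  # curved phantom: within 7% of the polyline arc length
  spec3 <- bandPhantomSpec(350, 16, 5, sineAmp = 12, sinePeriods = 2,
                           nGaps = 0, nHoles = 0, speckleDensity = 0,
                           seed = 11)
  ph3 <- generatePhantom(spec3)
  m3 <- measureVein(ph3$mask, scale)
  truthMm <- ph3$truth@centerlineLenPx * scale
  expect_lt(abs(lengthMm(m3) - truthMm) / truthMm, 0.07)
  expect_error(measureVein(matrix(0L, 5, 5), 0.25), "foreground")
})

test_that("measuring a 90-degree-rotated phantom changes length little", {
  ph <- generatePhantom(bandPhantomSpec(250, 15, 10, nGaps = 0, nHoles = 0,
                                        speckleDensity = 0, seed = 13))
  m0 <- measureVein(ph$mask, 1)
  rot <- augmentPair(ph$mask, ph$mask, "rotate", list(angleDeg = 90))$mask
  m90 <- measureVein(rot, 1)
  expect_lt(abs(lengthMm(m90) - lengthMm(m0)) / lengthMm(m0), 0.02)
})

test_that("width recovery holds across tilt angles with orientation on", {
  for (tilt in c(0, 10, 20, 30)) {
    ph <- generatePhantom(bandPhantomSpec(300, 20, tilt, nGaps = 0,
                                          nHoles = 0, speckleDensity = 0,
                                          seed = 20 + tilt))
    m <- measureVein(ph$mask, 1)
    expect_lt(abs(m@meanWidthPx - 10) / 10, 0.05)
  }
})
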