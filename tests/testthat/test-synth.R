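test_that("generatePhantom rasterizes a capsule with exact truth", {
  spec <- bandPhantomSpec(400, 20, 0, seed = 1)
  ph <- generatePhantom(spec)
  # capsule area: L*T + pi*(T/2)^2, within 2%
  want <- 400 * 20 + pi * 100
  expect_lt(abs(sum(ph$mask) - want) / want, 0.02)
  expect_equal(ph$truth@centerlineLenPx, 400)
  expect_equal(ph$truth@halfWidthPx, 10)
  # truth arc length re-derivable from the stored centerline
  segs <- diff(spec@centerline)
  expect_equal(sum(sqrt(rowSums(segs^2))), ph$truth@centerlineLenPx,
               tolerance = 1e-9)
  # determinism: identical spec -> identical bytes
  expect_identical(generatePhantom(spec)$mask, ph$mask)
  # RGB render is red on black
  expect_identical(ph$image[, , 1], ph$mask * 255L)
  expect_identical(sum(ph$image[, , 2]), 0L)
  # degenerate and out-of-bounds centerlines
  expect_error(generatePhantom(
    PhantomSpec(c(50, 50), rbind(c(25, 25), c(25, 25)), thickness = 8)),
    "zero-length")
  expect_error(generatePhantom(
    PhantomSpec(c(30, 80), rbind(c(2, 15), c(70, 15)), thickness = 10)),
    "border")
})

test_that("degradePhantom splits, punches and speckles as specified", {
  spec <- bandPhantomSpec(300, 16, 8, nGaps = 2, nHoles = 0,
                          speckleDensity = 0, seed = 5)
  ph <- generatePhantom(spec)
  deg <- degradePhantom(ph$mask, spec, ph$truth)
  expect_identical(connectedComponents(deg$mask)$nComponents, 3L)
  expect_identical(nrow(deg$truth@gapSpans), 2L)
  expect_true(all(deg$mask <= ph$mask))                 # anti-extensive
  # holes only: component count unchanged, interior cavities = nHoles
  specH <- bandPhantomSpec(300, 16, 8, nGaps = 0, nHoles = 5,
                           speckleDensity = 0, seed = 6)
  phH <- generatePhantom(specH)
  degH <- degradePhantom(phH$mask, specH)
  expect_identical(connectedComponents(degH$mask)$nComponents, 1L)
  expect_length(interiorCavities(degH$mask), 5)
  # no degradation configured: identity
  spec0 <- bandPhantomSpec(200, 12, 0, nGaps = 0, nHoles = 0,
                           speckleDensity = 0, seed = 7)
  ph0 <- generatePhantom(spec0)
  expect_identical(degradePhantom(ph0$mask, spec0)$mask, ph0$mask)
  # speckle is extensive only off the band, and a 3x3 opening removes it
  specS <- bandPhantomSpec(300, 16, 0, nGaps = 0, nHoles = 0,
                           speckleDensity = 2e-3, seed = 8)
  phS <- generatePhantom(specS)
  degS <- degradePhantom(phS$mask, specS)
  expect_true(all(degS$mask >= phS$mask))
  expect_gt(sum(degS$mask), sum(phS$mask))
  expect_identical(openMask(degS$mask, 3), openMask(phS$mask, 3))
  # determinism of the full degradation
  expect_identical(degradePhantom(phS$mask, specS)$mask, degS$mask)
})

test_that("augmentPair transforms image and mask consistently", {
  d <- degradedPhantom(9, lengthPx = 120, thicknessPx = 11, tiltDeg = 5)
  img <- renderFix <- d$image; mask <- d$mask
  # mirror twice = identity
  m1 <- augmentPair(img, mask, "mirror")
  m2 <- augmentPair(m1$image, m1$mask, "mirror")
  expect_identical(m2$mask, mask)
  expect_identical(m2$image, img)
  # rotate 90: lossless permutation of pixels
  r <- augmentPair(img, mask, "rotate", list(angleDeg = 90))
  expect_identical(sum(r$mask), sum(mask))
  expect_identical(dim(r$mask), rev(dim(mask)))
  # translate shifts the centroid by exactly (dx, dy) while content stays
  # clear of the borders
  clean <- generatePhantom(bandPhantomSpec(80, 9, 0, seed = 9))
  tr <- augmentPair(clean$image, clean$mask, "translate",
                    list(dx = 5, dy = 3))
  cen <- function(m) {
    idx <- which(m == 1L)
    c(mean((idx - 1) %/% nrow(m)), mean((idx - 1) %% nrow(m)))
  }
  expect_equal(cen(tr$mask), cen(clean$mask) + c(5, 3))
  # scale keeps the mask binary
  sc <- augmentPair(img, mask, "scale", list(factor = 0.5))
  expect_true(all(sc$mask %in% c(0L, 1L)))
  expect_identical(dim(sc$mask),
                   as.integer(round(dim(mask) * 0.5)))
  expect_error(augmentPair(img, mask, "shear"), "unknown")
})

test_that("writeVocDataset lays out the tree with seeded 8:1:1 splits", {
  withr::with_seed(2, {
    items <- lapply(1:10, function(i) {
      d <- degradedPhantom(30 + i, lengthPx = 80, thicknessPx = 9,
                          tiltDeg = 0, nGaps = 0, nHoles = 0)
      list(image = d$image, mask = d$mask)
    })
  })
  out <- withr::local_tempdir()
  man <- writeVocDataset(items, out, seed = 99)
  expect_identical(as.vector(table(man$split)[c("train", "val", "test")]),
                   c(8L, 1L, 1L))
  expect_length(list.files(file.path(out, "JPEGImages")), 10)
  expect_length(list.files(file.path(out, "SegmentationClass")), 10)
  tr <- readLines(file.path(out, "ImageSets", "Segmentation", "train.txt"))
  expect_length(tr, 8)
  # masks survive the round trip; images are real JPEGs
  m1 <- readMask(file.path(out, "SegmentationClass", "img_0001.png"))
  expect_identical(m1, items[[1]]$mask)
  jp <- EBImage::readImage(file.path(out, "JPEGImages", "img_0001.jpg"))
  expect_identical(dim(jp)[1:2], rev(dim(items[[1]]$mask)))
  # determinism of the split
  out2 <- withr::local_tempdir()
  man2 <- writeVocDataset(items, out2, seed = 99)
  expect_identical(man$split, man2$split)
  # reader resolves split ids to existing files
  tr2 <- readVocDataset(out, "train")
  expect_identical(tr2$id, tr)
  expect_true(all(file.exists(tr2$image)))
  expect_true(all(file.exists(tr2$mask)))
  expect_error(readVocDataset(out, "bogus"), "arg")
  # largest-remainder sizes at other n
  expect_identical(as.vector(table(writeVocDataset(items[1:7],
    withr::local_tempdir(), seed = 1)$split)[c("train", "val", "test")]),
    c(5L, 1L, 1L))
})

test_that("trainSmoke decreases the loss across the two-phase schedule", {
  hist <- trainSmoke(nImages = 8, cfg = TrainConfig(epochs = 4,
                     freezeEpochs = 2, lr0 = 0.05), seed = 3)
  expect_identical(nrow(hist), 4L)
  expect_identical(hist$phase, c("frozen", "frozen", "unfrozen", "unfrozen"))
  expect_lt(hist$loss[4], hist$loss[1])
})
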