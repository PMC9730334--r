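test_that("relu6 clamps to [0, 6]", {
  expect_equal(relu6(c(-1, 3, 7)), c(0, 3, 6))
  expect_equal(relu6(matrix(c(-2, 0.5, 6, 100), 2, 2)),
               matrix(c(0, 0.5, 6, 6), 2, 2))
})

test_that("convCosts matches hand arithmetic and the closed-form ratio", {
  cc <- convCosts(3, 8, 16, 32)
  expect_identical(cc$stdCost, 294912)
  expect_identical(cc$dscCost, 41984)
  expect_equal(cc$ratio, 1 / 32 + 1 / 9)
  expect_equal(convCosts(1, 4, 7, 1)$ratio, 2)
  # 3x3 kernel, many output channels: about one-ninth
  expect_equal(convCosts(3, 16, 32, 100000)$ratio, 1 / 9, tolerance = 1e-3)
  expect_error(convCosts(0, 8, 16, 32), "positive")
  withr::with_seed(4, {
    for (i in 1:100) {
      DK <- sample(1:7, 1); DF <- sample(1:64, 1)
      M <- sample(1:512, 1); N <- sample(1:512, 1)
      expect_equal(convCosts(DK, DF, M, N)$ratio, 1 / N + 1 / DK^2,
                   tolerance = 1e-14)
    }
  })
})

test_that("buildModel wires 17 inverted residuals with the right shapes", {
  m <- buildModel(ModelConfig())
  expect_identical(nrow(m$encoder), 17L)
  expect_identical(deepFeatureShape(m), c(32L, 32L, 320L))
  expect_identical(skipFeatureShape(m), c(128L, 128L, 24L))
  expect_identical(modelOutputShape(m), c(512L, 512L, 2L))
  expect_identical(m$aspp$rates, c(6L, 12L, 18L))
  # output stride 8: deeper dilation, wider ASPP rates, same output side
  m8 <- buildModel(ModelConfig(downsampleFactor = 8))
  expect_identical(deepFeatureShape(m8)[1], 64L)
  expect_identical(m8$aspp$rates, c(12L, 24L, 36L))
  expect_identical(modelOutputShape(m8), c(512L, 512L, 2L))
  # small input: 64/16 = 4
  m64 <- buildModel(ModelConfig(inputSide = 64))
  expect_identical(deepFeatureShape(m64)[1:2], c(4L, 4L))
  expect_identical(modelOutputShape(m64, 128), c(128L, 128L, 2L))
  expect_error(ModelConfig(downsampleFactor = 12), "8 or 16")
  expect_error(ModelConfig(inputSide = 100), "divisible")
})

test_that("confusion matrix counts and accumulates correctly", {
  truth <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0, 1, 0, 0, 1, 1, 1, 0, 0), 4, 4)
  pred <-  matrix(c(0, 1, 1, 1, 0, 1, 0, 0, 1, 1, 0, 1, 1, 0, 0, 0), 4, 4)
  cm <- confusionAccumulate(truth, pred)
  # manual tally over the 16 cells
  expect_identical(cm@counts[1, 1], sum(truth == 0 & pred == 0))
  expect_identical(cm@counts[2, 1], sum(truth == 1 & pred == 0))
  expect_identical(cm@counts[1, 2], sum(truth == 0 & pred == 1))
  expect_identical(cm@counts[2, 2], sum(truth == 1 & pred == 1))
  expect_identical(sum(cm@counts), 16L)
  # accumulation adds
  cm2 <- confusionAccumulate(truth, pred, cm = cm)
  expect_identical(cm2@counts, cm@counts * 2L)
  # perfect / inverted predictions
  perf <- confusionAccumulate(truth, truth)
  expect_identical(sum(perf@counts - diag(diag(perf@counts))), 0L)
  inv <- confusionAccumulate(truth, 1 - truth)
  expect_identical(sum(diag(inv@counts)), 0L)
  expect_error(confusionAccumulate(truth, pred[1:2, ]), "shape")
  expect_error(confusionAccumulate(truth, pred + 5), "labels")
})

test_that("mIoU and mPA match hand evaluation and are relabel-invariant", {
  mk <- function(counts) new("ConfusionMatrix", counts = counts)
  cm <- mk(matrix(c(6, 2, 2, 6), 2, 2, byrow = TRUE))
  expect_equal(mIoU(cm), 0.6)          # mean(6/10, 6/10)
  expect_equal(mPA(cm), 0.75)          # mean(12/16, 12/16)
  perfect <- mk(diag(c(30, 12)))
  expect_equal(mIoU(perfect), 1)
  expect_equal(mPA(perfect), 1)
  # a class with disjoint truth/prediction contributes 0
  dis <- mk(matrix(c(0, 5, 5, 0), 2, 2))
  expect_equal(mIoU(dis), 0)
  # empty classes are skipped from the mean
  sk <- mk(diag(c(10, 0, 4)))
  expect_equal(mIoU(sk), 1)
  # simultaneous relabeling leaves both metrics unchanged
  withr::with_seed(40, {
    truth <- matrix(sample(0:2, 64, TRUE), 8, 8)
    pred <- matrix(sample(0:2, 64, TRUE), 8, 8)
    a <- confusionAccumulate(truth, pred, 3)
    relab <- c(2L, 0L, 1L)
    b <- confusionAccumulate(matrix(relab[truth + 1], 8, 8),
                             matrix(relab[pred + 1], 8, 8), 3)
    expect_equal(mIoU(a), mIoU(b))
    expect_equal(mPA(a), mPA(b))
  })
})

test_that("adamStep follows the bias-corrected recurrence exactly", {
  cfg <- TrainConfig()
  st <- adamInit(1)
  # zero gradient: parameters unchanged
  expect_equal(adamStep(st, 0, 1.0, cfg)$params, 1.0)
  # hand-computed first step: theta = 1, g = 0.5
  up <- adamStep(st, 0.5, 1.0, cfg)
  expect_equal(up$state@m, 0.05)
  expect_equal(up$state@v, 0.0025)
  expect_equal(up$params, 1 - 0.001 * 0.5 / (0.5 + cfg@epsilon),
               tolerance = 1e-12)
  # first step magnitude ~ lr for constant nonzero gradients
  for (g in c(1e-4, 1, 250)) {
    d <- 1 - adamStep(adamInit(1), g, 1, cfg)$params
    expect_equal(d, cfg@lr0, tolerance = 1e-3)
  }
  # 50 random steps against an independent recurrence
  withr::with_seed(66, {
    n <- 4
    theta <- rnorm(n); st <- adamInit(n)
    m <- v <- numeric(n); ref <- theta
    for (t in 1:50) {
      g <- rnorm(n)
      up <- adamStep(st, g, theta, cfg)
      st <- up$state; theta <- up$params
      m <- cfg@beta1 * m + (1 - cfg@beta1) * g
      v <- cfg@beta2 * v + (1 - cfg@beta2) * g^2
      ref <- ref - cfg@lr0 * (m / (1 - cfg@beta1^t)) /
        (sqrt(v / (1 - cfg@beta2^t)) + cfg@epsilon)
    }
    expect_equal(theta, ref, tolerance = 1e-12)
  })
  expect_error(adamStep(adamInit(2), 1, 1, TrainConfig()), "length")
})

test_that("lrAtEpoch implements cos annealing and step decay", {
  cfg <- TrainConfig(epochs = 100, lr0 = 0.001)
  expect_equal(lrAtEpoch(cfg, 1), 0.001)
  expect_lt(lrAtEpoch(cfg, 100), lrAtEpoch(cfg, 50))
  stepCfg <- TrainConfig(scheduler = "step", gamma = 0.94)
  expect_equal(lrAtEpoch(stepCfg, 3), 0.001 * 0.94^2)
})

test_that("evalSegmentationDirs scores mask directories", {
  predDir <- withr::local_tempdir(); gtDir <- withr::local_tempdir()
  withr::with_seed(3, {
    for (i in 1:3) {
      gt <- randomMask(12, 12)
      pred <- gt
      pred[1:2, ] <- 1L - pred[1:2, ]     # corrupt two rows
      writeMask(gt, file.path(gtDir, sprintf("m%d.png", i)))
      writeMask(pred, file.path(predDir, sprintf("m%d.png", i)))
    }
  })
  res <- evalSegmentationDirs(predDir, gtDir)
  expect_lt(res$miou, 1)
  expect_gt(res$miou, 0.4)
  perfect <- evalSegmentationDirs(gtDir, gtDir)
  expect_equal(perfect$miou, 1)
  expect_equal(perfect$mpa, 1)
})
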