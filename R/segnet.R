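# MobileNetV2-DeepLabV3+ wiring contract and evaluation metrics
# -------------------------------------------------------------
# The network is described at shape level: a parameterized wiring of the
# inverted-residual encoder (17 blocks, truncated at the 320-channel
# stage), the ASPP head and the skip-concatenating decoder, with feature
# map sides and channel counts derivable for any valid input. The
# activation, the depthwise-separable cost model, the Adam recurrence and
# the confusion-matrix metrics are exact, unit-testable functions.

#' ReLU6 activation
#'
#' Elementwise min(max(0, x), 6): the ReLU clamped to the (0, 6) range used
#' by mobile-friendly networks so low-precision arithmetic keeps resolution.
#'
#' @param x numeric scalar or array.
#' @return Same shape as \code{x}.
#' @examples
#' relu6(c(-1, 3, 7))   # 0 3 6
#' @export
relu6 <- function(x) pmin(pmax(x, 0), 6)

#' Cost of standard vs depthwise-separable convolution
#'
#' Standard cost DK^2 M DF^2 N; depthwise-separable cost
#' DK^2 M DF^2 + M N DF^2 (per-channel spatial convolution plus 1x1
#' pointwise mixing); their ratio simplifies to 1/N + 1/DK^2 exactly, about
#' one-ninth for a 3x3 kernel and many output channels.
#'
#' @param DK kernel side; @param DF feature-map side;
#' @param M input channels; @param N output channels. All positive integers.
#' @return A list with \code{stdCost}, \code{dscCost} and \code{ratio}.
#' @examples
#' convCosts(3, 8, 16, 32)$ratio == 1/32 + 1/9
#' @export
convCosts <- function(DK, DF, M, N) {
  v <- c(DK, DF, M, N)
  if (any(v != round(v)) || any(v <= 0))
    stop("DK, DF, M and N must be positive integers")
  stdCost <- DK^2 * M * DF^2 * N
  dscCost <- DK^2 * M * DF^2 + M * N * DF^2
  list(stdCost = stdCost, dscCost = dscCost, ratio = dscCost / stdCost)
}

# MobileNetV2 inverted-residual stage table: expansion t, output channels
# c, repeats n, first-block stride s. 1+2+3+4+3+3+1 = 17 blocks, truncated
# at the 320-channel stage (no final 1280-channel conv: the encoder feeds
# ASPP directly).
mobilenetV2Stages <- function() {
  data.frame(t = c(1, 6, 6, 6, 6, 6, 6),
             c = c(16, 24, 32, 64, 96, 160, 320),
             n = c(1, 2, 3, 4, 3, 3, 1),
             s = c(1, 2, 2, 2, 1, 2, 1))
}

#' Build the MobileNetV2-DeepLabV3+ wiring description
#'
#' Produces a shape-level description of the network: the stem plus 17
#' inverted-residual encoder blocks (strides converted to dilation once the
#' configured output stride is reached), the five-branch ASPP head
#' (1x1, three dilated 3x3 at rates (6, 12, 18) for output stride 16 or
#' (12, 24, 36) for 8, and global pooling, fused by 1x1 to 256 channels),
#' and the decoder that projects the stride-4 24-channel shallow feature,
#' concatenates it with the upsampled ASPP output, refines with two 3x3
#' stages and upsamples to full resolution.
#'
#' @param cfg a \code{\link{ModelConfig}}.
#' @return A list with \code{config}, \code{encoder} (one row per block:
#'   stage, expansion, outChannels, stride, dilation, outSide),
#'   \code{aspp} and \code{decoder} descriptions.
#' @examples
#' m <- buildModel(ModelConfig())
#' deepFeatureShape(m)   # 32 32 320
#' skipFeatureShape(m)   # 128 128 24
#' @export
buildModel <- function(cfg = ModelConfig()) {
  validObject(cfg)
  side <- cfg@inputSide
  os <- cfg@downsampleFactor
  stages <- mobilenetV2Stages()
  stride <- 2L                       # stem: 3x3 conv, stride 2, 32 channels
  dilation <- 1L
  sideNow <- side %/% 2L
  enc <- list()
  for (st in seq_len(nrow(stages))) {
    for (b in seq_len(stages$n[st])) {
      s <- if (b == 1L) stages$s[st] else 1L
      if (s > 1L && stride * s > os) {      # cap output stride, dilate instead
        dilation <- dilation * s
        s <- 1L
      }
      stride <- stride * s
      sideNow <- sideNow %/% s
      enc[[length(enc) + 1L]] <- data.frame(
        stage = st, block = b, expansion = stages$t[st],
        outChannels = stages$c[st], stride = s, dilation = dilation,
        outSide = sideNow, cumStride = stride)
    }
  }
  encoder <- do.call(rbind, enc)
  rates <- if (os == 16L) c(6L, 12L, 18L) else c(12L, 24L, 36L)
  aspp <- list(inputSide = side %/% os, inputChannels = 320L,
               branches = c("1x1", paste0("3x3 dilated r", rates), "pool"),
               rates = rates, channels = cfg@asppChannels)
  skipRow <- encoder[encoder$outChannels == 24L, ]
  skipSide <- skipRow$outSide[nrow(skipRow)]
  decoder <- list(
    skipSide = skipSide, skipChannels = 24L,
    skipProjChannels = cfg@decoderSkipChannels,
    upsample1 = os %/% 4L,
    concatChannels = cfg@asppChannels + cfg@decoderSkipChannels,
    refine = c("3x3 conv 256", "3x3 conv 256"),
    classifierChannels = cfg@numClasses,
    upsample2 = 4L)
  list(config = cfg, encoder = encoder, aspp = aspp, decoder = decoder)
}

#' @describeIn buildModel side/side/channels of the deepest encoder map.
#' @param model a model description from \code{buildModel}.
#' @export
deepFeatureShape <- function(model) {
  n <- nrow(model$encoder)
  as.integer(c(model$encoder$outSide[n], model$encoder$outSide[n],
               model$encoder$outChannels[n]))
}

#' @describeIn buildModel side/side/channels of the shallow skip feature
#'   (before projection).
#' @export
skipFeatureShape <- function(model) {
  as.integer(c(model$decoder$skipSide, model$decoder$skipSide,
               model$decoder$skipChannels))
}

#' @describeIn buildModel side/side/channels of the network output for an
#'   input of side \code{inputSide} (defaults to the configured side).
#' @param inputSide optional square input side (divisible by the output
#'   stride).
#' @export
modelOutputShape <- function(model, inputSide = NULL) {
  cfg <- model$config
  if (is.null(inputSide)) inputSide <- cfg@inputSide
  if (inputSide %% cfg@downsampleFactor != 0)
    stop("inputSide must be divisible by the downsample factor")
  as.integer(c(inputSide, inputSide, cfg@numClasses))
}

#' Accumulate a segmentation confusion matrix
#'
#' Counts pixel pairs (truth = i, prediction = j) into a (k+1) x (k+1)
#' matrix with ground truth in rows; call repeatedly to accumulate over
#' images.
#'
#' @param truth,pred integer label grids of identical shape with labels in
#'   0 .. nClasses-1.
#' @param nClasses total number of classes (k+1).
#' @param cm an existing \code{\link{ConfusionMatrix}} to accumulate into,
#'   or NULL to start fresh.
#' @return A \code{\link{ConfusionMatrix}}.
#' @export
confusionAccumulate <- function(truth, pred, nClasses = 2, cm = NULL) {
  if (!identical(dim(truth), dim(pred)))
    stop("truth and pred must have identical shapes")
  n <- as.integer(nClasses)
  if (any(truth < 0 | truth >= n) || any(pred < 0 | pred >= n))
    stop("labels must lie in 0 .. nClasses-1")
  counts <- matrix(tabulate(as.integer(truth) * n + as.integer(pred) + 1L,
                            n * n), n, n, byrow = TRUE)
  dimnames(counts) <- list(truth = 0:(n - 1), pred = 0:(n - 1))
  if (!is.null(cm)) counts <- counts + cm@counts
  new("ConfusionMatrix", counts = counts)
}

classTallies <- function(cm) {
  counts <- cm@counts
  tp <- diag(counts)
  fn <- rowSums(counts) - tp
  fp <- colSums(counts) - tp
  tn <- sum(counts) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Mean intersection-over-union
#'
#' Mean over classes of TP / (FN + FP + TP) — the ratio of the
#' intersection to the union of the truth and prediction sets per class.
#' Classes absent from both truth and prediction are excluded from the
#' mean.
#'
#' @param cm a \code{\link{ConfusionMatrix}}.
#' @return A fraction in [0, 1]; 1 for a perfect prediction.
#' @export
mIoU <- function(cm) {
  t <- classTallies(cm)
  union <- t$tp + t$fn + t$fp
  if (all(union == 0)) stop("empty confusion matrix")
  mean((t$tp / union)[union > 0])
}

#' Mean pixel accuracy
#'
#' Mean over classes of (TP + TN) / (TP + TN + FP + FN), each class scored
#' one-vs-rest. Classes absent from both truth and prediction are excluded.
#'
#' @inheritParams mIoU
#' @return A fraction in [0, 1]; 1 for a perfect prediction.
#' @export
mPA <- function(cm) {
  t <- classTallies(cm)
  present <- (t$tp + t$fn + t$fp) > 0
  if (!any(present)) stop("empty confusion matrix")
  mean(((t$tp + t$tn) / (t$tp + t$tn + t$fp + t$fn))[present])
}

#' Initialize Adam optimizer state
#'
#' @param nParams number of learnable parameters.
#' @return An \code{\link{AdamState}} with t = 0 and zero moments.
#' @export
adamInit <- function(nParams) {
  new("AdamState", t = 0L, m = numeric(nParams), v = numeric(nParams))
}

#' One Adam update step
#'
#' The bias-corrected recurrence: t <- t + 1;
#' m <- beta1 m + (1 - beta1) g; v <- beta2 v + (1 - beta2) g^2;
#' mhat <- m / (1 - beta1^t); vhat <- v / (1 - beta2^t);
#' theta <- theta - lr * mhat / (sqrt(vhat) + epsilon). The first step for
#' any constant nonzero gradient has magnitude close to lr (bias
#' correction).
#'
#' @param state an \code{\link{AdamState}}.
#' @param grads gradient vector (same length as \code{params}).
#' @param params current parameter vector.
#' @param cfg a \code{\link{TrainConfig}} (beta1, beta2, epsilon).
#' @param lr learning rate for this step (defaults to \code{cfg@lr0}).
#' @return A list with updated \code{state} and \code{params}.
#' @export
adamStep <- function(state, grads, params, cfg = TrainConfig(), lr = cfg@lr0) {
  if (length(grads) != length(params) || length(grads) != length(state@m))
    stop("grads, params and state moments must have equal length")
  t <- state@t + 1L
  m <- cfg@beta1 * state@m + (1 - cfg@beta1) * grads
  v <- cfg@beta2 * state@v + (1 - cfg@beta2) * grads^2
  mhat <- m / (1 - cfg@beta1^t)
  vhat <- v / (1 - cfg@beta2^t)
  params <- params - lr * mhat / (sqrt(vhat) + cfg@epsilon)
  list(state = new("AdamState", t = t, m = m, v = v), params = params)
}

#' Learning rate at a given epoch
#'
#' "cos" anneals from lr0 to 0 over the configured epochs by
#' lr0/2 (1 + cos(pi (e-1)/epochs)); "step" decays by gamma each epoch.
#'
#' @param cfg a \code{\link{TrainConfig}}.
#' @param epoch 1-based epoch index.
#' @return The learning rate.
#' @export
lrAtEpoch <- function(cfg, epoch) {
  if (cfg@scheduler == "cos")
    cfg@lr0 / 2 * (1 + cos(pi * (epoch - 1) / cfg@epochs))
  else
    cfg@lr0 * cfg@gamma^(epoch - 1)
}

boxMean <- function(m, k) {
  h <- k %/% 2
  acc <- matrix(0, nrow(m), ncol(m))
  ri <- function(i) pmin(pmax(i, 1), nrow(m))
  ci <- function(j) pmin(pmax(j, 1), ncol(m))
  for (dr in -h:h) for (dc in -h:h)
    acc <- acc + m[ri(1:nrow(m) + dr), ci(1:ncol(m) + dc)]
  acc / k^2
}

#' Smoke-scale training run of the segmentation training protocol
#'
#' Exercises the two-phase transfer-learning schedule (backbone frozen for
#' the first \code{freezeEpochs} epochs with the large mini-batch, then the
#' whole parameter set with the small one) and the Adam recurrence on a
#' pixelwise logistic segmentation model with analytic gradients: per-pixel
#' features (noisy intensity plus 3x3 and 5x5 box means) pass through a
#' per-feature affine "backbone" (frozen phase keeps it at identity) into a
#' logistic classifier trained with binary cross-entropy (plus the
#' configured weight decay on the weights). This validates the optimizer
#' and schedule wiring end to end; it does not train the deep network,
#' which is described at shape level by \code{\link{buildModel}}.
#'
#' @param nImages number of synthetic vein images (default 16).
#' @param cfg a \code{\link{TrainConfig}}; defaults to a 2 frozen + 2
#'   unfrozen epoch smoke schedule.
#' @param seed RNG seed for data and noise.
#' @return A data.frame with one row per epoch: epoch, phase, lr, loss.
#' @export
trainSmoke <- function(nImages = 16,
                       cfg = TrainConfig(epochs = 4, freezeEpochs = 2),
                       seed = 1) {
  data <- withSeed(seed, {
    lapply(seq_len(nImages), function(i) {
      spec <- bandPhantomSpec(lengthPx = 60, thicknessPx = 7,
                              tiltDeg = stats::runif(1, -10, 10),
                              nGaps = 0, nHoles = 0, speckleDensity = 0,
                              seed = seed + i)
      mask <- generatePhantom(spec)$mask
      intensity <- mask + matrix(stats::rnorm(length(mask), 0, 0.3),
                                 nrow(mask), ncol(mask))
      list(y = mask,
           f = list(intensity, boxMean(intensity, 3), boxMean(intensity, 5)))
    })
  })
  nf <- 3L
  params <- c(rep(1, nf), rep(0, nf), rep(0.1, nf), 0)  # a, b, w, c
  state <- adamInit(length(params))
  hist <- list()
  for (epoch in seq_len(cfg@epochs)) {
    frozen <- epoch <= cfg@freezeEpochs
    batch <- if (frozen) cfg@batchFrozen else cfg@batchUnfrozen
    lr <- lrAtEpoch(cfg, epoch)
    ord <- withSeed(seed + 1000 + epoch, sample(nImages))
    losses <- c()
    for (start in seq(1, nImages, by = batch)) {
      ids <- ord[start:min(start + batch - 1, nImages)]
      g <- numeric(length(params)); loss <- 0
      for (id in ids) {
        d <- data[[id]]
        a <- params[1:nf]; b <- params[nf + 1:nf]
        w <- params[2 * nf + 1:nf]; cc <- params[2 * nf + nf + 1]
        z <- matrix(cc, nrow(d$y), ncol(d$y))
        for (k in seq_len(nf)) z <- z + w[k] * (a[k] * d$f[[k]] + b[k])
        p <- 1 / (1 + exp(-z))
        npx <- length(d$y)
        loss <- loss + -mean(d$y * log(p + 1e-12) +
                             (1 - d$y) * log(1 - p + 1e-12))
        dz <- (p - d$y) / npx
        for (k in seq_len(nf)) {
          g[2 * nf + k] <- g[2 * nf + k] + sum(dz * (a[k] * d$f[[k]] + b[k]))
          if (!frozen) {
            g[k] <- g[k] + sum(dz * w[k] * d$f[[k]])
            g[nf + k] <- g[nf + k] + sum(dz * w[k])
          }
        }
        g[2 * nf + nf + 1] <- g[2 * nf + nf + 1] + sum(dz)
      }
      g <- g / length(ids)
      wIdx <- 2 * nf + 1:nf
      g[wIdx] <- g[wIdx] + cfg@weightDecay * params[wIdx]
      upd <- adamStep(state, g, params, cfg, lr)
      state <- upd$state; params <- upd$params
      losses <- c(losses, loss / length(ids))
    }
    hist[[epoch]] <- data.frame(epoch = epoch,
                                phase = if (frozen) "frozen" else "unfrozen",
                                lr = lr, loss = mean(losses))
  }
  do.call(rbind, hist)
}

#' Evaluate predicted segmentation masks against ground truth
#'
#' Reads same-named PNG/TIFF mask pairs from two directories, accumulates
#' one confusion matrix over all of them and reports mean
#' intersection-over-union and mean pixel accuracy.
#'
#' @param predDir,gtDir directories of predicted and ground-truth masks.
#' @param nClasses number of classes (binary masks: 2).
#' @return A list with \code{miou}, \code{mpa} and the
#'   \code{\link{ConfusionMatrix}}.
#' @export
evalSegmentationDirs <- function(predDir, gtDir, nClasses = 2) {
  preds <- list.files(predDir, pattern = "\\.(png|tif|tiff)$")
  if (!length(preds)) stop("no mask files in ", predDir)
  cm <- NULL
  for (f in preds) {
    gt <- file.path(gtDir, f)
    if (!file.exists(gt)) stop("no ground-truth mask for ", f)
    cm <- confusionAccumulate(readMask(gt), readMask(file.path(predDir, f)),
                              nClasses, cm)
  }
  list(miou = mIoU(cm), mpa = mPA(cm), confusion = cm)
}
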