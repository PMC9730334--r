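#' @import methods
NULL

#' Repair parameters for the convex hull-scan method
#'
#' Controls how fragmented vein masks are bridged. A gap between two mask
#' components is bridged only when their boundary-to-boundary Euclidean
#' distance is at most \code{maxGapPx}; components smaller than
#' \code{minFragmentPx} pixels are treated as noise/isolated specks and are
#' swept into the hull of a nearby gap rather than bridged on their own;
#' \code{windowMarginPx} widens the local window around the two nearest
#' boundary points inside which hull points are collected.
#'
#' @slot maxGapPx largest fragment-to-fragment distance to bridge (pixels).
#' @slot minFragmentPx area (pixels) below which a component is noise.
#' @slot windowMarginPx margin of the local gap window (pixels).
#' @export
setClass("RepairParams",
  representation(maxGapPx = "numeric", minFragmentPx = "numeric",
                 windowMarginPx = "numeric"),
  prototype(maxGapPx = 40, minFragmentPx = 25, windowMarginPx = 10))

setValidity("RepairParams", function(object) {
  v <- c(object@maxGapPx, object@minFragmentPx, object@windowMarginPx)
  if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0))
    return("maxGapPx, minFragmentPx and windowMarginPx must be strictly positive scalars")
  TRUE
})

#' @rdname RepairParams-class
#' @param maxGapPx,minFragmentPx,windowMarginPx see slot documentation.
#' @return A \code{RepairParams} object.
#' @examples
#' RepairParams(maxGapPx = 30)
#' @export
RepairParams <- function(maxGapPx = 40, minFragmentPx = 25,
                         windowMarginPx = 10) {
  new("RepairParams", maxGapPx = maxGapPx, minFragmentPx = minFragmentPx,
      windowMarginPx = windowMarginPx)
}

#' Configuration of the F-3MS refinement pipeline
#'
#' @slot medianKernel odd side of the median-filter window (pixels);
#'   default 5, the kernel with the best measurement accuracy in the
#'   kernel-size ablation.
#' @slot openKernel odd side of the square opening element (pixels).
#' @slot skeletonElement \code{"cross"} (3x3 4-neighborhood) or
#'   \code{"square"} (3x3 box) structuring element for skeletonization.
#' @export
setClass("F3msConfig",
  representation(medianKernel = "integer", openKernel = "integer",
                 skeletonElement = "character"),
  prototype(medianKernel = 5L, openKernel = 3L, skeletonElement = "cross"))

setValidity("F3msConfig", function(object) {
  if (object@medianKernel < 1L || object@medianKernel %% 2L == 0L)
    return("medianKernel must be odd and >= 1")
  if (object@openKernel < 1L || object@openKernel %% 2L == 0L)
    return("openKernel must be odd and >= 1")
  if (!object@skeletonElement %in% c("cross", "square"))
    return("skeletonElement must be 'cross' or 'square'")
  TRUE
})

#' @rdname F3msConfig-class
#' @param medianKernel,openKernel,skeletonElement see slot documentation.
#' @return A \code{F3msConfig} object.
#' @examples
#' F3msConfig(medianKernel = 3)
#' @export
F3msConfig <- function(medianKernel = 5, openKernel = 3,
                       skeletonElement = "cross") {
  new("F3msConfig", medianKernel = as.integer(medianKernel),
      openKernel = as.integer(openKernel), skeletonElement = skeletonElement)
}

#' Per-column width profile along a vein skeleton
#'
#' Holds, per sampled column x, the half-separation (v(x)-u(x))/2 of the
#' upper/lower contours, the ordinate used for the local angle, the cosine
#' of the local skeleton inclination, and the angle-corrected true width
#' halfSep * cos(theta).
#'
#' @slot columns 0-based x indices (strictly increasing).
#' @slot skeletonOrdinate ordinate per column used for the angle.
#' @slot halfSep (v(x)-u(x))/2 per column (pixels).
#' @slot cosTheta cosine of the local inclination, in (0, 1].
#' @slot trueWidth halfSep * cosTheta per column (pixels).
#' @export
setClass("WidthProfile",
  representation(columns = "numeric", skeletonOrdinate = "numeric",
                 halfSep = "numeric", cosTheta = "numeric",
                 trueWidth = "numeric"))

setValidity("WidthProfile", function(object) {
  n <- length(object@columns)
  if (any(vapply(list(object@skeletonOrdinate, object@halfSep,
                      object@cosTheta, object@trueWidth),
                 length, 1L) != n))
    return("all profile fields must have equal length")
  if (n > 1 && any(diff(object@columns) <= 0))
    return("columns must be strictly increasing")
  if (any(object@cosTheta <= 0 | object@cosTheta > 1 + 1e-12))
    return("cosTheta must lie in (0, 1]")
  if (any(object@trueWidth > object@halfSep + 1e-9))
    return("trueWidth must not exceed halfSep")
  TRUE
})

#' @describeIn WidthProfile-class number of profiled columns.
#' @param x a \code{WidthProfile}.
#' @export
setMethod("length", "WidthProfile", function(x) length(x@columns))

#' @describeIn WidthProfile-class angle-corrected per-column widths (pixels).
#' @param object a \code{WidthProfile}.
#' @export
setGeneric("trueWidth", function(object) standardGeneric("trueWidth"))

#' @rdname WidthProfile-class
#' @export
setMethod("trueWidth", "WidthProfile", function(object) object@trueWidth)

#' @describeIn WidthProfile-class per-column cosine of inclination.
#' @export
setGeneric("cosTheta", function(object) standardGeneric("cosTheta"))

#' @rdname WidthProfile-class
#' @export
setMethod("cosTheta", "WidthProfile", function(object) object@cosTheta)

setMethod("show", "WidthProfile", function(object) {
  cat(sprintf("WidthProfile: %d columns, mean true width %.3f px (half-separation %.3f px)\n",
              length(object@columns), mean(object@trueWidth),
              mean(object@halfSep)))
})

#' End-to-end vein measurement
#'
#' Result of \code{\link{measureVein}}: the skeleton pixel count, the length
#' and mean angle-corrected width both in pixels and in millimetres (via the
#' scale bar), plus provenance (orientation angle, width mode, and the full
#' per-column profile).
#'
#' @slot skeletonPixels number of skeleton foreground pixels.
#' @slot lengthMm skeletonPixels * mmPerPixel.
#' @slot meanWidthPx mean angle-corrected width (pixels).
#' @slot widthMm meanWidthPx * mmPerPixel.
#' @slot mmPerPixel the scale bar (mm per pixel).
#' @slot angleDeg principal-axis angle removed before measurement (degrees).
#' @slot mode width angle-ordinate mode used.
#' @slot profile the \code{WidthProfile}.
#' @export
setClass("VeinMeasurement",
  representation(skeletonPixels = "numeric", lengthMm = "numeric",
                 meanWidthPx = "numeric", widthMm = "numeric",
                 mmPerPixel = "numeric", angleDeg = "numeric",
                 mode = "character", profile = "WidthProfile"))

setValidity("VeinMeasurement", function(object) {
  if (object@mmPerPixel <= 0) return("mmPerPixel must be strictly positive")
  if (object@skeletonPixels < 0 || object@lengthMm < 0 ||
      object@meanWidthPx < 0 || object@widthMm < 0)
    return("measurements must be non-negative")
  if (abs(object@lengthMm - object@skeletonPixels * object@mmPerPixel) > 1e-9)
    return("lengthMm must equal skeletonPixels * mmPerPixel")
  TRUE
})

setMethod("show", "VeinMeasurement", function(object) {
  cat("VeinMeasurement\n")
  cat(sprintf("  scale bar    : %.4f mm/pixel\n", object@mmPerPixel))
  cat(sprintf("  skeleton     : %g pixels\n", object@skeletonPixels))
  cat(sprintf("  length       : %.4f mm\n", object@lengthMm))
  cat(sprintf("  mean width   : %.4f px  (%s mode)\n", object@meanWidthPx,
              object@mode))
  cat(sprintf("  width        : %.4f mm\n", object@widthMm))
  cat(sprintf("  axis removed : %.2f deg\n", object@angleDeg))
})

#' @describeIn VeinMeasurement-class measured length in millimetres.
#' @param object a \code{VeinMeasurement}.
#' @export
setGeneric("lengthMm", function(object) standardGeneric("lengthMm"))

#' @rdname VeinMeasurement-class
#' @export
setMethod("lengthMm", "VeinMeasurement", function(object) object@lengthMm)

#' @describeIn VeinMeasurement-class measured mean width in millimetres.
#' @export
setGeneric("widthMm", function(object) standardGeneric("widthMm"))

#' @rdname VeinMeasurement-class
#' @export
setMethod("widthMm", "VeinMeasurement", function(object) object@widthMm)

#' @describeIn VeinMeasurement-class skeleton foreground pixel count.
#' @export
setGeneric("skeletonPixels", function(object) standardGeneric("skeletonPixels"))

#' @rdname VeinMeasurement-class
#' @export
setMethod("skeletonPixels", "VeinMeasurement",
          function(object) object@skeletonPixels)

#' @describeIn VeinMeasurement-class the per-column width profile.
#' @export
setGeneric("widthProfile", function(object) standardGeneric("widthProfile"))

#' @rdname VeinMeasurement-class
#' @export
setMethod("widthProfile", "VeinMeasurement", function(object) object@profile)

#' Per-class confusion matrix for segmentation evaluation
#'
#' Counts with ground-truth classes in rows and predicted classes in
#' columns; feeds \code{\link{mIoU}} and \code{\link{mPA}}. Accumulate over
#' images with \code{\link{confusionAccumulate}}.
#'
#' @slot counts square count matrix, truth i in rows, prediction j in columns.
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  cm <- object@counts
  if (nrow(cm) != ncol(cm)) return("counts must be square")
  if (any(cm < 0)) return("counts must be non-negative")
  TRUE
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: %d classes, %g pixels\n",
              nrow(object@counts), sum(object@counts)))
  print(object@counts)
})

#' Configuration of the MobileNetV2-DeepLabV3+ wiring contract
#'
#' @slot numClasses number of output classes (vein vs background: 2).
#' @slot inputSide square input resolution (pixels), default 512.
#' @slot downsampleFactor output stride of the encoder, 8 or 16.
#' @slot asppChannels channels of every ASPP branch and of the fused head.
#' @slot decoderSkipChannels channels of the projected shallow skip.
#' @export
setClass("ModelConfig",
  representation(numClasses = "integer", inputSide = "integer",
                 downsampleFactor = "integer", asppChannels = "integer",
                 decoderSkipChannels = "integer"),
  prototype(numClasses = 2L, inputSide = 512L, downsampleFactor = 16L,
            asppChannels = 256L, decoderSkipChannels = 48L))

setValidity("ModelConfig", function(object) {
  if (!object@downsampleFactor %in% c(8L, 16L))
    return("downsampleFactor must be 8 or 16")
  if (object@inputSide %% object@downsampleFactor != 0L)
    return("inputSide must be divisible by downsampleFactor")
  if (object@numClasses < 2L) return("numClasses must be >= 2")
  TRUE
})

#' @rdname ModelConfig-class
#' @param numClasses,inputSide,downsampleFactor,asppChannels,decoderSkipChannels
#'   see slot documentation.
#' @return A \code{ModelConfig} object.
#' @examples
#' ModelConfig(downsampleFactor = 8)
#' @export
ModelConfig <- function(numClasses = 2, inputSide = 512,
                        downsampleFactor = 16, asppChannels = 256,
                        decoderSkipChannels = 48) {
  new("ModelConfig", numClasses = as.integer(numClasses),
      inputSide = as.integer(inputSide),
      downsampleFactor = as.integer(downsampleFactor),
      asppChannels = as.integer(asppChannels),
      decoderSkipChannels = as.integer(decoderSkipChannels))
}

#' Training configuration (transfer-learning schedule + Adam)
#'
#' Mirrors the training protocol: 100 epochs, backbone frozen for the first
#' 50 with mini-batch 8, whole network unfrozen afterwards with mini-batch
#' 4; Adam with lr 0.001, beta1 0.9, beta2 0.99, weight decay 5e-4; "cos"
#' learning-rate scheduler (gamma 0.94 is the step-decay rate, stored but
#' unused under "cos"); dropout 0.5.
#'
#' @slot epochs,freezeEpochs,batchFrozen,batchUnfrozen schedule.
#' @slot lr0,beta1,beta2,weightDecay,epsilon Adam hyper-parameters.
#' @slot scheduler "cos" or "step".
#' @slot gamma step-decay rate (used by the "step" scheduler only).
#' @slot dropout dropout probability.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", freezeEpochs = "integer",
                 batchFrozen = "integer", batchUnfrozen = "integer",
                 lr0 = "numeric", scheduler = "character", beta1 = "numeric",
                 beta2 = "numeric", weightDecay = "numeric",
                 gamma = "numeric", dropout = "numeric", epsilon = "numeric"),
  prototype(epochs = 100L, freezeEpochs = 50L, batchFrozen = 8L,
            batchUnfrozen = 4L, lr0 = 0.001, scheduler = "cos", beta1 = 0.9,
            beta2 = 0.99, weightDecay = 5e-4, gamma = 0.94, dropout = 0.5,
            epsilon = 1e-8))

setValidity("TrainConfig", function(object) {
  if (object@beta1 <= 0 || object@beta1 >= 1 ||
      object@beta2 <= 0 || object@beta2 >= 1)
    return("beta1 and beta2 must lie strictly in (0, 1)")
  if (object@freezeEpochs > object@epochs)
    return("freezeEpochs must not exceed epochs")
  if (!object@scheduler %in% c("cos", "step"))
    return("scheduler must be 'cos' or 'step'")
  TRUE
})

#' @rdname TrainConfig-class
#' @param epochs,freezeEpochs,batchFrozen,batchUnfrozen,lr0,scheduler
#'   schedule and optimizer settings; see slots.
#' @param beta1,beta2,weightDecay,gamma,dropout,epsilon see slots.
#' @return A \code{TrainConfig} object.
#' @examples
#' TrainConfig(epochs = 4, freezeEpochs = 2)
#' @export
TrainConfig <- function(epochs = 100, freezeEpochs = 50, batchFrozen = 8,
                        batchUnfrozen = 4, lr0 = 0.001, scheduler = "cos",
                        beta1 = 0.9, beta2 = 0.99, weightDecay = 5e-4,
                        gamma = 0.94, dropout = 0.5, epsilon = 1e-8) {
  new("TrainConfig", epochs = as.integer(epochs),
      freezeEpochs = as.integer(freezeEpochs),
      batchFrozen = as.integer(batchFrozen),
      batchUnfrozen = as.integer(batchUnfrozen), lr0 = lr0,
      scheduler = scheduler, beta1 = beta1, beta2 = beta2,
      weightDecay = weightDecay, gamma = gamma, dropout = dropout,
      epsilon = epsilon)
}

#' Adam optimizer state
#'
#' First/second moment accumulators and step counter, initialized to zero.
#'
#' @slot t step counter (>= 0).
#' @slot m first-moment accumulator (one entry per parameter).
#' @slot v second-moment accumulator (elementwise >= 0).
#' @export
setClass("AdamState",
  representation(t = "integer", m = "numeric", v = "numeric"))

setValidity("AdamState", function(object) {
  if (object@t < 0L) return("t must be >= 0")
  if (length(object@m) != length(object@v))
    return("m and v must have equal length")
  if (any(object@v < 0)) return("v must be elementwise non-negative")
  if (object@t == 0L && (any(object@m != 0) || any(object@v != 0)))
    return("m and v must be zero at t = 0")
  TRUE
})

#' Synthetic vein-phantom specification
#'
#' Defines an elongated vein band phantom: a centerline polyline swept with
#' a disc of radius thickness/2 (a capsule), degraded by transverse
#' occlusion gaps, interior pinholes and isolated background speckle. All
#' randomness in degradation flows from \code{seed}.
#'
#' @slot canvas c(height, width) in pixels.
#' @slot centerline n x 2 matrix of (x, y) control points, 0-based.
#' @slot thickness full band thickness T in pixels (>= 3).
#' @slot nGaps number of transverse occlusion gaps.
#' @slot gapLenPx gap length along the centerline (pixels).
#' @slot nHoles number of interior 1-2 px pinholes.
#' @slot speckleDensity fraction of background pixels turned into specks.
#' @slot seed integer RNG seed fixing all degradation randomness.
#' @export
setClass("PhantomSpec",
  representation(canvas = "integer", centerline = "matrix",
                 thickness = "numeric", nGaps = "integer",
                 gapLenPx = "numeric", nHoles = "integer",
                 speckleDensity = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@canvas) != 2 || any(object@canvas < 1))
    return("canvas must be c(height, width) with positive entries")
  if (ncol(object@centerline) != 2 || nrow(object@centerline) < 2)
    return("centerline must be an n x 2 matrix with n >= 2")
  if (object@thickness < 3) return("thickness must be >= 3")
  if (object@nGaps < 0 || object@nHoles < 0 || object@gapLenPx < 0 ||
      object@speckleDensity < 0)
    return("gaps, holes, gap length and speckle density must be non-negative")
  TRUE
})

#' @rdname PhantomSpec-class
#' @param canvas,centerline,thickness,nGaps,gapLenPx,nHoles,speckleDensity,seed
#'   see slot documentation.
#' @return A \code{PhantomSpec} object.
#' @export
PhantomSpec <- function(canvas, centerline, thickness = 20, nGaps = 2,
                        gapLenPx = 8, nHoles = 5, speckleDensity = 5e-4,
                        seed = 1) {
  new("PhantomSpec", canvas = as.integer(canvas),
      centerline = as.matrix(centerline), thickness = thickness,
      nGaps = as.integer(nGaps), gapLenPx = gapLenPx,
      nHoles = as.integer(nHoles), speckleDensity = speckleDensity,
      seed = as.integer(seed))
}

#' Exact ground truth of a synthetic phantom
#'
#' @slot centerlineLenPx polyline arc length (pixels).
#' @slot thicknessPx full band thickness T.
#' @slot halfWidthPx T/2, the half-width the width model should recover.
#' @slot gapSpans arc-length intervals removed by occlusion gaps
#'   (2-column matrix, one row per gap; zero rows before degradation).
#' @slot cleanMask the pre-degradation binary mask.
#' @export
setClass("PhantomTruth",
  representation(centerlineLenPx = "numeric", thicknessPx = "numeric",
                 halfWidthPx = "numeric", gapSpans = "matrix",
                 cleanMask = "matrix"))

setValidity("PhantomTruth", function(object) {
  if (object@centerlineLenPx <= 0) return("centerlineLenPx must be positive")
  if (abs(object@halfWidthPx - object@thicknessPx / 2) > 1e-12)
    return("halfWidthPx must equal thicknessPx/2 exactly")
  TRUE
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: centerline %.2f px, thickness %g px, %d gap(s)\n",
              object@centerlineLenPx, object@thicknessPx,
              nrow(object@gapSpans)))
})
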