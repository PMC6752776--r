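#' @import methods
#' @importFrom stats rnorm runif qnorm setNames var quantile
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib fundusAdapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.LEFT <- "left"
.RIGHT <- "right"

#' Ground-truth metadata attached to a synthetic fundus photograph
#'
#' Records what the generator knows about an image: the laterality label, the
#' fraction of the fundus area hidden by occlusion, the fraction of the optic
#' disc still inside the frame, the canvas size, the disc centre (0-based
#' pixel coordinates) and the seed the image was rendered from.
#'
#' @slot laterality `"left"` or `"right"`.
#' @slot obscuredFraction Fraction of the fundus area occluded, in \[0, 1\].
#' @slot discVisibleFraction Fraction of the optic disc visible, in \[0, 1\].
#' @slot canvasSize Integer `(width, height)` of the canvas in pixels.
#' @slot discCenter Numeric `(x, y)` disc centre, 0-based pixel coordinates.
#' @slot seed Integer seed the image was rendered from.
#' @export
setClass("ImageMeta",
  representation(
    laterality = "character",
    obscuredFraction = "numeric",
    discVisibleFraction = "numeric",
    canvasSize = "integer",
    discCenter = "numeric",
    seed = "integer"
  )
)

setValidity("ImageMeta", function(object) {
  msg <- character()
  if (!object@laterality %in% c(.LEFT, .RIGHT))
    msg <- c(msg, "laterality must be 'left' or 'right'")
  if (object@obscuredFraction < 0 || object@obscuredFraction > 1)
    msg <- c(msg, "obscuredFraction must lie in [0, 1]")
  if (object@discVisibleFraction < 0 || object@discVisibleFraction > 1)
    msg <- c(msg, "discVisibleFraction must lie in [0, 1]")
  if (length(object@canvasSize) != 2L || any(object@canvasSize <= 0L))
    msg <- c(msg, "canvasSize must be two positive integers")
  if (length(object@discCenter) != 2L)
    msg <- c(msg, "discCenter must have length 2")
  if (length(msg)) msg else TRUE
})

#' An 8-bit RGB fundus photograph
#'
#' The unit that flows through preprocessing, training and inference: a
#' `height x width x 3` array of intensities in \[0, 255\] plus optional
#' generator metadata (absent for external images).
#'
#' @slot pixels Numeric array `height x width x 3`, values in \[0, 255\].
#' @slot meta An [ImageMeta-class] object, or `NULL` for external images.
#' @export
setClass("FundusImage",
  representation(pixels = "array", meta = "ANY"),
  prototype(meta = NULL)
)

setValidity("FundusImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a height x width x 3 array")
  if (any(d[1:2] < 1L)) return("pixels must be non-empty")
  rng <- range(object@pixels)
  if (rng[1] < 0 || rng[2] > 255)
    return("intensities must lie in [0, 255]")
  if (!is.null(object@meta) && !is(object@meta, "ImageMeta"))
    return("meta must be NULL or an ImageMeta")
  TRUE
})

#' Configuration of the synthetic fundus generator
#'
#' Defaults describe the geometry the laterality classifier relies on: an
#' optic disc displaced horizontally by 0.55 fundus radii toward the
#' laterality side, a central macula, vessel arcs, an overexposed rim, and
#' black side bars occupying 12.5% of the width on each side.
#'
#' @slot nImages Number of images to generate.
#' @slot leftFraction Fraction of images labelled left, in \[0, 1\].
#' @slot canvasSizes List of `(width, height)` integer pairs; landscape
#'   (width >= height), cycled over the dataset.
#' @slot discOffset Horizontal disc displacement as a fraction of the fundus
#'   radius.
#' @slot discRadiusFrac Disc radius as a fraction of the fundus radius.
#' @slot maculaRadiusFrac Macula radius as a fraction of the fundus radius.
#' @slot vesselCount Number of vessel arcs emanating from the disc.
#' @slot poorQualityFraction Fraction of images rendered poor quality.
#' @slot borderBarFrac Black side-bar width as a fraction of the width.
#' @slot seed Integer base seed; the dataset is a pure function of the
#'   configuration.
#' @export
setClass("SynthConfig",
  representation(
    nImages = "integer",
    leftFraction = "numeric",
    canvasSizes = "list",
    discOffset = "numeric",
    discRadiusFrac = "numeric",
    maculaRadiusFrac = "numeric",
    vesselCount = "integer",
    poorQualityFraction = "numeric",
    borderBarFrac = "numeric",
    seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@leftFraction < 0 || object@leftFraction > 1)
    msg <- c(msg, "leftFraction must lie in [0, 1]")
  if (object@poorQualityFraction < 0 || object@poorQualityFraction > 1)
    msg <- c(msg, "poorQualityFraction must lie in [0, 1]")
  for (f in c(object@discOffset, object@discRadiusFrac,
              object@maculaRadiusFrac, object@borderBarFrac))
    if (f <= 0 || f >= 1)
      msg <- c(msg, "radius/offset fractions must lie in (0, 1)")
  for (cs in object@canvasSizes) {
    if (length(cs) != 2L || any(cs <= 0))
      msg <- c(msg, "canvas sizes must be positive (width, height) pairs")
    else if (cs[1] < cs[2])
      msg <- c(msg, "canvas sizes must be landscape (width >= height)")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Configuration of fundus size normalisation and enhancement
#'
#' @slot targetSide Output side length in pixels (square output).
#' @slot maskRatio Circular-mask radius as a fraction of half the side.
#' @slot borderThreshold Dark-border cut-off as a fraction of the peak
#'   per-line intensity sum.
#' @slot method One of `"ORIGINAL"`, `"CLAHE"`, `"LSACR"`, `"GRAY"`.
#' @slot claheClip CLAHE contrast clip limit.
#' @slot claheTiles CLAHE tile grid `(nx, ny)`.
#' @slot lsacrAlpha,lsacrBeta,lsacrGamma Scalars of the Gaussian
#'   background-subtraction form `clip(alpha*I - beta*G(I) + gamma)`.
#' @slot lsacrSigmaFrac Gaussian scale as a fraction of the image side.
#' @export
setClass("PreprocessConfig",
  representation(
    targetSide = "integer",
    maskRatio = "numeric",
    borderThreshold = "numeric",
    method = "character",
    claheClip = "numeric",
    claheTiles = "integer",
    lsacrAlpha = "numeric",
    lsacrBeta = "numeric",
    lsacrGamma = "numeric",
    lsacrSigmaFrac = "numeric"
  )
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@targetSide < 32L) msg <- c(msg, "targetSide must be >= 32")
  if (object@maskRatio <= 0 || object@maskRatio > 1)
    msg <- c(msg, "maskRatio must lie in (0, 1]")
  if (object@borderThreshold < 0 || object@borderThreshold >= 1)
    msg <- c(msg, "borderThreshold must lie in [0, 1)")
  if (!object@method %in% c("ORIGINAL", "CLAHE", "LSACR", "GRAY"))
    msg <- c(msg, "unknown enhancement method")
  if (length(msg)) msg else TRUE
})

#' Training configuration for the laterality classifier
#'
#' Houses the optimiser constants, the augmentation bounds, and every
#' constant of the self-adaptive strategy: initial learning rate `l0 = 0.1`,
#' alert length `k = 5`, reduction factor `alpha = 0.5`, monitor threshold
#' `0.005`, pool gates accuracy >= 0.95 and loss <= 0.1, and a best-model
#' reload every 10 epochs.
#'
#' @slot backbone `"tiny"` or `"inception_v3"`.
#' @slot inputSide Input side length in pixels.
#' @slot l0 Initial learning rate.
#' @slot momentum SGD momentum coefficient.
#' @slot l2Lambda L2 regularisation strength.
#' @slot batchSize Mini-batch size.
#' @slot maxEpochs Number of training epochs.
#' @slot k Alert-period length in epochs.
#' @slot alpha Learning-rate reduction factor, in (0, 1].
#' @slot mThreshold Monitor threshold gating the model pool.
#' @slot accGate Accuracy gate for the model pool.
#' @slot lossGate Loss gate for the model pool.
#' @slot reloadPeriod Pool-reload period in epochs.
#' @slot minLr Learning-rate floor.
#' @slot gradClip Global L2 gradient-norm clip applied to the mean
#'   mini-batch gradient (0 disables clipping).
#' @slot shiftMax Maximum absolute horizontal shift in pixels.
#' @slot rotMax Maximum absolute rotation in degrees.
#' @slot seed Integer seed governing initialisation, shuffling, augmentation.
#' @export
setClass("TrainConfig",
  representation(
    backbone = "character",
    inputSide = "integer",
    l0 = "numeric",
    momentum = "numeric",
    l2Lambda = "numeric",
    batchSize = "integer",
    maxEpochs = "integer",
    k = "integer",
    alpha = "numeric",
    mThreshold = "numeric",
    accGate = "numeric",
    lossGate = "numeric",
    reloadPeriod = "integer",
    minLr = "numeric",
    gradClip = "numeric",
    shiftMax = "numeric",
    rotMax = "numeric",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@backbone %in% c("tiny", "inception_v3"))
    msg <- c(msg, "backbone must be 'tiny' or 'inception_v3'")
  if (object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in (0, 1]")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (object@mThreshold <= 0 || object@accGate <= 0 || object@lossGate <= 0)
    msg <- c(msg, "gates must be positive")
  if (object@shiftMax < 0 || object@rotMax < 0)
    msg <- c(msg, "augmentation bounds must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-epoch validation metrics and the derived monitor
#'
#' The monitor is `M = (1 - accuracy) * loss`; smaller is better, and `M`
#' vanishes exactly when accuracy is perfect or loss is zero.
#'
#' @slot epoch Epoch index, starting at 1.
#' @slot accuracy Validation accuracy in \[0, 1\].
#' @slot loss Validation loss, non-negative.
#' @slot monitor The derived monitor value.
#' @export
setClass("EpochMetrics",
  representation(
    epoch = "integer",
    accuracy = "numeric",
    loss = "numeric",
    monitor = "numeric"
  )
)

#' State of the self-adaptive training controller
#'
#' The controller's entire memory: current learning rate, alert-period
#' bookkeeping, the previous monitor value, the best pool monitor
#' (initialised to the monitor threshold so the chained pool condition is
#' satisfiable from an empty pool) and the single best snapshot.
#'
#' @slot lr Current learning rate.
#' @slot alertActive Whether an alert period is running.
#' @slot alertBaseline Baseline monitor the alert compares against.
#' @slot alertCount Epochs elapsed in the current alert, in \[0, k\].
#' @slot mPrev Previous epoch's monitor (`NA` before the first epoch).
#' @slot mBest Best pool monitor, non-increasing over the run.
#' @slot pool List of length 0 or 1 holding the best snapshot.
#' @slot epoch Last epoch observed (0 initially).
#' @slot config The [TrainConfig-class] constants.
#' @export
setClass("ControllerState",
  representation(
    lr = "numeric",
    alertActive = "logical",
    alertBaseline = "numeric",
    alertCount = "integer",
    mPrev = "numeric",
    mBest = "numeric",
    pool = "list",
    epoch = "integer",
    config = "TrainConfig"
  )
)

#' A GAP-headed convolutional laterality classifier
#'
#' A network ending in global average pooling followed by a single affine
#' layer to two logits and softmax, so class activation maps are
#' well-defined. `P1` is the probability of the left eye, `P2` of the right.
#'
#' @slot backbone `"tiny"` or `"inception_v3"`.
#' @slot inputSide Expected input side length in pixels.
#' @slot layers Layer list (weights included) evaluated sequentially.
#' @export
setClass("FundusClassifier",
  representation(
    backbone = "character",
    inputSide = "integer",
    layers = "list"
  )
)

#' Softmax output of the laterality classifier
#'
#' @slot pLeft Probability `P1` of the left eye.
#' @slot pRight Probability `P2` of the right eye.
#' @slot label Argmax label, `"left"` on ties.
#' @export
setClass("PredictionResult",
  representation(pLeft = "numeric", pRight = "numeric", label = "character")
)

setValidity("PredictionResult", function(object) {
  if (abs(object@pLeft + object@pRight - 1) > 1e-6)
    return("probabilities must sum to 1")
  if (object@pLeft < 0 || object@pLeft > 1)
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' A class activation heat map
#'
#' @slot values `H x W` matrix of activations min-max normalised to \[0, 1\]
#'   (all zeros when the raw map is constant).
#' @slot targetClass `"left"` or `"right"`.
#' @export
setClass("HeatMap",
  representation(values = "matrix", targetClass = "character")
)

#' Evaluation report for left-eye detection
#'
#' Confusion matrix (left eye positive), accuracy / sensitivity /
#' specificity with Wilson 95% confidence intervals, AUC with a DeLong 95%
#' interval, and the ROC points from the threshold sweep.
#'
#' @slot confusion Named integer vector `tp, fn, fp, tn`.
#' @slot accuracy,sensitivity,specificity Point estimates in \[0, 1\].
#' @slot accuracyCI,sensitivityCI,specificityCI `(lower, upper)` pairs.
#' @slot auc Area under the ROC curve.
#' @slot aucCI `(lower, upper)` DeLong interval.
#' @slot rocPoints `data.frame` with columns `fpr`, `tpr`.
#' @export
setClass("EvalReport",
  representation(
    confusion = "integer",
    accuracy = "numeric",
    accuracyCI = "numeric",
    sensitivity = "numeric",
    sensitivityCI = "numeric",
    specificity = "numeric",
    specificityCI = "numeric",
    auc = "numeric",
    aucCI = "numeric",
    rocPoints = "data.frame"
  )
)
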