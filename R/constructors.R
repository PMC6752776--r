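#' Create a synthetic-generator configuration
#'
#' @param nImages Number of images.
#' @param leftFraction Fraction of left-eye images.
#' @param canvasSizes List of `(width, height)` pairs, landscape.
#' @param discOffset Horizontal disc displacement as a fraction of the
#'   fundus radius.
#' @param discRadiusFrac,maculaRadiusFrac Structure radii as fractions of
#'   the fundus radius.
#' @param vesselCount Number of vessel arcs.
#' @param poorQualityFraction Fraction of images rendered poor quality.
#' @param borderBarFrac Black side-bar width as a fraction of the width.
#' @param seed Integer base seed.
#' @return A [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(nImages = 10, canvasSizes = list(c(160, 120)))
#' @export
synthConfig <- function(nImages = 100L, leftFraction = 0.5,
                        canvasSizes = list(c(2560L, 1920L), c(3280L, 2480L),
                                           c(4700L, 3100L)),
                        discOffset = 0.55, discRadiusFrac = 0.18,
                        maculaRadiusFrac = 0.12, vesselCount = 6L,
                        poorQualityFraction = 0, borderBarFrac = 0.125,
                        seed = 1L) {
  new("SynthConfig",
    nImages = as.integer(nImages), leftFraction = leftFraction,
    canvasSizes = lapply(canvasSizes, as.integer), discOffset = discOffset,
    discRadiusFrac = discRadiusFrac, maculaRadiusFrac = maculaRadiusFrac,
    vesselCount = as.integer(vesselCount),
    poorQualityFraction = poorQualityFraction,
    borderBarFrac = borderBarFrac, seed = as.integer(seed))
}

#' Create a preprocessing configuration
#'
#' @param targetSide Output side in pixels.
#' @param maskRatio Circular-mask radius as a fraction of half the side.
#' @param borderThreshold Dark-border cut-off as a fraction of the peak
#'   line sum.
#' @param method `"ORIGINAL"`, `"CLAHE"`, `"LSACR"` or `"GRAY"`.
#' @param claheClip,claheTiles CLAHE clip limit and tile grid.
#' @param lsacrAlpha,lsacrBeta,lsacrGamma,lsacrSigmaFrac Constants of the
#'   local-space-average-color removal
#'   `clip(alpha*I - beta*G_sigma(I) + gamma)` with
#'   `sigma = side * lsacrSigmaFrac`.
#' @return A [PreprocessConfig-class] object.
#' @examples
#' preprocessConfig(method = "CLAHE")
#' @export
preprocessConfig <- function(targetSide = 299L, maskRatio = 0.95,
                             borderThreshold = 0.02, method = "ORIGINAL",
                             claheClip = 2, claheTiles = c(8L, 8L),
                             lsacrAlpha = 4, lsacrBeta = 4, lsacrGamma = 128,
                             lsacrSigmaFrac = 1 / 30) {
  new("PreprocessConfig",
    targetSide = as.integer(targetSide), maskRatio = maskRatio,
    borderThreshold = borderThreshold, method = method,
    claheClip = claheClip, claheTiles = as.integer(claheTiles),
    lsacrAlpha = lsacrAlpha, lsacrBeta = lsacrBeta, lsacrGamma = lsacrGamma,
    lsacrSigmaFrac = lsacrSigmaFrac)
}

#' Create a training configuration
#'
#' Defaults carry the self-adaptive strategy's constants: `l0 = 0.1`,
#' `k = 5`, `alpha = 0.5`, monitor threshold `0.005`, pool gates
#' accuracy >= 0.95 and loss <= 0.1, reload period 10 epochs; and the
#' augmentation bounds (horizontal shift of 0-10 pixels, rotation bounded
#' by 30 degrees).
#'
#' @param backbone `"tiny"` or `"inception_v3"`.
#' @param inputSide Input side in pixels.
#' @param l0 Initial learning rate.
#' @param momentum SGD momentum.
#' @param l2Lambda L2 regularisation strength.
#' @param batchSize Mini-batch size.
#' @param maxEpochs Training epochs.
#' @param k Alert-period length.
#' @param alpha Learning-rate reduction factor in (0, 1].
#' @param mThreshold Monitor threshold gating the pool.
#' @param accGate,lossGate Pool accuracy and loss gates.
#' @param reloadPeriod Pool-reload period in epochs.
#' @param minLr Learning-rate floor.
#' @param gradClip Global L2 gradient-norm clip on the mean mini-batch
#'   gradient; keeps SGD stable at the large initial learning rate
#'   (0 disables).
#' @param shiftMax,rotMax Augmentation bounds (pixels, degrees).
#' @param seed Integer seed.
#' @return A [TrainConfig-class] object.
#' @examples
#' trainConfig(backbone = "tiny", inputSide = 96L, maxEpochs = 5L)
#' @export
trainConfig <- function(backbone = "tiny", inputSide = 299L, l0 = 0.1,
                        momentum = 0.9, l2Lambda = 1e-4, batchSize = 32L,
                        maxEpochs = 20L, k = 5L, alpha = 0.5,
                        mThreshold = 0.005, accGate = 0.95, lossGate = 0.1,
                        reloadPeriod = 10L, minLr = 1e-5, gradClip = 2,
                        shiftMax = 10, rotMax = 30, seed = 1L) {
  new("TrainConfig",
    backbone = backbone, inputSide = as.integer(inputSide), l0 = l0,
    momentum = momentum, l2Lambda = l2Lambda,
    batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
    k = as.integer(k), alpha = alpha, mThreshold = mThreshold,
    accGate = accGate, lossGate = lossGate,
    reloadPeriod = as.integer(reloadPeriod), minLr = minLr,
    gradClip = gradClip, shiftMax = shiftMax, rotMax = rotMax,
    seed = as.integer(seed))
}

#' Wrap a pixel array as a FundusImage
#'
#' @param pixels `height x width x 3` array with intensities in \[0, 255\].
#' @param meta Optional [ImageMeta-class].
#' @return A [FundusImage-class] object.
#' @examples
#' img <- fundusImage(array(128, c(8, 8, 3)))
#' @export
fundusImage <- function(pixels, meta = NULL) {
  new("FundusImage", pixels = pixels, meta = meta)
}

#' Bundle per-epoch metrics with the derived monitor
#'
#' @param epoch Epoch index (>= 1).
#' @param accuracy Validation accuracy in \[0, 1\].
#' @param loss Validation loss (>= 0).
#' @return An [EpochMetrics-class] object with `monitor = (1 - accuracy) *
#'   loss`.
#' @examples
#' epochMetrics(1L, 0.95, 0.1)
#' @export
epochMetrics <- function(epoch, accuracy, loss) {
  new("EpochMetrics", epoch = as.integer(epoch), accuracy = accuracy,
      loss = loss, monitor = computeMonitor(accuracy, loss))
}
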