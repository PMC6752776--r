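#' Extract the pixel array of a fundus image
#'
#' @param object A [FundusImage-class].
#' @return The `height x width x 3` pixel array.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "FundusImage", function(object) object@pixels)

#' Extract the generator metadata of a fundus image
#'
#' @param object A [FundusImage-class].
#' @return The [ImageMeta-class], or `NULL` for external images.
#' @export
setGeneric("imageMeta", function(object) standardGeneric("imageMeta"))

#' @rdname imageMeta
#' @export
setMethod("imageMeta", "FundusImage", function(object) object@meta)

#' Extract a laterality label
#'
#' @param object An [ImageMeta-class], [FundusImage-class] or
#'   [PredictionResult-class].
#' @return `"left"` or `"right"` (`NA` for an image without metadata).
#' @export
setGeneric("laterality", function(object) standardGeneric("laterality"))

#' @rdname laterality
#' @export
setMethod("laterality", "ImageMeta", function(object) object@laterality)

#' @rdname laterality
#' @export
setMethod("laterality", "FundusImage", function(object) {
  if (is.null(object@meta)) NA_character_ else object@meta@laterality
})

#' @rdname laterality
#' @export
setMethod("laterality", "PredictionResult", function(object) object@label)

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage %d x %d x %d (8-bit RGB)\n", d[1], d[2], d[3]))
  if (!is.null(object@meta)) {
    m <- object@meta
    cat(sprintf("  laterality: %s  disc centre: (%.0f, %.0f)\n",
                m@laterality, m@discCenter[1], m@discCenter[2]))
    cat(sprintf("  obscured: %.2f  disc visible: %.2f  seed: %d\n",
                m@obscuredFraction, m@discVisibleFraction, m@seed))
  }
  invisible(object)
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: P1(left) = %.4f, P2(right) = %.4f -> %s\n",
              object@pLeft, object@pRight, object@label))
  invisible(object)
})

setMethod("show", "FundusClassifier", function(object) {
  np <- sum(vapply(.modelWeights(object), length, integer(1)))
  cat(sprintf("FundusClassifier '%s' (input %d x %d x 3, %d parameters)\n",
              object@backbone, object@inputSide, object@inputSide, np))
  invisible(object)
})

setMethod("show", "ControllerState", function(object) {
  cat(sprintf(
    "ControllerState: lr = %g, alert = %s (count %d), M_best = %g, pool %s\n",
    object@lr, if (object@alertActive) "active" else "off",
    object@alertCount, object@mBest,
    if (length(object@pool)) "1 snapshot" else "empty"))
  invisible(object)
})

setMethod("show", "EvalReport", function(object) {
  cm <- object@confusion
  cat("EvalReport (left eye positive)\n")
  cat(sprintf("  confusion: tp=%d fn=%d fp=%d tn=%d\n",
              cm["tp"], cm["fn"], cm["fp"], cm["tn"]))
  cat(sprintf("  accuracy    %.4f (95%% CI %.4f-%.4f)\n",
              object@accuracy, object@accuracyCI[1], object@accuracyCI[2]))
  cat(sprintf("  sensitivity %.4f (95%% CI %.4f-%.4f)\n",
              object@sensitivity, object@sensitivityCI[1],
              object@sensitivityCI[2]))
  cat(sprintf("  specificity %.4f (95%% CI %.4f-%.4f)\n",
              object@specificity, object@specificityCI[1],
              object@specificityCI[2]))
  cat(sprintf("  AUC         %.4f (95%% CI %.4f-%.4f)\n",
              object@auc, object@aucCI[1], object@aucCI[2]))
  invisible(object)
})
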