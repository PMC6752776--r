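# Class activation maps for the GAP-headed classifier.
#
# With global average pooling feeding a single affine layer, the evidence
# for a class at location (x, y) is the weighted sum of the last
# convolutional layer's feature maps, weighted by that class's affine
# weights; the affine bias is a constant shift and is removed by the
# min-max normalisation.

#' Weighted sum of feature maps
#'
#' The computational core of the class activation map:
#' `R(x, y) = sum_k w_k * f_k(x, y)`.
#'
#' @param features `H x W x K` array of feature maps.
#' @param weights Numeric vector of length `K`.
#' @return The raw `H x W` activation matrix (not normalised).
#' @export
camFromFeatures <- function(features, weights) {
  d <- dim(features)
  .stopIf(length(d) != 3L || d[3] != length(weights),
          "features must be H x W x K with one weight per map")
  matrix(matrix(features, d[1] * d[2], d[3]) %*% weights, d[1], d[2])
}

.normalizeHeat <- function(raw) {
  rng <- range(raw)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, nrow(raw), ncol(raw)))
  (raw - rng[1]) / (rng[2] - rng[1])
}

#' Compute a class activation map
#'
#' Forms the class-weighted sum of the feature maps entering the GAP head,
#' upsamples it bilinearly to the model's input side, and min-max
#' normalises to \[0, 1\] (a constant raw map yields all zeros). Negative
#' raw values are retained before normalisation.
#'
#' @param model A GAP-headed [FundusClassifier-class].
#' @param image A [FundusImage-class] at the model's input side.
#' @param targetClass `"left"`, `"right"`, or `"predicted"`.
#' @return A [HeatMap-class] at the model's input resolution.
#' @export
computeCAM <- function(model, image,
                       targetClass = c("left", "right", "predicted")) {
  stopifnot(is(model, "FundusClassifier"), is(image, "FundusImage"))
  targetClass <- match.arg(targetClass)
  types <- vapply(model@layers, `[[`, character(1), "type")
  gapIdx <- which(types == "gap")
  .stopIf(length(gapIdx) != 1L || gapIdx == length(types) ||
            types[gapIdx + 1L] != "dense",
          "unsupported architecture: model must end in GAP + affine head")
  fw <- .netForward(model@layers, .inputScale(image@pixels))
  p <- .softmax(fw$y)
  if (targetClass == "predicted")
    targetClass <- if (p[1] >= p[2]) .LEFT else .RIGHT
  features <- fw$caches[[gapIdx]]$x
  w <- model@layers[[gapIdx + 1L]]$W[, if (targetClass == .LEFT) 1L else 2L]
  raw <- camFromFeatures(features, w)
  side <- model@inputSide
  up <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(raw)),
                                             side, side)))
  new("HeatMap", values = .normalizeHeat(up), targetClass = targetClass)
}

.jet <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  list(r = r, g = g, b = b)
}

#' Render a heat-map overlay
#'
#' Pseudo-colour (jet-style ramp) blend of a class activation map over the
#' photograph: `out = (1 - opacity) * image + opacity * colormap(heat)`,
#' clipped to 8 bits.
#'
#' @param heat A [HeatMap-class].
#' @param image A [FundusImage-class] of matching dimensions.
#' @param opacity Blend weight in \[0, 1\].
#' @return The blended [FundusImage-class].
#' @export
overlayCAM <- function(heat, image, opacity = 0.4) {
  stopifnot(is(heat, "HeatMap"), is(image, "FundusImage"))
  d <- dim(image@pixels)
  .stopIf(!all(dim(heat@values) == d[1:2]),
          "heat map and image dimensions must match")
  col <- .jet(heat@values)
  px <- image@pixels
  out <- array(0, d)
  out[, , 1] <- (1 - opacity) * px[, , 1] + opacity * 255 * col$r
  out[, , 2] <- (1 - opacity) * px[, , 2] + opacity * 255 * col$g
  out[, , 3] <- (1 - opacity) * px[, , 3] + opacity * 255 * col$b
  fundusImage(.clip8(round(out)), image@meta)
}

#' Centroid of the activated region
#'
#' Intensity-weighted centroid over the cells whose activation reaches the
#' threshold; used to quantify where the classifier looks (for laterality,
#' the optic disc and its surroundings).
#'
#' @param heat A [HeatMap-class].
#' @param threshold Activation threshold in (0, 1).
#' @return Numeric `(x, y)` in 0-based cell coordinates, or `NULL` when no
#'   cell reaches the threshold.
#' @export
roiCentroid <- function(heat, threshold = 0.5) {
  stopifnot(is(heat, "HeatMap"))
  .stopIf(threshold <= 0 || threshold >= 1,
          "threshold must lie in (0, 1)")
  v <- heat@values
  sel <- which(v >= threshold, arr.ind = TRUE)
  if (!nrow(sel)) return(NULL)
  wts <- v[sel]
  c(x = sum((sel[, 2] - 1) * wts) / sum(wts),
    y = sum((sel[, 1] - 1) * wts) / sum(wts))
}
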