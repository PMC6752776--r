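# Size normalisation and enhancement of fundus photographs.
#
# The normalisation chain mirrors how raw camera output is reduced to the
# classifier's input: cut off the black border by pixel summation, centre-crop
# to a square, rescale (bilinear) to the target side, then zero everything
# outside a circle whose radius is 95% of the fundus radius to remove the
# overexposed rim. Generator metadata (disc centre, canvas size) is carried
# through every step so ground truth stays aligned with the pixels.

.updateMeta <- function(meta, fx, fy, w, h) {
  if (is.null(meta)) return(NULL)
  meta@discCenter <- c(fx(meta@discCenter[1]), fy(meta@discCenter[2]))
  meta@canvasSize <- c(as.integer(w), as.integer(h))
  meta
}

#' Cut off the dark border of a fundus photograph
#'
#' Scores each row and column by the sum of its per-pixel maximum channel
#' intensity and keeps the span between the first and last line whose sum
#' exceeds `borderThreshold` times the peak line sum. Content pixels are
#' preserved bit-exactly; an image with no dark border is returned unchanged.
#'
#' @param image A [FundusImage-class].
#' @param borderThreshold Fraction of the peak line sum (default 0.02).
#' @return The cropped [FundusImage-class].
#' @export
cropDarkBorder <- function(image, borderThreshold = 0.02) {
  stopifnot(is(image, "FundusImage"))
  px <- image@pixels
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  rs <- rowSums(mx)
  cs <- colSums(mx)
  keepR <- which(rs > borderThreshold * max(rs))
  keepC <- which(cs > borderThreshold * max(cs))
  .stopIf(max(mx) <= 0 || !length(keepR) || !length(keepC),
          "degenerate input: image is entirely dark")
  r0 <- min(keepR); r1 <- max(keepR)
  c0 <- min(keepC); c1 <- max(keepC)
  out <- px[r0:r1, c0:c1, , drop = FALSE]
  meta <- .updateMeta(image@meta, function(x) x - (c0 - 1),
                      function(y) y - (r0 - 1), ncol(out), nrow(out))
  fundusImage(out, meta)
}

#' Centre-crop a fundus photograph to a square
#'
#' The longer dimension is cropped to equal the shorter; when the difference
#' is odd the extra pixel is removed from the trailing (bottom/right) side.
#'
#' @param image A [FundusImage-class].
#' @return A square [FundusImage-class].
#' @export
toSquare <- function(image) {
  stopifnot(is(image, "FundusImage"))
  px <- image@pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  s <- min(h, w)
  offC <- floor((w - s) / 2)
  offR <- floor((h - s) / 2)
  out <- px[(offR + 1):(offR + s), (offC + 1):(offC + s), , drop = FALSE]
  meta <- .updateMeta(image@meta, function(x) x - offC, function(y) y - offR,
                      s, s)
  fundusImage(out, meta)
}

#' Rescale a square fundus photograph
#'
#' Bilinear resampling to `targetSide x targetSide x 3`
#' (half-pixel-centred coordinate convention), re-quantised to 8 bits.
#'
#' @param image A square [FundusImage-class].
#' @param targetSide Output side in pixels (default 299).
#' @return The rescaled [FundusImage-class].
#' @export
resizeFundus <- function(image, targetSide = 299L) {
  stopifnot(is(image, "FundusImage"))
  d <- dim(image@pixels)
  .stopIf(d[1] != d[2], "resizeFundus requires a square input")
  targetSide <- as.integer(targetSide)
  if (d[1] == targetSide) return(image)
  out <- .fromEB(EBImage::resize(.asEB(image@pixels), targetSide, targetSide))
  f <- targetSide / d[1]
  meta <- .updateMeta(image@meta, function(x) (x + 0.5) * f - 0.5,
                      function(y) (y + 0.5) * f - 0.5,
                      targetSide, targetSide)
  fundusImage(.clip8(round(out)), meta)
}

#' Mask the overexposed fundus rim
#'
#' Zeroes every pixel farther than `maskRatio` times half the side from the
#' image centre (the fundus radius is taken as half the post-crop square
#' side); interior pixels are unchanged.
#'
#' @param image A square [FundusImage-class].
#' @param maskRatio Mask radius as a fraction of half the side (default
#'   0.95).
#' @return The masked [FundusImage-class].
#' @export
circularMask <- function(image, maskRatio = 0.95) {
  stopifnot(is(image, "FundusImage"))
  d <- dim(image@pixels)
  .stopIf(d[1] != d[2], "circularMask requires a square input")
  s <- d[1]
  ctr <- (s - 1) / 2
  dist <- sqrt(outer((0:(s - 1) - ctr)^2, (0:(s - 1) - ctr)^2, "+"))
  outside <- dist > maskRatio * s / 2
  px <- image@pixels
  for (ch in 1:3) px[, , ch][outside] <- 0
  fundusImage(px, image@meta)
}

#' Normalise a fundus photograph to classifier input geometry
#'
#' Composition of [cropDarkBorder()], [toSquare()], [resizeFundus()] and
#' [circularMask()], in that order.
#'
#' @param image A [FundusImage-class] at native camera size.
#' @param config A [PreprocessConfig-class].
#' @return A `targetSide x targetSide x 3` [FundusImage-class] with the rim
#'   masked to zero.
#' @examples
#' img <- generateFundusImage(1L, "left", c(320L, 240L))
#' dim(pixels(normalizeFundus(img, preprocessConfig(targetSide = 96L))))
#' @export
normalizeFundus <- function(image, config = preprocessConfig()) {
  img <- cropDarkBorder(image, config@borderThreshold)
  img <- toSquare(img)
  img <- resizeFundus(img, config@targetSide)
  circularMask(img, config@maskRatio)
}

.rec601 <- c(0.299, 0.587, 0.114)

.enhanceGray <- function(px) {
  luma <- px[, , 1] * .rec601[1] + px[, , 2] * .rec601[2] +
    px[, , 3] * .rec601[3]
  luma <- .clip8(round(luma))
  array(rep(luma, 3), dim(px))
}

.enhanceLSACR <- function(px, cfg) {
  side <- max(dim(px)[1:2])
  sigma <- side * cfg@lsacrSigmaFrac
  bg <- .fromEB(EBImage::gblur(.asEB(px), sigma = sigma))
  .clip8(round(cfg@lsacrAlpha * px - cfg@lsacrBeta * bg + cfg@lsacrGamma))
}

.enhanceCLAHE <- function(px, cfg) {
  h <- dim(px)[1]; w <- dim(px)[2]
  rgb <- matrix(px, ncol = 3) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1] / 100, h, w)
  nx <- cfg@claheTiles[1]; ny <- cfg@claheTiles[2]
  # EBImage's CLAHE needs sides divisible by the tile grid; resample to the
  # aligned grid and back when they are not (keeps mirror equivariance).
  wa <- nx * ceiling(w / nx); ha <- ny * ceiling(h / ny)
  Limg <- EBImage::Image(t(L))
  aligned <- (wa == w && ha == h)
  if (!aligned) Limg <- EBImage::resize(Limg, wa, ha)
  Leq <- EBImage::clahe(Limg, nx = nx, ny = ny, limit = cfg@claheClip)
  if (!aligned) Leq <- EBImage::resize(Leq, w, h)
  lab[, 1] <- pmin(pmax(as.numeric(t(as.matrix(Leq))), 0), 1) * 100
  out <- grDevices::convertColor(lab, from = "Lab", to = "sRGB") * 255
  .clip8(round(array(out, dim(px))))
}

#' Enhance a normalised fundus photograph
#'
#' The four enhancement methods compared for classifier training:
#' \describe{
#'   \item{ORIGINAL}{input returned unchanged;}
#'   \item{CLAHE}{contrast-limited adaptive histogram equalisation applied
#'     to the CIELAB luminance channel, recombined with the original
#'     chroma;}
#'   \item{LSACR}{local-space-average-color removal,
#'     `clip(alpha*I - beta*G_sigma(I) + gamma, 0, 255)` per channel with
#'     `sigma = side * lsacrSigmaFrac`;}
#'   \item{GRAY}{Rec.601 luma (`0.299 R + 0.587 G + 0.114 B`) replicated to
#'     all three channels.}
#' }
#'
#' @param image A normalised 3-channel [FundusImage-class].
#' @param config A [PreprocessConfig-class]; `config@method` selects the
#'   method.
#' @return A [FundusImage-class] of the same shape.
#' @examples
#' img <- generateFundusImage(1L, "left", c(320L, 240L))
#' nrm <- normalizeFundus(img, preprocessConfig(targetSide = 96L))
#' gry <- enhanceFundus(nrm, preprocessConfig(targetSide = 96L,
#'                                            method = "GRAY"))
#' @export
enhanceFundus <- function(image, config = preprocessConfig()) {
  stopifnot(is(image, "FundusImage"))
  px <- image@pixels
  out <- switch(config@method,
    ORIGINAL = px,
    GRAY = .enhanceGray(px),
    LSACR = .enhanceLSACR(px, config),
    CLAHE = .enhanceCLAHE(px, config),
    stop("unknown enhancement method: ", config@method, call. = FALSE)
  )
  fundusImage(out, image@meta)
}
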