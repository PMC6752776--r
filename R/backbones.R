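# Network topologies. Both end in global average pooling followed by a
# single affine layer to 2 logits, so class activation maps are defined.

.tinyLayers <- function() {
  list(
    .convLayer(3L, 3L, 3L, 8L, ph = 1L), .reluLayer(), .poolLayer(2L),
    .convLayer(3L, 3L, 8L, 16L, ph = 1L), .reluLayer(), .poolLayer(2L),
    .convLayer(3L, 3L, 16L, 32L, ph = 1L), .reluLayer(), .poolLayer(2L),
    .convLayer(3L, 3L, 32L, 32L, ph = 1L), .reluLayer(), .poolLayer(2L),
    .gapLayer(), .denseLayer(32L, 2L)
  )
}

.cr <- function(kh, kw, cin, cout, sh = 1L, ph = 0L, pw = ph) {
  list(.convLayer(kh, kw, cin, cout, sh = sh, ph = ph, pw = pw),
       .reluLayer())
}

.inceptionA <- function(cin, poolf) {
  .branchLayer(list(
    .cr(1L, 1L, cin, 64L),
    c(.cr(1L, 1L, cin, 48L), .cr(5L, 5L, 48L, 64L, ph = 2L)),
    c(.cr(1L, 1L, cin, 64L), .cr(3L, 3L, 64L, 96L, ph = 1L),
      .cr(3L, 3L, 96L, 96L, ph = 1L)),
    c(list(.poolLayer(3L, sh = 1L, ph = 1L, mode = "avg")),
      .cr(1L, 1L, cin, poolf))
  ))
}

.inceptionB <- function(cin) {
  .branchLayer(list(
    .cr(3L, 3L, cin, 384L, sh = 2L),
    c(.cr(1L, 1L, cin, 64L), .cr(3L, 3L, 64L, 96L, ph = 1L),
      .cr(3L, 3L, 96L, 96L, sh = 2L)),
    list(.poolLayer(3L, sh = 2L, mode = "max"))
  ))
}

.inceptionC <- function(cin, c7) {
  .branchLayer(list(
    .cr(1L, 1L, cin, 192L),
    c(.cr(1L, 1L, cin, c7), .cr(1L, 7L, c7, c7, ph = 0L, pw = 3L),
      .cr(7L, 1L, c7, 192L, ph = 3L, pw = 0L)),
    c(.cr(1L, 1L, cin, c7), .cr(7L, 1L, c7, c7, ph = 3L, pw = 0L),
      .cr(1L, 7L, c7, c7, ph = 0L, pw = 3L),
      .cr(7L, 1L, c7, c7, ph = 3L, pw = 0L),
      .cr(1L, 7L, c7, 192L, ph = 0L, pw = 3L)),
    c(list(.poolLayer(3L, sh = 1L, ph = 1L, mode = "avg")),
      .cr(1L, 1L, cin, 192L))
  ))
}

.inceptionD <- function(cin) {
  .branchLayer(list(
    c(.cr(1L, 1L, cin, 192L), .cr(3L, 3L, 192L, 320L, sh = 2L)),
    c(.cr(1L, 1L, cin, 192L), .cr(1L, 7L, 192L, 192L, ph = 0L, pw = 3L),
      .cr(7L, 1L, 192L, 192L, ph = 3L, pw = 0L),
      .cr(3L, 3L, 192L, 192L, sh = 2L)),
    list(.poolLayer(3L, sh = 2L, mode = "max"))
  ))
}

.inceptionE <- function(cin) {
  .branchLayer(list(
    .cr(1L, 1L, cin, 320L),
    c(.cr(1L, 1L, cin, 384L),
      list(.branchLayer(list(
        .cr(1L, 3L, 384L, 384L, ph = 0L, pw = 1L),
        .cr(3L, 1L, 384L, 384L, ph = 1L, pw = 0L)
      )))),
    c(.cr(1L, 1L, cin, 448L), .cr(3L, 3L, 448L, 384L, ph = 1L),
      list(.branchLayer(list(
        .cr(1L, 3L, 384L, 384L, ph = 0L, pw = 1L),
        .cr(3L, 1L, 384L, 384L, ph = 1L, pw = 0L)
      )))),
    c(list(.poolLayer(3L, sh = 1L, ph = 1L, mode = "avg")),
      .cr(1L, 1L, cin, 192L))
  ))
}

# Inception-V3 style topology with 11 inception modules (3 x A, 1 x B,
# 4 x C, 1 x D, 2 x E) over the standard stem, without batch
# normalisation, ending in GAP and a 2-way affine head.
.inceptionV3Layers <- function() {
  c(
    .cr(3L, 3L, 3L, 32L, sh = 2L),
    .cr(3L, 3L, 32L, 32L),
    .cr(3L, 3L, 32L, 64L, ph = 1L),
    list(.poolLayer(3L, sh = 2L, mode = "max")),
    .cr(1L, 1L, 64L, 80L),
    .cr(3L, 3L, 80L, 192L),
    list(.poolLayer(3L, sh = 2L, mode = "max")),
    list(
      .inceptionA(192L, 32L),
      .inceptionA(256L, 64L),
      .inceptionA(288L, 64L),
      .inceptionB(288L),
      .inceptionC(768L, 128L),
      .inceptionC(768L, 160L),
      .inceptionC(768L, 160L),
      .inceptionC(768L, 192L),
      .inceptionD(768L),
      .inceptionE(1280L),
      .inceptionE(2048L),
      .gapLayer(),
      .denseLayer(2048L, 2L)
    )
  )
}

#' Build a laterality classifier
#'
#' Constructs a trainable GAP-headed convolutional network emitting the
#' probability vector `(P1, P2)`. `"inception_v3"` follows the Inception-V3
#' topology (11 inception modules) at its native 299-pixel input;
#' `"tiny"` is a 4-block conv/pool stack for desk-scale runs. Weights are
#' He-initialised from the current RNG stream.
#'
#' @param backbone `"tiny"` or `"inception_v3"`.
#' @param inputSide Input side in pixels (must be 299 for
#'   `"inception_v3"`; any multiple of 16 at least 32 for `"tiny"`).
#' @return A [FundusClassifier-class].
#' @examples
#' set.seed(1)
#' model <- buildClassifier("tiny", 96L)
#' @export
buildClassifier <- function(backbone = c("tiny", "inception_v3"),
                            inputSide = 299L) {
  backbone <- match.arg(backbone)
  inputSide <- as.integer(inputSide)
  if (backbone == "tiny") {
    .stopIf(inputSide < 32L || inputSide %% 16L != 0L,
            "tiny backbone needs an input side >= 32 divisible by 16")
    layers <- .tinyLayers()
  } else {
    .stopIf(inputSide != 299L, "inception_v3 operates on 299 x 299 inputs")
    layers <- .inceptionV3Layers()
  }
  new("FundusClassifier", backbone = backbone, inputSide = inputSide,
      layers = layers)
}
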