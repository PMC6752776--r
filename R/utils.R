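# Internal helpers: EBImage conversion, seeded evaluation, 8-bit clipping.

.clip8 <- function(x) pmin(pmax(x, 0), 255)

# FundusImage arrays are [row, col, channel]; EBImage images are [x, y, c].
.asEB <- function(px) {
  EBImage::Image(aperm(px, c(2, 1, 3)) / 255, colormode = "Color")
}

.fromEB <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  aperm(a, c(2, 1, 3)) * 255
}

# Evaluate expr under a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopIf <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
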