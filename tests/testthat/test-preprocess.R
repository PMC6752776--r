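# Size normalisation and the four enhancement methods.

test_that("dark-border cropping recovers the known content box", {
  # fixture with exactly 320-pixel black bars on each side of white content
  px <- array(0, c(1920, 2560, 3))
  px[, 321:2240, ] <- 255
  out <- cropDarkBorder(fundusImage(px))
  expect_equal(dim(pixels(out)), c(1920L, 1920L, 3L))
  # oracle: direct bounding-box scan of non-dark columns
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  expect_equal(range(which(colSums(mx) > 0.02 * max(colSums(mx)))),
               c(321L, 2240L))
  # content preserved bit-exactly
  expect_identical(pixels(out), px[, 321:2240, , drop = FALSE])
})

test_that("cropping is idempotent without a border and rejects darkness", {
  px <- array(runif(48 * 48 * 3, 50, 200), c(48, 48, 3))
  img <- fundusImage(px)
  expect_identical(pixels(cropDarkBorder(img)), px)
  expect_error(cropDarkBorder(fundusImage(array(0, c(8, 8, 3)))),
               "entirely dark")
})

test_that("square cropping removes the centre-split excess", {
  mk <- function(h, w) fundusImage(array(seq_len(h * w * 3) %% 256,
                                         c(h, w, 3)))
  expect_equal(dim(pixels(toSquare(mk(1920, 1920)))), c(1920L, 1920L, 3L))
  out <- toSquare(mk(1920, 1930))
  expect_equal(dim(pixels(out)), c(1920L, 1920L, 3L))
  expect_identical(pixels(out), pixels(mk(1920, 1930))[, 6:1925, ])
  # odd difference: extra pixel comes off the trailing side
  out2 <- toSquare(mk(80, 85))
  expect_identical(pixels(out2), pixels(mk(80, 85))[, 3:82, ])
  expect_equal(dim(pixels(toSquare(mk(80, 100)))), c(80L, 80L, 3L))
})

test_that("resizing is bilinear to the target side and needs square input", {
  img <- generateFundusImage(1L, "left", c(320L, 240L))
  sq <- toSquare(cropDarkBorder(img))
  expect_equal(dim(pixels(resizeFundus(sq, 96L))), c(96L, 96L, 3L))
  expect_error(resizeFundus(img, 96L), "square")
  const <- fundusImage(array(137, c(50, 50, 3)))
  expect_true(all(pixels(resizeFundus(const, 299L)) == 137))
  expect_identical(resizeFundus(const, 50L), const)
})

test_that("the circular mask zeroes exactly the out-of-radius pixels", {
  white <- fundusImage(array(255, c(299, 299, 3)))
  out <- pixels(circularMask(white, 0.95))
  expect_equal(out[1, 1, ], c(0, 0, 0))
  expect_equal(out[150, 150, ], c(255, 255, 255))
  s <- 299
  ctr <- (s - 1) / 2
  dist <- sqrt(outer((0:(s - 1) - ctr)^2, (0:(s - 1) - ctr)^2, "+"))
  mx <- pmax(out[, , 1], out[, , 2], out[, , 3])
  expect_true(all(mx[dist > 0.95 * s / 2] == 0))
  expect_true(all(mx[dist <= 0.95 * s / 2] == 255))
  # surviving radius ratio within one pixel of the mask ratio
  expect_lt(abs(max(dist[mx > 0]) / (s / 2) - 0.95), 1 / (s / 2))
  # ratio 1: only pixels beyond the inscribed circle are zeroed
  full <- pixels(circularMask(white, 1))
  expect_true(all(pmax(full[, , 1], full[, , 2], full[, , 3])
                  [dist <= s / 2] == 255))
  expect_error(circularMask(fundusImage(array(1, c(4, 6, 3)))), "square")
})

test_that("normalisation produces masked classifier input at any size", {
  for (cs in list(c(320L, 240L), c(410L, 310L))) {
    img <- generateFundusImage(2L, "right", cs)
    out <- normalizeFundus(img, preprocessConfig(targetSide = 96L))
    px <- pixels(out)
    expect_equal(dim(px), c(96L, 96L, 3L))
    expect_equal(px[1, 1, ], c(0, 0, 0))   # corners masked
    ctr <- (96 - 1) / 2
    dist <- sqrt(outer((0:95 - ctr)^2, (0:95 - ctr)^2, "+"))
    mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
    expect_true(all(mx[dist > 0.95 * 48] == 0))
  }
})

test_that("component steps are idempotent at the target geometry", {
  img <- generateFundusImage(4L, "left", c(320L, 240L))
  nrm <- normalizeFundus(img, preprocessConfig(targetSide = 96L))
  expect_identical(pixels(circularMask(nrm, 0.95)), pixels(nrm))
  expect_identical(pixels(toSquare(nrm)), pixels(nrm))
  expect_identical(pixels(resizeFundus(nrm, 96L)), pixels(nrm))
})

test_that("GRAY collapses to replicated Rec.601 luma", {
  red <- fundusImage(array(rep(c(255, 0, 0), each = 16), c(4, 4, 3)))
  out <- pixels(enhanceFundus(red, preprocessConfig(method = "GRAY")))
  expect_true(all(out == 76))                       # round(0.299 * 255)
  white <- fundusImage(array(255, c(4, 4, 3)))
  expect_true(all(pixels(enhanceFundus(
    white, preprocessConfig(method = "GRAY"))) == 255))
  img <- generateFundusImage(1L, "left", c(160L, 120L))
  g <- pixels(enhanceFundus(img, preprocessConfig(method = "GRAY")))
  expect_identical(g[, , 1], g[, , 2])
  expect_identical(g[, , 1], g[, , 3])
})

test_that("LSACR reduces a constant image to the gamma offset", {
  const <- fundusImage(array(100, c(64, 64, 3)))
  out <- pixels(enhanceFundus(const, preprocessConfig(targetSide = 64L,
                                                      method = "LSACR")))
  # alpha = beta = 4 cancels the signal; gamma = 128 remains (interior,
  # away from any blur boundary)
  expect_true(all(out[20:44, 20:44, ] == 128))
})

test_that("CLAHE maps a constant image to a constant image", {
  const <- fundusImage(array(100, c(64, 64, 3)))
  out <- pixels(enhanceFundus(const, preprocessConfig(targetSide = 64L,
                                                      method = "CLAHE")))
  expect_equal(length(unique(as.vector(out))), 1L)
})

test_that("enhancement commutes with horizontal mirroring", {
  img <- generateFundusImage(3L, "left", c(320L, 240L))
  nrm <- normalizeFundus(img, preprocessConfig(targetSide = 96L))
  for (m in c("ORIGINAL", "GRAY", "LSACR")) {
    cfg <- preprocessConfig(targetSide = 96L, method = m)
    expect_identical(pixels(enhanceFundus(mirrorImage(nrm), cfg)),
                     pixels(mirrorImage(enhanceFundus(nrm, cfg))))
  }
  cfg <- preprocessConfig(targetSide = 96L, method = "CLAHE")
  a <- pixels(enhanceFundus(mirrorImage(nrm), cfg))
  b <- pixels(mirrorImage(enhanceFundus(nrm, cfg)))
  expect_gte(mean(abs(a - b) <= 2), 0.99)
})

test_that("unknown enhancement methods are rejected", {
  expect_error(preprocessConfig(method = "SHARPEN"), "unknown")
  img <- fundusImage(array(1, c(8, 8, 3)))
  cfg <- preprocessConfig()
  slot(cfg, "method", check = FALSE) <- "BOGUS"
  expect_error(enhanceFundus(img, cfg), "unknown")
})
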