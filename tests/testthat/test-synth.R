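# Synthetic fundus generator: geometry, determinism, quality model.

test_that("disc placement follows the laterality convention", {
  for (seed in c(0L, 1L, 7L)) {
    for (lat in c("left", "right")) {
      img <- generateFundusImage(seed, lat, c(160L, 120L))
      m <- imageMeta(img)
      mid <- (m@canvasSize[1] - 1) / 2
      if (lat == "left") expect_lt(m@discCenter[1], mid)
      else expect_gt(m@discCenter[1], mid)
    }
  }
})

test_that("generation is deterministic and rejects bad canvases", {
  a <- generateFundusImage(5L, "left", c(160L, 120L))
  b <- generateFundusImage(5L, "left", c(160L, 120L))
  expect_identical(pixels(a), pixels(b))
  expect_error(generateFundusImage(1L, "left", c(0L, 120L)),
               "positive dimensions")
})

test_that("right-eye images are exact mirrors of the left-eye rendering", {
  for (seed in c(2L, 9L)) {
    left <- generateFundusImage(seed, "left", c(192L, 144L))
    right <- generateFundusImage(seed, "right", c(192L, 144L))
    expect_identical(pixels(mirrorImage(left)), pixels(right))
    expect_identical(imageMeta(mirrorImage(left))@discCenter,
                     imageMeta(right)@discCenter)
  }
})

test_that("mirroring is an involution and swaps the label", {
  img <- generateFundusImage(3L, "left", c(160L, 120L))
  expect_identical(pixels(mirrorImage(mirrorImage(img))), pixels(img))
  expect_identical(laterality(mirrorImage(img)), "right")
  # a column-symmetric image is unchanged
  gray <- fundusImage(array(128, c(8, 8, 3)))
  expect_identical(pixels(mirrorImage(gray)), pixels(gray))
})

test_that("poor-quality rendering triggers the exclusion rule", {
  for (seed in 1:6) {
    img <- generateFundusImage(seed, "right", c(160L, 120L),
                               quality = "poor")
    m <- imageMeta(img)
    expect_true(m@obscuredFraction >= 0.5 || m@discVisibleFraction < 1)
    expect_true(isPoorQuality(m))
  }
})

test_that("the exclusion rule matches the stated thresholds", {
  mk <- function(obsc, vis) {
    new("ImageMeta", laterality = "left", obscuredFraction = obsc,
        discVisibleFraction = vis, canvasSize = c(10L, 10L),
        discCenter = c(2, 5), seed = 1L)
  }
  expect_true(isPoorQuality(mk(0.6, 1.0)))    # half the area obscured
  expect_false(isPoorQuality(mk(0.1, 1.0)))   # neither condition met
  expect_true(isPoorQuality(mk(0.0, 0.4)))    # disc only partly visible
  expect_true(isPoorQuality(mk(0.5, 1.0)))    # boundary: >= 50%
  bad <- mk(0.1, 1.0)
  bad@obscuredFraction <- NA_real_
  expect_error(isPoorQuality(bad), "populated")
})

test_that("laterality convention holds across many generated images", {
  cfg <- synthConfig(nImages = 1000L, canvasSizes = list(c(64L, 48L)),
                     seed = 5L)
  ds <- generateFundusSet(cfg)
  mids <- (ds$manifest$width - 1) / 2
  xs <- vapply(ds$images, function(im) imageMeta(im)@discCenter[1],
               numeric(1))
  isLeft <- ds$manifest$laterality == "left"
  expect_true(all(xs[isLeft] < mids[isLeft]))
  expect_true(all(xs[!isLeft] > mids[!isLeft]))
  expect_equal(sum(isLeft), 500L)
})

test_that("dataset plans honour class balance and the poor fraction", {
  cfg <- synthConfig(nImages = 10L, leftFraction = 0.5,
                     canvasSizes = list(c(64L, 48L)), seed = 2L)
  ds <- generateFundusSet(cfg)
  expect_equal(sum(ds$manifest$laterality == "left"), 5L)
  cfg2 <- synthConfig(nImages = 100L, poorQualityFraction = 0.2,
                      canvasSizes = list(c(64L, 48L)), seed = 3L)
  ds2 <- generateFundusSet(cfg2)
  poor <- mapply(function(o, v) o >= 0.5 || v < 1,
                 ds2$manifest$obscured_fraction,
                 ds2$manifest$disc_visible_fraction)
  expect_equal(sum(poor), 20L)
  # filter arithmetic: excluding poor images removes exactly that fraction
  expect_equal(mean(poor), cfg2@poorQualityFraction)
})

test_that("written datasets are byte-reproducible from the config", {
  cfg <- synthConfig(nImages = 4L, canvasSizes = list(c(96L, 72L)),
                     seed = 7L)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  m1 <- generateFundusDataset(cfg, d1)
  m2 <- generateFundusDataset(cfg, d2)
  expect_identical(m1, m2)
  for (f in m1$filename) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # manifest round-trips and images reload with matching labels
  man <- readManifest(d1)
  expect_equal(man$filename, m1$filename)
  imgs <- loadFundusDataset(d1, man)
  expect_identical(vapply(imgs, laterality, character(1)),
                   man$laterality)
})
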