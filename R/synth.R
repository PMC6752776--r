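# Synthetic fundus photograph generator.
#
# Images carry the geometric cues a laterality classifier exploits: a bright
# circular fundus region inside black side bars, an optic disc displaced
# horizontally toward the laterality side (mirror-symmetric between eyes), a
# darker central macula, vessel arcs emanating from the disc, and an
# overexposed rim annulus. Right-eye images are exact mirror images of the
# left-eye rendering at the same seed, so left and right form perfect mirror
# populations.

# Render the canonical LEFT-eye image; returns pixels plus ground truth.
.renderLeftFundus <- function(seed, w, h, quality, cfg) {
  .withSeed(seed, {
    cx <- (w - 1) / 2
    cy <- (h - 1) / 2
    inner <- w * (1 - 2 * cfg@borderBarFrac)
    R <- min(h, inner) / 2
    X <- matrix(0:(w - 1), h, w, byrow = TRUE)
    Y <- matrix(0:(h - 1), h, w)
    dist <- sqrt((X - cx)^2 + (Y - cy)^2)
    fundus <- dist <= R

    r <- matrix(200, h, w)
    g <- matrix(90, h, w)
    b <- matrix(40, h, w)

    # darker central macula (Gaussian falloff)
    mr <- cfg@maculaRadiusFrac * R
    shade <- 1 - 0.45 * exp(-(dist / mr)^2)
    r <- r * shade; g <- g * shade; b <- b * shade

    # optic disc: bright ellipse centred 0.55 R to the left of the macula
    dcx <- cx - cfg@discOffset * R
    dcy <- cy
    da <- cfg@discRadiusFrac * R      # vertical semi-axis
    db <- 0.85 * da                   # horizontal semi-axis
    e <- sqrt(((X - dcx) / db)^2 + ((Y - dcy) / da)^2)
    wd <- pmin(1, pmax(0, (1.15 - e) / 0.3))
    discMask <- e <= 1
    r <- r * (1 - wd) + 238 * wd
    g <- g * (1 - wd) + 206 * wd
    b <- b * (1 - wd) + 150 * wd

    # vessel arcs: quadratic Bezier curves from the disc toward the rim
    lw <- max(1L, round(R / 250))
    npts <- max(64L, as.integer(round(2.5 * R)))
    t <- seq(0, 1, length.out = npts)
    vmask <- matrix(FALSE, h, w)
    off <- expand.grid(dy = -lw:lw, dx = -lw:lw)
    for (v in seq_len(cfg@vesselCount)) {
      th <- 2 * pi * (v - 0.5) / cfg@vesselCount + runif(1, -0.2, 0.2)
      p2 <- c(cx + 0.85 * R * cos(th), cy + 0.85 * R * sin(th))
      mid <- c((dcx + p2[1]) / 2, (dcy + p2[2]) / 2)
      perp <- c(-(p2[2] - dcy), p2[1] - dcx)
      perp <- perp / sqrt(sum(perp^2) + 1e-9)
      p1 <- mid + perp * runif(1, -0.25, 0.25) * R
      bx <- (1 - t)^2 * dcx + 2 * t * (1 - t) * p1[1] + t^2 * p2[1]
      by <- (1 - t)^2 * dcy + 2 * t * (1 - t) * p1[2] + t^2 * p2[2]
      xi <- rep(round(bx), each = nrow(off)) + off$dx
      yi <- rep(round(by), each = nrow(off)) + off$dy
      ok <- xi >= 0 & xi < w & yi >= 0 & yi < h
      vmask[cbind(yi[ok] + 1, xi[ok] + 1)] <- TRUE
    }
    vmask <- vmask & fundus
    r[vmask] <- r[vmask] * 0.45 + 120 * 0.55
    g[vmask] <- g[vmask] * 0.45 + 30 * 0.55
    b[vmask] <- b[vmask] * 0.45 + 25 * 0.55

    # pixel noise, then the overexposed rim annulus
    r <- r + matrix(rnorm(h * w, 0, 8), h, w)
    g <- g + matrix(rnorm(h * w, 0, 8), h, w)
    b <- b + matrix(rnorm(h * w, 0, 8), h, w)
    rim <- fundus & dist > 0.92 * R
    r[rim] <- r[rim] * 1.2 + 30
    g[rim] <- g[rim] * 1.2 + 30
    b[rim] <- b[rim] * 1.2 + 30

    px <- array(0, c(h, w, 3))
    px[, , 1][fundus] <- r[fundus]
    px[, , 2][fundus] <- g[fundus]
    px[, , 3][fundus] <- b[fundus]

    obscured <- 0
    discVisible <- 1
    if (quality == "poor") {
      mode <- sample.int(3L, 1L)
      nFundus <- sum(fundus)
      if (mode == 1L) {
        # vertical half-plane occlusion covering 50-70% of the fundus
        frac <- runif(1, 0.5, 0.7)
        xs <- X[fundus]
        x0 <- as.numeric(stats::quantile(xs, frac))
        occ <- X <= x0
        px[, , 1][occ] <- 0; px[, , 2][occ] <- 0; px[, , 3][occ] <- 0
        obscured <- sum(occ & fundus) / nFundus
        discVisible <- sum(discMask & !occ) / max(1, sum(discMask))
      } else if (mode == 2L) {
        # dark disk occlusion over at least half the fundus area
        rr <- R * sqrt(runif(1, 0.55, 0.75))
        ox <- cx + runif(1, -0.1, 0.1) * R
        oy <- cy + runif(1, -0.1, 0.1) * R
        occ <- (X - ox)^2 + (Y - oy)^2 <= rr^2
        px[, , 1][occ] <- 0; px[, , 2][occ] <- 0; px[, , 3][occ] <- 0
        obscured <- sum(occ & fundus) / nFundus
        discVisible <- sum(discMask & !occ) / max(1, sum(discMask))
      } else {
        # crop shift pushing the disc partially out of frame
        s <- as.integer(round(dcx + runif(1, -0.5, 0.5) * db))
        s <- max(1L, min(w - 1L, s))
        shifted <- array(0, c(h, w, 3))
        shifted[, 1:(w - s), ] <- px[, (s + 1):w, , drop = FALSE]
        px <- shifted
        obscured <- sum(fundus & X <= s) / nFundus
        discVisible <- sum(discMask & X > s) / max(1, sum(discMask))
        dcx <- dcx - s
      }
    }
    list(px = .clip8(round(px)), discCenter = c(dcx, dcy),
         obscured = min(1, obscured), discVisible = max(0, min(1, discVisible)))
  })
}

#' Generate one synthetic fundus photograph
#'
#' Deterministic for fixed arguments. A right-eye image is the exact
#' horizontal mirror of the left-eye rendering at the same seed, so the two
#' classes are perfect mirror populations. `quality = "poor"` applies a
#' seeded occlusion (half-plane or dark disk over at least 50% of the fundus)
#' or a crop shift leaving only part of the optic disc in frame.
#'
#' @param seed Integer seed.
#' @param laterality `"left"` or `"right"`.
#' @param canvasSize `(width, height)` in pixels.
#' @param quality `"good"` or `"poor"`.
#' @param config A [SynthConfig-class] carrying the geometric parameters.
#' @return A [FundusImage-class] with ground-truth [ImageMeta-class].
#' @examples
#' img <- generateFundusImage(1L, "left", c(160L, 120L))
#' laterality(img)
#' @export
generateFundusImage <- function(seed, laterality = c("left", "right"),
                                canvasSize = c(2560L, 1920L),
                                quality = c("good", "poor"),
                                config = synthConfig()) {
  laterality <- match.arg(laterality)
  quality <- match.arg(quality)
  .stopIf(length(canvasSize) != 2L || any(canvasSize <= 0),
          "canvasSize must be two positive dimensions")
  w <- as.integer(canvasSize[1])
  h <- as.integer(canvasSize[2])
  rend <- .renderLeftFundus(as.integer(seed), w, h, quality, config)
  px <- rend$px
  dc <- rend$discCenter
  if (laterality == .RIGHT) {
    px <- px[, w:1, , drop = FALSE]
    dc[1] <- (w - 1) - dc[1]
  }
  meta <- new("ImageMeta", laterality = laterality,
              obscuredFraction = rend$obscured,
              discVisibleFraction = rend$discVisible,
              canvasSize = c(w, h), discCenter = dc,
              seed = as.integer(seed))
  fundusImage(px, meta)
}

#' Mirror a fundus image horizontally
#'
#' Reflects the pixel array about the vertical midline; when metadata is
#' present the laterality label is swapped and the disc centre reflected.
#' `mirrorImage` is an involution: applying it twice restores the input
#' bit-exactly.
#'
#' @param image A [FundusImage-class].
#' @return The mirrored [FundusImage-class].
#' @examples
#' img <- generateFundusImage(1L, "left", c(160L, 120L))
#' laterality(mirrorImage(img))
#' @export
mirrorImage <- function(image) {
  stopifnot(is(image, "FundusImage"))
  px <- image@pixels
  w <- dim(px)[2]
  px <- px[, w:1, , drop = FALSE]
  meta <- image@meta
  if (!is.null(meta)) {
    meta@laterality <- if (meta@laterality == .LEFT) .RIGHT else .LEFT
    meta@discCenter[1] <- (w - 1) - meta@discCenter[1]
  }
  fundusImage(px, meta)
}

#' Apply the poor-quality exclusion rule
#'
#' An image is poor quality when at least 50% of the fundus area is obscured
#' or only part of the optic disc is visible; such images are excluded from
#' model development.
#'
#' @param meta An [ImageMeta-class].
#' @return `TRUE` iff `obscuredFraction >= 0.5` or
#'   `discVisibleFraction < 1`.
#' @examples
#' m <- imageMeta(generateFundusImage(1L, "left", c(160L, 120L)))
#' isPoorQuality(m)
#' @export
isPoorQuality <- function(meta) {
  .stopIf(!is(meta, "ImageMeta"), "meta must be an ImageMeta")
  .stopIf(length(meta@obscuredFraction) != 1L ||
            length(meta@discVisibleFraction) != 1L ||
            is.na(meta@obscuredFraction) || is.na(meta@discVisibleFraction),
          "meta fields must be populated")
  meta@obscuredFraction >= 0.5 || meta@discVisibleFraction < 1
}

# Deterministic per-dataset assignment of labels, sizes and quality flags.
.datasetPlan <- function(config) {
  n <- config@nImages
  nLeft <- round(n * config@leftFraction)
  lat <- c(rep(.LEFT, nLeft), rep(.RIGHT, n - nLeft))
  lat <- .withSeed(config@seed, sample(lat))
  nPoor <- round(n * config@poorQualityFraction)
  poor <- rep(FALSE, n)
  if (nPoor > 0) poor[unique(round(seq(1, n, length.out = nPoor)))] <- TRUE
  # rounding of the spread can collide; top up deterministically
  short <- nPoor - sum(poor)
  if (short > 0) poor[which(!poor)[seq_len(short)]] <- TRUE
  sizes <- config@canvasSizes[((seq_len(n) - 1) %% length(config@canvasSizes)) + 1]
  data.frame(
    index = seq_len(n), laterality = lat, poor = poor,
    width = vapply(sizes, `[`, integer(1), 1L),
    height = vapply(sizes, `[`, integer(1), 2L),
    seed = config@seed + seq_len(n)
  )
}

#' Generate an in-memory synthetic dataset
#'
#' @param config A [SynthConfig-class].
#' @return A list with `images` (list of [FundusImage-class]) and `manifest`
#'   (`data.frame` with columns `filename, laterality, obscured_fraction,
#'   disc_visible_fraction, width, height, seed`).
#' @examples
#' ds <- generateFundusSet(synthConfig(nImages = 4,
#'                                     canvasSizes = list(c(160L, 120L))))
#' ds$manifest
#' @export
generateFundusSet <- function(config) {
  plan <- .datasetPlan(config)
  images <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    images[[i]] <- generateFundusImage(
      plan$seed[i], plan$laterality[i], c(plan$width[i], plan$height[i]),
      if (plan$poor[i]) "poor" else "good", config)
  }
  manifest <- data.frame(
    filename = sprintf("img_%05d.png", plan$index),
    laterality = plan$laterality,
    obscured_fraction = vapply(images, function(im) im@meta@obscuredFraction,
                               numeric(1)),
    disc_visible_fraction = vapply(images,
                                   function(im) im@meta@discVisibleFraction,
                                   numeric(1)),
    width = plan$width, height = plan$height, seed = plan$seed,
    stringsAsFactors = FALSE
  )
  list(images = images, manifest = manifest)
}

#' Generate and write a synthetic dataset to disk
#'
#' Writes `nImages` PNG files plus a `manifest.csv`; the output is a pure
#' function of the configuration (identical manifests and image bytes on
#' repeated calls).
#'
#' @param config A [SynthConfig-class].
#' @param outDir Output directory (created if missing).
#' @return The manifest `data.frame`, invisibly; `manifest.csv` and the PNGs
#'   are written under `outDir`.
#' @examples
#' \donttest{
#' d <- tempfile()
#' generateFundusDataset(synthConfig(nImages = 2,
#'                                   canvasSizes = list(c(160L, 120L))), d)
#' }
#' @export
generateFundusDataset <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .stopIf(!dir.exists(outDir), sprintf("cannot create '%s'", outDir))
  ds <- generateFundusSet(config)
  for (i in seq_along(ds$images)) {
    png::writePNG(ds$images[[i]]@pixels / 255,
                  file.path(outDir, ds$manifest$filename[i]))
  }
  write.csv(ds$manifest, file.path(outDir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(ds$manifest)
}

#' Read a dataset manifest
#'
#' @param path A manifest CSV or a directory containing `manifest.csv`.
#' @return The manifest `data.frame`.
#' @export
readManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  .stopIf(!file.exists(path), sprintf("manifest '%s' not found", path))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Load a dataset written by [generateFundusDataset()]
#'
#' @param dir Dataset directory.
#' @param manifest Optional manifest subset to load.
#' @return List of [FundusImage-class] (metadata rebuilt from the manifest).
#' @export
loadFundusDataset <- function(dir, manifest = NULL) {
  if (is.null(manifest)) manifest <- readManifest(dir)
  lapply(seq_len(nrow(manifest)), function(i) {
    px <- png::readPNG(file.path(dir, manifest$filename[i])) * 255
    meta <- new("ImageMeta", laterality = manifest$laterality[i],
                obscuredFraction = manifest$obscured_fraction[i],
                discVisibleFraction = manifest$disc_visible_fraction[i],
                canvasSize = c(manifest$width[i], manifest$height[i]),
                discCenter = c(NA_real_, NA_real_),
                seed = as.integer(manifest$seed[i]))
    fundusImage(px, meta)
  })
}
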