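# Training and inference for the two-way laterality classifier. Epoch-level
# adaptation (learning rate, best-model pool) is delegated entirely to the
# controller in controller.R; this file only runs SGD and bookkeeping.

#' Randomly shift and rotate a fundus image
#'
#' Training-time augmentation: a horizontal translation by an integer offset
#' with `|offset| <= shiftMax` (magnitude uniform on `{0, ..., shiftMax}`
#' with random sign) and a rotation about the image centre by an angle
#' uniform on `[-rotMax, rotMax]` degrees. Both are applied as a single
#' bilinear warp with vacated pixels filled black. Deterministic given the
#' RNG state; the draws actually applied are attached as attributes
#' `shift` and `angle`.
#'
#' @param image A [FundusImage-class].
#' @param config A [TrainConfig-class] supplying `shiftMax` and `rotMax`.
#' @return The augmented [FundusImage-class].
#' @examples
#' img <- generateFundusImage(1L, "left", c(160L, 120L))
#' set.seed(7)
#' aug <- augmentFundus(img, trainConfig())
#' attr(aug, "angle")
#' @export
augmentFundus <- function(image, config = trainConfig()) {
  stopifnot(is(image, "FundusImage"))
  shift <- sample.int(floor(config@shiftMax) + 1L, 1L) - 1L
  shift <- shift * sample(c(-1L, 1L), 1L)
  angle <- runif(1, -config@rotMax, config@rotMax)
  if (shift == 0L && angle == 0) {
    out <- image
  } else {
    px <- image@pixels
    h <- dim(px)[1]; w <- dim(px)[2]
    th <- angle * pi / 180
    rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    ctr <- c((w + 1) / 2, (h + 1) / 2)
    m <- rbind(rot, ctr - drop(ctr %*% rot) + c(shift, 0))
    warped <- EBImage::affine(.asEB(px), m, filter = "bilinear",
                              output.dim = c(w, h), bg.col = 0,
                              antialias = FALSE)
    out <- fundusImage(.clip8(round(.fromEB(warped))), image@meta)
  }
  attr(out, "shift") <- shift
  attr(out, "angle") <- angle
  out
}

#' Sample augmentation transforms
#'
#' Draws `n` augmentation parameter pairs from the current RNG stream using
#' the same sampling scheme as [augmentFundus()].
#'
#' @param n Number of draws.
#' @param config A [TrainConfig-class].
#' @return A `data.frame` with columns `shift` (pixels) and `angle`
#'   (degrees).
#' @export
sampleAugment <- function(n, config = trainConfig()) {
  shift <- integer(n)
  angle <- numeric(n)
  for (i in seq_len(n)) {
    s <- sample.int(floor(config@shiftMax) + 1L, 1L) - 1L
    shift[i] <- s * sample(c(-1L, 1L), 1L)
    angle[i] <- runif(1, -config@rotMax, config@rotMax)
  }
  data.frame(shift = shift, angle = angle)
}

#' Cross-entropy loss with L2 regularisation
#'
#' Mean categorical cross-entropy `-log p_true` (probabilities clamped at
#' 1e-7) plus `lambda * sum(w^2)` over the trainable weights.
#'
#' @param probs Matrix with columns `(P1, P2)`, one row per instance.
#' @param labels Character vector of `"left"` / `"right"` truths.
#' @param weights Numeric vector of trainable weights (or a
#'   [FundusClassifier-class] whose weights are used).
#' @param lambda L2 regularisation strength.
#' @return The scalar loss (non-negative).
#' @examples
#' classifierLoss(rbind(c(0.5, 0.5)), "left")   # log(2)
#' @export
classifierLoss <- function(probs, labels, weights = numeric(0), lambda = 0) {
  probs <- rbind(probs)
  .stopIf(nrow(probs) == 0L || nrow(probs) != length(labels),
          "probs and labels must be non-empty and of equal length")
  if (is(weights, "FundusClassifier"))
    weights <- unlist(.modelWeights(weights))
  pTrue <- ifelse(labels == .LEFT, probs[, 1], probs[, 2])
  mean(-log(pmax(pTrue, 1e-7))) + lambda * sum(unlist(weights)^2)
}

.forwardLogits <- function(model, x, keep = FALSE) {
  r <- .netForward(model@layers, x)
  if (keep) r else r$y
}

#' Predict eye laterality for a fundus image
#'
#' A pure function of the model weights and the image: softmax probabilities
#' `(P1, P2)` and the argmax label, with `"left"` on ties.
#'
#' @param model A [FundusClassifier-class].
#' @param image A [FundusImage-class] at the model's input side.
#' @return A [PredictionResult-class].
#' @export
predictLaterality <- function(model, image) {
  stopifnot(is(model, "FundusClassifier"), is(image, "FundusImage"))
  d <- dim(image@pixels)
  .stopIf(d[1] != model@inputSide || d[2] != model@inputSide,
          sprintf("input must be %d x %d x 3", model@inputSide,
                  model@inputSide))
  p <- .softmax(.forwardLogits(model, .inputScale(image@pixels)))
  new("PredictionResult", pLeft = p[1], pRight = p[2],
      label = if (p[1] >= p[2]) .LEFT else .RIGHT)
}

#' Predict laterality for a list of images
#'
#' @param model A [FundusClassifier-class].
#' @param images List of [FundusImage-class] at the model's input side.
#' @return A `data.frame` with columns `p_left`, `p_right`, `pred` and
#'   (when metadata is present) `truth`.
#' @export
predictBatch <- function(model, images) {
  res <- lapply(images, predictLaterality, model = model)
  data.frame(
    p_left = vapply(res, function(r) r@pLeft, numeric(1)),
    p_right = vapply(res, function(r) r@pRight, numeric(1)),
    pred = vapply(res, function(r) r@label, character(1)),
    truth = vapply(images, laterality, character(1)),
    stringsAsFactors = FALSE
  )
}

.labelsOf <- function(images) vapply(images, laterality, character(1))

#' Train the laterality classifier
#'
#' Mini-batch SGD with momentum at the controller's current learning rate;
#' the loss is cross-entropy with L2 regularisation and every training image
#' is re-augmented each epoch ([augmentFundus()]). After each epoch the
#' validation accuracy and loss are evaluated, bundled as
#' [epochMetrics()], and handed to the controller, whose returned actions
#' (learning-rate reduction, best-snapshot save, snapshot reload) are
#' applied before the next epoch. A snapshot reload restores weights only;
#' optimiser momentum is reset. All randomness (shuffling, augmentation,
#' and any weight initialisation performed by the caller) is governed by
#' `config@seed`, which is set at entry.
#'
#' @param model A freshly built [FundusClassifier-class].
#' @param train,validation Disjoint lists of [FundusImage-class] with
#'   metadata labels; the training set must contain both classes.
#' @param config A [TrainConfig-class].
#' @param controller A [ControllerState-class] from [controllerInit()], or
#'   `NULL` to train at a fixed learning rate with no pool.
#' @param learningRate Fixed learning rate used when `controller` is
#'   `NULL` (defaults to `config@l0`).
#' @param verbose Print one line per epoch.
#' @return A list with elements `model` (the pool's best snapshot when the
#'   pool is non-empty, otherwise the last-epoch model), `log` (the
#'   per-epoch curve `data.frame` with columns `epoch, train_loss,
#'   val_loss, val_acc, monitor, lr, actions`), and `controller` (final
#'   state, or `NULL`).
#' @export
fitClassifier <- function(model, train, validation, config,
                          controller = NULL, learningRate = NULL,
                          verbose = FALSE) {
  stopifnot(is(model, "FundusClassifier"), is(config, "TrainConfig"))
  yTrain <- .labelsOf(train)
  yVal <- .labelsOf(validation)
  .stopIf(length(unique(yTrain)) < 2L,
          "training set must contain both classes")
  .stopIf(length(validation) == 0L, "validation set must be non-empty")
  set.seed(config@seed)

  layers <- model@layers
  vel <- .zeroGrads(layers)
  lr <- if (!is.null(controller)) controller@lr
        else (learningRate %||% config@l0)
  n <- length(train)
  lambda <- config@l2Lambda
  augment <- config@shiftMax > 0 || config@rotMax > 0
  valX <- lapply(validation, function(im) .inputScale(im@pixels))

  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_acc = numeric(),
                    monitor = numeric(), lr = numeric(),
                    actions = character(), stringsAsFactors = FALSE)

  for (epoch in seq_len(config@maxEpochs)) {
    perm <- sample(n)
    batchLosses <- numeric(0)
    at <- 1L
    while (at <= n) {
      idx <- perm[at:min(n, at + config@batchSize - 1L)]
      at <- at + config@batchSize
      acc <- .zeroGrads(layers)
      ce <- 0
      for (i in idx) {
        img <- if (augment) augmentFundus(train[[i]], config) else train[[i]]
        x <- .inputScale(img@pixels)
        fw <- .netForward(layers, x)
        p <- .softmax(fw$y)
        tgt <- if (yTrain[i] == .LEFT) c(1, 0) else c(0, 1)
        ce <- ce - log(max(p[if (yTrain[i] == .LEFT) 1 else 2], 1e-7))
        bw <- .netBackward(layers, fw$caches, p - tgt)
        acc <- .addGrads(acc, bw$grads)
      }
      acc <- .clipGrads(acc, config@gradClip, length(idx))
      step <- .sgdStep(layers, acc, vel, lr, config@momentum, lambda,
                       length(idx))
      layers <- step$layers
      vel <- step$vel
      l2 <- lambda * sum(unlist(.layersWeights(layers))^2)
      batchLosses <- c(batchLosses, ce / length(idx) + l2)
    }

    # validation pass
    probs <- t(vapply(valX, function(x) {
      .softmax(.netForward(layers, x)$y)
    }, numeric(2)))
    predLab <- ifelse(probs[, 1] >= probs[, 2], .LEFT, .RIGHT)
    valAcc <- mean(predLab == yVal)
    valLoss <- classifierLoss(probs, yVal, .layersWeights(layers), lambda)
    metrics <- epochMetrics(epoch, valAcc, valLoss)

    tokens <- character(0)
    if (!is.null(controller)) {
      res <- controllerObserve(controller, metrics, weightsRef = layers)
      controller <- res$state
      for (a in res$actions) {
        if (a$kind == "SAVE_BEST") {
          tokens <- c(tokens, "save")
        } else if (a$kind == "REDUCE_LR") {
          lr <- a$payload
          tokens <- c(tokens, sprintf("reduce_lr(%g)", lr))
        } else if (a$kind == "RELOAD_BEST") {
          layers <- a$payload$weights
          vel <- .zeroGrads(layers)
          tokens <- c(tokens, "reload")
        }
      }
    }

    log <- rbind(log, data.frame(
      epoch = epoch, train_loss = mean(batchLosses), val_loss = valLoss,
      val_acc = valAcc, monitor = metrics@monitor, lr = lr,
      actions = paste(tokens, collapse = ";"), stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  val_loss %.4f  val_acc %.4f  M %.5f  lr %g %s",
        epoch, mean(batchLosses), valLoss, valAcc, metrics@monitor, lr,
        paste(tokens, collapse = ";")))
  }

  finalLayers <- layers
  if (!is.null(controller)) {
    best <- bestSnapshot(controller)
    if (!is.null(best)) finalLayers <- best$weights
  }
  final <- new("FundusClassifier", backbone = model@backbone,
               inputSide = model@inputSide, layers = finalLayers)
  list(model = final, log = log, controller = controller)
}

#' Save a classifier snapshot
#'
#' Writes the weights (`weights.rds`) and a sidecar `snapshot.json` with
#' the epoch, accuracy, loss, monitor and learning rate at save time.
#'
#' @param model A [FundusClassifier-class].
#' @param dir Output directory.
#' @param metrics Optional [EpochMetrics-class] at save time.
#' @param lr Optional learning rate at save time.
#' @return `dir`, invisibly.
#' @export
saveClassifier <- function(model, dir, metrics = NULL, lr = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "weights.rds"))
  side <- list(backbone = model@backbone, input_side = model@inputSide)
  if (!is.null(metrics)) {
    side$epoch <- metrics@epoch
    side$accuracy <- metrics@accuracy
    side$loss <- metrics@loss
    side$monitor <- metrics@monitor
  }
  if (!is.null(lr)) side$lr <- lr
  jsonlite::write_json(side, file.path(dir, "snapshot.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a classifier snapshot saved by [saveClassifier()]
#'
#' @param dir Snapshot directory.
#' @return The [FundusClassifier-class].
#' @export
loadClassifier <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}
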