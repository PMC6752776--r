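# Shared fixtures. Everything is generated in code; the expensive pieces
# (the desk-scale dataset and the trained models) are memoised so the
# training-dependent tests share one run per seed.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

smallCanvas <- list(c(256L, 192L))
deskSide <- 64L

deskPrepConfig <- function() preprocessConfig(targetSide = deskSide)

# The desk-scale study set: 400 clean synthetic images, balanced classes.
deskDataset <- function() {
  memoFixture("deskDataset", generateFundusSet(
    synthConfig(nImages = 400L, canvasSizes = smallCanvas, seed = 11L)))
}

deskPrepped <- function() {
  memoFixture("deskPrepped", {
    lapply(deskDataset()$images,
           function(im) normalizeFundus(im, deskPrepConfig()))
  })
}

# A held-out clean set from a different generator stream.
holdoutPrepped <- function() {
  memoFixture("holdoutPrepped", {
    ds <- generateFundusSet(
      synthConfig(nImages = 120L, canvasSizes = smallCanvas, seed = 999L))
    lapply(ds$images, function(im) normalizeFundus(im, deskPrepConfig()))
  })
}

deskTrainConfig <- function(seed) {
  trainConfig(backbone = "tiny", inputSide = deskSide, maxEpochs = 20L,
              seed = as.integer(seed))
}

# One self-adaptive training run per seed (memoised).
deskRun <- function(seed) {
  memoFixture(paste0("deskRun", seed), {
    ds <- deskDataset()
    prep <- deskPrepped()
    sp <- splitDataset(ds$manifest, 0.8, 1L)
    iTr <- match(sp$train$filename, ds$manifest$filename)
    iVa <- match(sp$validation$filename, ds$manifest$filename)
    cfg <- deskTrainConfig(seed)
    model <- .withSeedHelper(cfg@seed, buildClassifier("tiny", deskSide))
    fit <- fitClassifier(model, prep[iTr], prep[iVa], cfg,
                         controller = controllerInit(cfg))
    fit$validation <- prep[iVa]
    fit
  })
}

deskSeeds <- c(101L, 202L, 303L)

# First seed whose run reaches the accuracy bar; used by the CAM and
# mirror tests so they examine a model that actually learned the task.
deskBestRun <- function() {
  for (s in deskSeeds) {
    run <- deskRun(s)
    if (max(run$log$val_acc) >= 0.95) return(run)
  }
  deskRun(deskSeeds[1])
}

.withSeedHelper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Brute-force pairwise AUC oracle (ties count one half).
bruteForceAUC <- function(scores, truths) {
  pos <- scores[truths == "left"]
  neg <- scores[truths == "right"]
  mean(outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y)))
}
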