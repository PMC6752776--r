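# Orchestration of the two experiments: the four-way preprocessing
# comparison (fixed learning rate, no self-adaptive strategy) and the
# self-adaptive training run, plus the stratified 8:2 split both rely on.

#' Stratified train/validation split of a manifest
#'
#' Disjoint and exhaustive by filename, stratified by laterality, with the
#' per-stratum training count rounded to the nearest integer; deterministic
#' given the seed.
#'
#' @param manifest Manifest `data.frame` (needs columns `filename`,
#'   `laterality`).
#' @param fraction Training fraction in (0, 1), default 0.8 (an 8:2 split).
#' @param seed Integer seed.
#' @return A list with `train` and `validation` manifest subsets.
#' @export
splitDataset <- function(manifest, fraction = 0.8, seed = 1L) {
  .stopIf(nrow(manifest) == 0L, "manifest must be non-empty")
  .stopIf(fraction <= 0 || fraction >= 1, "fraction must lie in (0, 1)")
  idxTrain <- integer(0)
  .withSeed(seed, {
    for (lat in sort(unique(manifest$laterality))) {
      idx <- which(manifest$laterality == lat)
      nTr <- round(length(idx) * fraction)
      idxTrain <- c(idxTrain, sample(idx, nTr))
    }
  })
  .stopIf(length(idxTrain) == 0L || length(idxTrain) == nrow(manifest),
          "fraction leaves the training or validation side empty")
  idxTrain <- sort(idxTrain)
  list(train = manifest[idxTrain, , drop = FALSE],
       validation = manifest[-idxTrain, , drop = FALSE])
}

# Normalise + enhance a list of images (images aligned with the manifest).
# The circular mask is re-applied after enhancement: histogram-based
# methods can lift masked-out rim pixels above zero, and no method should
# introduce signal outside the valid fundus region.
.preprocessAll <- function(images, config) {
  lapply(images, function(im) {
    circularMask(enhanceFundus(normalizeFundus(im, config), config),
                 config@maskRatio)
  })
}

#' Compare enhancement methods under identical training conditions
#'
#' For each method the same raw images are preprocessed, split and used to
#' train a fresh model at a fixed learning rate with no self-adaptive
#' strategy (the strategy is reserved for the laterality model itself), so
#' the per-epoch validation curves differ only through the preprocessing.
#' The split membership and the initial weights are identical across
#' methods; duplicate method names are dropped with a warning.
#'
#' @param images List of raw [FundusImage-class] with metadata labels.
#' @param methods Character vector out of `ORIGINAL, CLAHE, LSACR, GRAY`.
#' @param epochs Training epochs per method.
#' @param preprocess A [PreprocessConfig-class] (method field overridden).
#' @param train A [TrainConfig-class].
#' @param fraction Training fraction of the split.
#' @param learningRate Fixed learning rate (default 0.01).
#' @return Named list of per-epoch curve `data.frame`s, one per unique
#'   method.
#' @export
comparePreprocessing <- function(images, methods, epochs = 20L,
                                 preprocess = preprocessConfig(),
                                 train = trainConfig(),
                                 fraction = 0.8, learningRate = 0.01) {
  .stopIf(length(methods) == 0L, "need at least one method")
  bad <- setdiff(methods, c("ORIGINAL", "CLAHE", "LSACR", "GRAY"))
  .stopIf(length(bad) > 0, paste("unknown method:", paste(bad, collapse = ", ")))
  if (anyDuplicated(methods)) {
    warning("duplicate methods dropped; one curve per unique method")
    methods <- unique(methods)
  }
  train@maxEpochs <- as.integer(epochs)
  manifest <- data.frame(filename = sprintf("img_%05d", seq_along(images)),
                         laterality = .labelsOf(images),
                         stringsAsFactors = FALSE)
  split <- splitDataset(manifest, fraction, train@seed)
  iTr <- match(split$train$filename, manifest$filename)
  iVa <- match(split$validation$filename, manifest$filename)
  out <- list()
  for (m in methods) {
    cfg <- preprocess
    cfg@method <- m
    prepped <- .preprocessAll(images, cfg)
    model <- .withSeed(train@seed,
                       buildClassifier(train@backbone, train@inputSide))
    fit <- fitClassifier(model, prepped[iTr], prepped[iVa], train,
                         controller = NULL, learningRate = learningRate)
    out[[m]] <- fit$log
  }
  out
}

#' Read a pipeline run configuration
#'
#' YAML (or JSON) mirroring the configuration fields: top-level `data`
#' (manifest path or synthetic generator section), `preprocess`, `train`,
#' `split` and `out`.
#'
#' @param path Configuration file.
#' @return A named list.
#' @export
readRunConfig <- function(path) {
  .stopIf(!file.exists(path), sprintf("config '%s' not found", path))
  yaml::read_yaml(path)
}

.applyFields <- function(obj, fields) {
  for (nm in names(fields)) {
    if (!nm %in% slotNames(class(obj))) next
    cur <- slot(obj, nm)
    val <- fields[[nm]]
    if (is.integer(cur)) val <- as.integer(val)
    slot(obj, nm) <- val
  }
  validObject(obj)
  obj
}

#' Run the full self-adaptive training pipeline
#'
#' Synthesise-or-load, preprocess, split, fit with the self-adaptive
#' controller, and evaluate; every stage's outputs are written under
#' `outDir`: `config.yaml` (a copy of the effective configuration),
#' `curve.csv`, `report.json`, `predictions.csv`, a `best/` snapshot and
#' `run.log`.
#'
#' @param config Named list as returned by [readRunConfig()], or a path to
#'   a YAML/JSON configuration.
#' @param outDir Output run directory (created).
#' @return `outDir`, invisibly.
#' @export
runTraining <- function(config, outDir) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  say <- function(stage, msg) {
    line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage, msg)
    message(line)
    cat(line, "\n", file = logFile, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  prepCfg <- .applyFields(preprocessConfig(), config$preprocess)
  trainCfg <- .applyFields(trainConfig(), config$train)
  fraction <- config$split %||% 0.8

  images <- stage("data", {
    if (!is.null(config$data$manifest)) {
      dir <- dirname(config$data$manifest)
      say("data", sprintf("loading %s", config$data$manifest))
      loadFundusDataset(dir, readManifest(config$data$manifest))
    } else {
      synthCfg <- .applyFields(synthConfig(), config$data$synth)
      say("data", sprintf("synthesising %d images", synthCfg@nImages))
      generateFundusSet(synthCfg)$images
    }
  })

  keep <- stage("filter", {
    ok <- !vapply(images, function(im) {
      !is.null(im@meta) && isPoorQuality(im@meta)
    }, logical(1))
    say("filter", sprintf("%d / %d images pass the quality rule",
                          sum(ok), length(ok)))
    images[ok]
  })

  prepped <- stage("preprocess", {
    say("preprocess", sprintf("method %s, side %d", prepCfg@method,
                              prepCfg@targetSide))
    .preprocessAll(keep, prepCfg)
  })

  manifest <- data.frame(filename = sprintf("img_%05d", seq_along(prepped)),
                         laterality = .labelsOf(prepped),
                         stringsAsFactors = FALSE)
  split <- stage("split", splitDataset(manifest, fraction, trainCfg@seed))
  iTr <- match(split$train$filename, manifest$filename)
  iVa <- match(split$validation$filename, manifest$filename)

  fit <- stage("train", {
    say("train", sprintf("backbone %s, %d epochs", trainCfg@backbone,
                         trainCfg@maxEpochs))
    model <- .withSeed(trainCfg@seed,
                       buildClassifier(trainCfg@backbone,
                                       trainCfg@inputSide))
    fitClassifier(model, prepped[iTr], prepped[iVa], trainCfg,
                  controller = controllerInit(trainCfg))
  })

  stage("evaluate", {
    ev <- evaluateClassifier(fit$model, prepped[iVa])
    say("evaluate", sprintf("val accuracy %.4f, AUC %.4f",
                            ev$report@accuracy, ev$report@auc))
    writeEvalReport(ev$report, file.path(outDir, "report.json"))
    write.csv(cbind(filename = split$validation$filename, ev$predictions),
              file.path(outDir, "predictions.csv"), row.names = FALSE)
  })

  write.csv(fit$log, file.path(outDir, "curve.csv"), row.names = FALSE)
  best <- bestSnapshot(fit$controller)
  saveClassifier(fit$model, file.path(outDir, "best"),
                 metrics = if (!is.null(best)) best$metrics else NULL)
  yaml::write_yaml(list(preprocess = config$preprocess,
                        train = config$train, split = fraction,
                        data = config$data),
                   file.path(outDir, "config.yaml"))
  say("done", sprintf("run directory: %s", outDir))
  invisible(outDir)
}
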