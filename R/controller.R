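# The self-adaptive training strategy as a pure state machine.
#
# After each epoch the trainer reports validation accuracy and loss; the
# controller derives the monitor M = (1 - accuracy) * loss and emits
# actions:
#   SAVE_BEST  - the epoch enters the model pool (monitor at most the pool
#                best, which starts at the threshold 0.005, accuracy >= 0.95
#                and loss <= 0.1);
#   REDUCE_LR  - M failed to improve on the alert baseline for k consecutive
#                epochs, so the learning rate is multiplied by alpha;
#   RELOAD_BEST- every reloadPeriod epochs the pool's best weights are
#                loaded back into training.
# The controller exchanges only plain values and never touches the training
# framework, so any metric stream can be replayed against it.

#' Compute the training monitor
#'
#' `M = (1 - accuracy) * loss`; smaller indicates better joint
#' accuracy/loss performance, and `M = 0` exactly when accuracy is 1 or
#' loss is 0.
#'
#' @param accuracy Validation accuracy in \[0, 1\].
#' @param loss Validation loss, non-negative.
#' @return The monitor value.
#' @examples
#' computeMonitor(0.95, 0.1)   # 0.005
#' @export
computeMonitor <- function(accuracy, loss) {
  .stopIf(accuracy < 0 || accuracy > 1, "accuracy must lie in [0, 1]")
  .stopIf(loss < 0, "loss must be non-negative")
  (1 - accuracy) * loss
}

#' Initialise the self-adaptive controller
#'
#' The learning rate starts at the relatively large `l0` (0.1 by default),
#' no alert is active, the pool is empty, and the best pool monitor is
#' initialised to the monitor threshold so the chained pool condition
#' `M_n <= M_best <= M_threshold` is satisfiable from an empty pool.
#'
#' @param config A [TrainConfig-class]; `alpha` must lie in (0, 1].
#' @return A [ControllerState-class].
#' @examples
#' st <- controllerInit(trainConfig())
#' @export
controllerInit <- function(config = trainConfig()) {
  stopifnot(is(config, "TrainConfig"))
  .stopIf(config@alpha <= 0 || config@alpha > 1,
          "alpha must lie in (0, 1]")
  new("ControllerState", lr = config@l0, alertActive = FALSE,
      alertBaseline = NA_real_, alertCount = 0L, mPrev = NA_real_,
      mBest = config@mThreshold, pool = list(), epoch = 0L,
      config = config)
}

#' Feed one epoch's metrics to the controller
#'
#' A pure function of `(state, metrics)`. Three steps run in order and
#' their actions are emitted as SAVE_BEST, REDUCE_LR, RELOAD_BEST:
#' \enumerate{
#'   \item pool: if `M_n <= M_best`, `accuracy >= accGate` and
#'     `loss <= lossGate`, the snapshot replaces the pool best (ties
#'     replace, keeping the later epoch) and `M_best <- M_n`;
#'   \item learning rate: outside an alert, `M_n >= M_prev` starts an
#'     alert with baseline `B = M_prev`; inside an alert, `M_n >= B`
#'     increments the alert counter and on the k-th such epoch the rate is
#'     reduced to `max(lr * alpha, minLr)` and the alert ends, while
#'     `M_n < B` cancels the alert;
#'   \item reload: on every `reloadPeriod`-th epoch with a non-empty pool,
#'     RELOAD_BEST re-issues the pool's best snapshot.
#' }
#'
#' @param state A [ControllerState-class].
#' @param metrics An [EpochMetrics-class] for the next consecutive epoch.
#' @param weightsRef Opaque handle to the epoch's weights, stored with a
#'   SAVE_BEST snapshot (may be `NULL` for replay).
#' @return A list with `state` (updated) and `actions` (list of
#'   `list(kind, payload)`).
#' @examples
#' st <- controllerInit(trainConfig())
#' r <- controllerObserve(st, epochMetrics(1L, 0.5, 1.0))
#' @export
controllerObserve <- function(state, metrics, weightsRef = NULL) {
  stopifnot(is(state, "ControllerState"), is(metrics, "EpochMetrics"))
  .stopIf(metrics@epoch != state@epoch + 1L,
          sprintf("expected epoch %d, got %d", state@epoch + 1L,
                  metrics@epoch))
  cfg <- state@config
  m <- metrics@monitor
  actions <- list()

  # (a) model pool. The monitor comparison carries a 1e-12 absolute
  # tolerance so an epoch sitting exactly on the gate corner (accuracy =
  # accGate, loss = lossGate, hence M = mThreshold up to floating-point
  # rounding) is admissible, as it is in exact arithmetic.
  if (m <= state@mBest + 1e-12 && metrics@accuracy >= cfg@accGate &&
      metrics@loss <= cfg@lossGate) {
    snap <- list(weights = weightsRef, metrics = metrics)
    state@pool <- list(snap)
    state@mBest <- min(m, state@mBest)
    actions <- c(actions, list(list(kind = "SAVE_BEST", payload = snap)))
  }

  # (b) learning-rate adaptation
  stagnant <- FALSE
  if (!state@alertActive) {
    if (!is.na(state@mPrev) && m >= state@mPrev) {
      state@alertActive <- TRUE
      state@alertBaseline <- state@mPrev
      state@alertCount <- 1L
      stagnant <- TRUE
    }
  } else if (m >= state@alertBaseline) {
    state@alertCount <- state@alertCount + 1L
    stagnant <- TRUE
  } else {
    state@alertActive <- FALSE
    state@alertCount <- 0L
    state@alertBaseline <- NA_real_
  }
  if (stagnant && state@alertCount >= cfg@k) {
    state@lr <- max(state@lr * cfg@alpha, cfg@minLr)
    actions <- c(actions,
                 list(list(kind = "REDUCE_LR", payload = state@lr)))
    state@alertActive <- FALSE
    state@alertCount <- 0L
    state@alertBaseline <- NA_real_
  }

  # (c) periodic reload of the pool best
  if (metrics@epoch %% cfg@reloadPeriod == 0L && length(state@pool)) {
    actions <- c(actions,
                 list(list(kind = "RELOAD_BEST",
                           payload = state@pool[[1]])))
  }

  state@mPrev <- m
  state@epoch <- metrics@epoch
  list(state = state, actions = actions)
}

#' Best snapshot in the model pool
#'
#' @param state A [ControllerState-class].
#' @return The snapshot with minimal monitor (the most recent on ties), or
#'   `NULL` when the pool is empty.
#' @export
bestSnapshot <- function(state) {
  stopifnot(is(state, "ControllerState"))
  if (!length(state@pool)) return(NULL)
  state@pool[[1]]
}

#' Replay a metric stream through the controller
#'
#' Convenience wrapper used for testing and analysis: feeds a sequence of
#' (accuracy, loss) pairs to a fresh controller and records the actions.
#'
#' @param accuracy,loss Equal-length numeric vectors, one entry per epoch.
#' @param config A [TrainConfig-class].
#' @return A `data.frame` with columns `epoch`, `monitor`, `lr` and
#'   `actions` (semicolon-joined tokens).
#' @export
replayController <- function(accuracy, loss, config = trainConfig()) {
  .stopIf(length(accuracy) != length(loss),
          "accuracy and loss must have equal length")
  st <- controllerInit(config)
  out <- data.frame(epoch = integer(), monitor = numeric(),
                    lr = numeric(), actions = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(accuracy)) {
    r <- controllerObserve(st, epochMetrics(i, accuracy[i], loss[i]))
    st <- r$state
    tokens <- vapply(r$actions, function(a) {
      switch(a$kind,
        SAVE_BEST = "save",
        REDUCE_LR = sprintf("reduce_lr(%g)", a$payload),
        RELOAD_BEST = "reload")
    }, character(1))
    out <- rbind(out, data.frame(
      epoch = i, monitor = st@mPrev, lr = st@lr,
      actions = paste(tokens, collapse = ";"), stringsAsFactors = FALSE))
  }
  attr(out, "state") <- st
  out
}
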