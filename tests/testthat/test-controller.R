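# The self-adaptive strategy as a pure state machine.

test_that("the monitor multiplies the error rate into the loss", {
  expect_equal(computeMonitor(1.0, 0.3), 0)
  expect_equal(computeMonitor(0.95, 0.1), 0.005)
  expect_equal(computeMonitor(0.9, 0.2), 0.02)
  expect_error(computeMonitor(1.2, 0.1), "accuracy")
  expect_error(computeMonitor(0.5, -1), "loss")
})

test_that("initialisation starts at l0 with an empty pool", {
  st <- controllerInit(trainConfig())
  expect_equal(st@lr, 0.1)
  expect_null(bestSnapshot(st))
  expect_equal(st@mBest, 0.005)
  expect_error(trainConfig(alpha = 0), "alpha")
  expect_error(trainConfig(alpha = 1.5), "alpha")
})

test_that("an improving monitor stream never reduces the rate", {
  tr <- replayController(accuracy = 1 - c(0.5, 0.4, 0.3),
                         loss = rep(1, 3))
  expect_true(all(tr$lr == 0.1))
  expect_true(all(tr$actions == ""))
})

test_that("five stagnant epochs halve the rate", {
  tr <- replayController(accuracy = rep(0.5, 6), loss = rep(1, 6))
  expect_equal(tr$lr, c(rep(0.1, 5), 0.05))
  expect_equal(tr$actions[6], "reduce_lr(0.05)")
})

test_that("an improvement below the baseline cancels the alert", {
  tr <- replayController(accuracy = 1 - c(0.5, 0.6, 0.6, 0.4, 0.41,
                                          0.41, 0.41, 0.41),
                         loss = rep(1, 8))
  # alert armed at epoch 2 dies at epoch 4; the one re-armed at epoch 5
  # has not yet reached k = 5 stagnant epochs
  expect_true(all(tr$lr == 0.1))
  expect_true(all(!grepl("reduce", tr$actions)))
})

test_that("pool admission needs the monitor and both gates", {
  tr <- replayController(accuracy = c(0.96, 0.99), loss = c(0.08, 0.2))
  expect_equal(tr$actions, c("save", ""))   # loss gate fails at epoch 2
  st <- attr(tr, "state")
  expect_equal(bestSnapshot(st)$metrics@monitor, (1 - 0.96) * 0.08)
  # accuracy gate
  tr2 <- replayController(accuracy = c(0.94), loss = c(0.05))
  expect_equal(tr2$actions, "")
})

test_that("pool ties replace the snapshot and keep the best monitor", {
  tr <- replayController(accuracy = c(0.96, 0.96, 0.97),
                         loss = c(0.1, 0.1, 0.1))
  # monitors 0.004, 0.004 (tie: replace), 0.003
  expect_equal(tr$actions, c("save", "save", "save"))
  st <- attr(tr, "state")
  expect_equal(bestSnapshot(st)$metrics@epoch, 3L)
  expect_equal(st@mBest, 0.003)
})

test_that("non-consecutive epochs are rejected", {
  st <- controllerInit(trainConfig())
  r <- controllerObserve(st, epochMetrics(1L, 0.5, 1))
  expect_error(controllerObserve(r$state, epochMetrics(3L, 0.5, 1)),
               "epoch")
})

test_that("replay is deterministic and obeys the learning-rate law", {
  set.seed(42)
  cfg <- trainConfig()
  for (rep in 1:5) {
    n <- 40L
    acc <- runif(n, 0.3, 1)
    loss <- runif(n, 0, 0.5)
    t1 <- replayController(acc, loss, cfg)
    t2 <- replayController(acc, loss, cfg)
    expect_identical(t1, t2)
    nRed <- sum(grepl("reduce", t1$actions))
    expect_equal(t1$lr[n], max(cfg@l0 * cfg@alpha^nRed, cfg@minLr))
    expect_true(all(diff(t1$lr) <= 0))
    # saves carry non-increasing monitors
    savedM <- t1$monitor[grepl("save", t1$actions)]
    if (length(savedM) > 1) expect_true(all(diff(savedM) <= 0))
    # reloads happen exactly at period multiples with a non-empty pool
    firstSave <- match(TRUE, grepl("save", t1$actions), nomatch = n + 1L)
    expReload <- which(seq_len(n) %% cfg@reloadPeriod == 0 &
                         seq_len(n) >= firstSave)
    expect_equal(which(grepl("reload", t1$actions)), expReload)
  }
})

test_that("the rate never drops below the floor", {
  cfg <- trainConfig(k = 1L, minLr = 0.02)
  tr <- replayController(accuracy = rep(0.5, 8), loss = rep(1, 8),
                         config = cfg)
  expect_equal(tail(tr$lr, 1), 0.02)
  expect_true(all(tr$lr >= 0.02))
})
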