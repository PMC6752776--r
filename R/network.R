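# Layer-graph engine behind the classifiers.
#
# A network is a list of layer specs evaluated sequentially; a "branch"
# layer holds parallel sub-networks whose outputs are concatenated along the
# channel axis (enough to express inception modules). Convolution and
# pooling run through the compiled im2col kernels in src/; the global
# average pooling (GAP) head and the affine output layer are plain R.

.convLayer <- function(kh, kw, cin, cout, sh = 1L, sw = sh, ph = 0L,
                       pw = ph) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       sh = as.integer(sh), sw = as.integer(sw), ph = as.integer(ph),
       pw = as.integer(pw),
       W = array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout)),
       b = numeric(cout))
}

.reluLayer <- function() list(type = "relu")

.poolLayer <- function(kh = 2L, kw = kh, sh = kh, sw = sh, ph = 0L,
                       pw = ph, mode = "max") {
  list(type = "pool", kh = as.integer(kh), kw = as.integer(kw),
       sh = as.integer(sh), sw = as.integer(sw), ph = as.integer(ph),
       pw = as.integer(pw), mode = mode)
}

.gapLayer <- function() list(type = "gap")

.denseLayer <- function(cin, cout) {
  list(type = "dense",
       W = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

.branchLayer <- function(branches) list(type = "branch", branches = branches)

# Forward one layer; returns list(y, cache).
.layerForward <- function(layer, x) {
  switch(layer$type,
    conv = {
      y <- .nnConvForward(x, layer$W, layer$b, layer$sh, layer$sw,
                          layer$ph, layer$pw)
      list(y = y, cache = x)
    },
    relu = {
      y <- x * (x > 0)
      list(y = y, cache = x)
    },
    pool = {
      res <- .nnPoolForward(x, layer$kh, layer$kw, layer$sh, layer$sw,
                            layer$ph, layer$pw, layer$mode == "max")
      list(y = res$y, cache = list(idx = res$idx, xdim = dim(x)))
    },
    gap = {
      d <- dim(x)
      y <- colMeans(matrix(x, d[1] * d[2], d[3]))
      list(y = y, cache = list(xdim = d, x = x))
    },
    dense = {
      list(y = drop(crossprod(layer$W, x)) + layer$b, cache = x)
    },
    branch = {
      outs <- vector("list", length(layer$branches))
      caches <- vector("list", length(layer$branches))
      for (i in seq_along(layer$branches)) {
        r <- .netForward(layer$branches[[i]], x)
        outs[[i]] <- r$y
        caches[[i]] <- r$caches
      }
      d1 <- dim(outs[[1]])
      chans <- vapply(outs, function(o) dim(o)[3], integer(1))
      y <- array(0, c(d1[1], d1[2], sum(chans)))
      at <- 0L
      for (i in seq_along(outs)) {
        y[, , (at + 1):(at + chans[i])] <- outs[[i]]
        at <- at + chans[i]
      }
      list(y = y, cache = list(caches = caches, chans = chans,
                               xdim = dim(x)))
    },
    stop("unknown layer type: ", layer$type)
  )
}

.netForward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- .layerForward(layers[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

# Backward one layer; returns list(dx, grad) with grad NULL for
# parameter-free layers.
.layerBackward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      r <- .nnConvBackward(cache, layer$W, dy, layer$sh, layer$sw,
                           layer$ph, layer$pw)
      list(dx = r$dx, grad = list(W = r$dw, b = r$db))
    },
    relu = list(dx = dy * (cache > 0), grad = NULL),
    pool = {
      if (is.null(cache$idx)) {
        dx <- .nnAvgPoolBackward(dy, as.integer(cache$xdim), layer$kh,
                                 layer$kw, layer$sh, layer$sw, layer$ph,
                                 layer$pw)
      } else {
        dx <- .nnMaxPoolBackward(dy, cache$idx, as.integer(cache$xdim))
      }
      list(dx = dx, grad = NULL)
    },
    gap = {
      d <- cache$xdim
      n <- d[1] * d[2]
      dx <- array(rep(dy / n, each = n), d)
      list(dx = dx, grad = NULL)
    },
    dense = {
      list(dx = drop(layer$W %*% dy),
           grad = list(W = outer(cache, dy), b = dy))
    },
    branch = {
      dx <- NULL
      grads <- vector("list", length(layer$branches))
      at <- 0L
      for (i in seq_along(layer$branches)) {
        ch <- cache$chans[i]
        dyi <- dy[, , (at + 1):(at + ch), drop = FALSE]
        at <- at + ch
        r <- .netBackward(layer$branches[[i]], cache$caches[[i]], dyi)
        grads[[i]] <- r$grads
        dx <- if (is.null(dx)) r$dx else dx + r$dx
      }
      list(dx = dx, grad = grads)
    },
    stop("unknown layer type: ", layer$type)
  )
}

.netBackward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- .layerBackward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grad)  # keep NULL slots for parameter-free layers
  }
  list(dx = dy, grads = grads)
}

# Collect all trainable weight arrays (recursing into branches).
.layersWeights <- function(layers) {
  out <- list()
  for (layer in layers) {
    if (layer$type %in% c("conv", "dense")) {
      out[[length(out) + 1L]] <- layer$W
      out[[length(out) + 1L]] <- layer$b
    } else if (layer$type == "branch") {
      for (br in layer$branches) out <- c(out, .layersWeights(br))
    }
  }
  out
}

.modelWeights <- function(model) .layersWeights(model@layers)

# Zero-filled gradient accumulator shaped like the layer parameters.
.zeroGrads <- function(layers) {
  lapply(layers, function(layer) {
    if (layer$type %in% c("conv", "dense")) {
      list(W = array(0, dim(layer$W) %||% length(layer$W)),
           b = numeric(length(layer$b)))
    } else if (layer$type == "branch") {
      lapply(layer$branches, .zeroGrads)
    } else NULL
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.addGrads <- function(acc, g) {
  for (i in seq_along(acc)) {
    if (is.null(acc[[i]])) next
    if (!is.null(acc[[i]]$W)) {
      acc[[i]]$W <- acc[[i]]$W + g[[i]]$W
      acc[[i]]$b <- acc[[i]]$b + g[[i]]$b
    } else {
      for (j in seq_along(acc[[i]]))
        acc[[i]][[j]] <- .addGrads(acc[[i]][[j]], g[[i]][[j]])
    }
  }
  acc
}

# One SGD-with-momentum step with L2 weight decay (penalty lambda * sum w^2,
# hence gradient 2 * lambda * w). Returns list(layers, vel).
.sgdStep <- function(layers, grads, vel, lr, momentum, lambda, nbatch) {
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    if (layer$type %in% c("conv", "dense")) {
      gW <- grads[[i]]$W / nbatch + 2 * lambda * layer$W
      gb <- grads[[i]]$b / nbatch
      vel[[i]]$W <- momentum * vel[[i]]$W - lr * gW
      vel[[i]]$b <- momentum * vel[[i]]$b - lr * gb
      layers[[i]]$W <- layer$W + vel[[i]]$W
      layers[[i]]$b <- layer$b + vel[[i]]$b
    } else if (layer$type == "branch") {
      for (j in seq_along(layer$branches)) {
        r <- .sgdStep(layers[[i]]$branches[[j]], grads[[i]][[j]],
                      vel[[i]][[j]], lr, momentum, lambda, nbatch)
        layers[[i]]$branches[[j]] <- r$layers
        vel[[i]][[j]] <- r$vel
      }
    }
  }
  list(layers = layers, vel = vel)
}

# Inputs are 8-bit intensities; the network consumes them scaled to
# [-1, 1], the convention Inception-style networks are trained with.
.inputScale <- function(px) px / 127.5 - 1

# Global L2-norm clip of a (mean) gradient set; returns the scaled set.
.clipGrads <- function(grads, maxNorm, nbatch) {
  if (maxNorm <= 0) return(grads)
  sq <- function(g) {
    if (is.null(g)) return(0)
    if (!is.null(g$W)) return(sum(g$W^2) + sum(g$b^2))
    sum(vapply(g, function(b) sum(vapply(b, sq, numeric(1))), numeric(1)))
  }
  gn <- sqrt(sum(vapply(grads, sq, numeric(1)))) / nbatch
  if (gn <= maxNorm) return(grads)
  rapply(grads, function(z) z * (maxNorm / gn), how = "replace")
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
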