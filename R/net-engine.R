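## Minimal CNN engine on BLAS matrix multiplication.
##
## Feature maps are arrays laid out (H, W, N, C); convolution is im2col with
## 3x3 kernels and 'same' zero padding, built from nine shifted views so the
## heavy lifting is a single dgemm per layer. Backward passes propagate to
## the input, which is what the gradient-map interpretation needs.

convOffsets <- expand.grid(di = 0:2, dj = 0:2)

im2col3 <- function(X) {
  d <- dim(X) # H W N C
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  P <- array(0, c(H + 2, W + 2, N, C))
  P[2:(H + 1), 2:(W + 1), , ] <- X
  cols <- matrix(0, H * W * N, 9 * C)
  for (o in seq_len(9)) {
    di <- convOffsets$di[o]; dj <- convOffsets$dj[o]
    blk <- P[di + seq_len(H), dj + seq_len(W), , , drop = FALSE]
    cols[, (o - 1) * C + seq_len(C)] <- matrix(blk, H * W * N, C)
  }
  cols
}

col2im3 <- function(dCols, H, W, N, C) {
  dP <- array(0, c(H + 2, W + 2, N, C))
  for (o in seq_len(9)) {
    di <- convOffsets$di[o]; dj <- convOffsets$dj[o]
    blk <- array(dCols[, (o - 1) * C + seq_len(C)], c(H, W, N, C))
    dP[di + seq_len(H), dj + seq_len(W), , ] <-
      dP[di + seq_len(H), dj + seq_len(W), , , drop = FALSE] + blk
  }
  dP[2:(H + 1), 2:(W + 1), , , drop = FALSE]
}

## ---- layer constructors ------------------------------------------------

layerConv <- function(cin, cout, sdInit = 0.1) {
  list(type = "conv", cin = cin, cout = cout,
       W = matrix(rtruncnorm2(9 * cin * cout, sdInit), 9 * cin, cout),
       b = numeric(cout))
}

layerBN <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), momentum = momentum, eps = eps)
}

layerReLU <- function() list(type = "relu")
layerPool <- function() list(type = "pool")
layerFlatten <- function() list(type = "flatten")

layerDense <- function(din, dout, sdInit = 0.1, tag = "") {
  list(type = "dense", din = din, dout = dout, tag = tag,
       W = matrix(rtruncnorm2(din * dout, sdInit), din, dout),
       b = numeric(dout))
}

layerDropout <- function(p) list(type = "dropout", p = p)

## ---- forward -----------------------------------------------------------

## X: (H, W, N, C) array for conv stages, N x D matrix after flatten.
## Returns list(out, caches, features) where features is the output of the
## dense layer tagged "feature" (pre-activation).
engineForward <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  features <- NULL
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    if (L$type == "conv") {
      d <- dim(X)
      cols <- im2col3(X)
      Y <- cols %*% L$W
      Y <- sweep(Y, 2, L$b, "+")
      caches[[li]] <- list(cols = cols, dims = d)
      X <- array(Y, c(d[1], d[2], d[3], L$cout))
    } else if (L$type == "bn") {
      d <- dim(X)
      m <- matrix(X, prod(d[1:3]), d[4])
      if (train) {
        mu <- colMeans(m)
        v <- colVarsPop(m)
        layers[[li]]$rmean <- L$momentum * L$rmean + (1 - L$momentum) * mu
        layers[[li]]$rvar <- L$momentum * L$rvar + (1 - L$momentum) * v
      } else {
        mu <- L$rmean; v <- L$rvar
      }
      invstd <- 1 / sqrt(v + L$eps)
      xhat <- sweep(sweep(m, 2, mu), 2, invstd, "*")
      out <- sweep(sweep(xhat, 2, L$gamma, "*"), 2, L$beta, "+")
      caches[[li]] <- list(xhat = xhat, invstd = invstd, M = nrow(m),
                           train = train)
      X <- array(out, d)
    } else if (L$type == "relu") {
      caches[[li]] <- list(mask = X > 0)
      X <- X * caches[[li]]$mask
    } else if (L$type == "pool") {
      d <- dim(X)
      i1 <- seq(1, d[1], 2); i2 <- i1 + 1
      j1 <- seq(1, d[2], 2); j2 <- j1 + 1
      A <- X[i1, j1, , , drop = FALSE]; B <- X[i2, j1, , , drop = FALSE]
      C <- X[i1, j2, , , drop = FALSE]; D <- X[i2, j2, , , drop = FALSE]
      Y <- pmax(A, B, C, D)
      w <- ifelse(A == Y, 1L, ifelse(B == Y, 2L, ifelse(C == Y, 3L, 4L)))
      caches[[li]] <- list(w = w, dims = d)
      X <- Y
    } else if (L$type == "flatten") {
      d <- dim(X)
      caches[[li]] <- list(dims = d)
      X <- t(matrix(aperm(X, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]))
    } else if (L$type == "dense") {
      caches[[li]] <- list(input = X)
      X <- sweep(X %*% L$W, 2, L$b, "+")
      if (L$tag == "feature") features <- X
    } else if (L$type == "dropout") {
      if (train && L$p > 0) {
        mask <- (matrix(runif(length(X)), nrow(X)) >= L$p) / (1 - L$p)
        caches[[li]] <- list(mask = mask)
        X <- X * mask
      } else {
        caches[[li]] <- list(mask = NULL)
      }
    }
  }
  list(out = X, caches = caches, features = features, layers = layers)
}

## ---- backward ----------------------------------------------------------

## dOut: gradient at the output of layer `from` (defaults to the last
## layer). Returns list(grads = per-layer parameter gradients, dX =
## gradient at the network input).
engineBackward <- function(layers, caches, dOut, from = length(layers)) {
  grads <- vector("list", length(layers))
  dX <- dOut
  for (li in rev(seq_len(from))) {
    L <- layers[[li]]
    cc <- caches[[li]]
    if (L$type == "conv") {
      d <- dim(dX)
      dYm <- matrix(dX, prod(d[1:3]), d[4])
      grads[[li]] <- list(W = crossprod(cc$cols, dYm), b = colSums(dYm))
      dCols <- dYm %*% t(L$W)
      dX <- col2im3(dCols, cc$dims[1], cc$dims[2], cc$dims[3], cc$dims[4])
    } else if (L$type == "bn") {
      d <- dim(dX)
      dout <- matrix(dX, prod(d[1:3]), d[4])
      xhat <- cc$xhat
      grads[[li]] <- list(gamma = colSums(dout * xhat), beta = colSums(dout))
      dxhat <- sweep(dout, 2, L$gamma, "*")
      if (cc$train) {
        ## batch statistics participate in the forward pass
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
        dm <- sweep(t1 - t2, 2, cc$invstd, "*")
      } else {
        ## running statistics: BN is a fixed per-channel affine map
        dm <- sweep(dxhat, 2, cc$invstd, "*")
      }
      dX <- array(dm, d)
    } else if (L$type == "relu") {
      dX <- dX * cc$mask
    } else if (L$type == "pool") {
      d <- cc$dims
      dXfull <- array(0, d)
      i1 <- seq(1, d[1], 2); i2 <- i1 + 1
      j1 <- seq(1, d[2], 2); j2 <- j1 + 1
      dXfull[i1, j1, , ] <- dX * (cc$w == 1L)
      dXfull[i2, j1, , ] <- dX * (cc$w == 2L)
      dXfull[i1, j2, , ] <- dX * (cc$w == 3L)
      dXfull[i2, j2, , ] <- dX * (cc$w == 4L)
      dX <- dXfull
    } else if (L$type == "flatten") {
      d <- cc$dims
      dX <- aperm(array(t(dX), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    } else if (L$type == "dense") {
      grads[[li]] <- list(W = crossprod(cc$input, dX), b = colSums(dX))
      dX <- dX %*% t(L$W)
    } else if (L$type == "dropout") {
      if (!is.null(cc$mask)) dX <- dX * cc$mask
    }
  }
  list(grads = grads, dX = dX)
}

## ---- optimizer ---------------------------------------------------------

adamInit <- function(layers) {
  lapply(layers, function(L) {
    if (L$type %in% c("conv", "dense")) {
      list(mW = L$W * 0, vW = L$W * 0, mb = L$b * 0, vb = L$b * 0)
    } else if (L$type == "bn") {
      list(mg = L$gamma * 0, vg = L$gamma * 0, mb = L$beta * 0, vb = L$beta * 0)
    } else NULL
  })
}

adamStep <- function(layers, state, grads, lr, t, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  upd <- function(m, v, g, x) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    x <- x - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(m = m, v = v, x = x)
  }
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    L <- layers[[li]]
    s <- state[[li]]
    if (L$type %in% c("conv", "dense")) {
      u <- upd(s$mW, s$vW, g$W, L$W); s$mW <- u$m; s$vW <- u$v; L$W <- u$x
      u <- upd(s$mb, s$vb, g$b, L$b); s$mb <- u$m; s$vb <- u$v; L$b <- u$x
    } else if (L$type == "bn") {
      u <- upd(s$mg, s$vg, g$gamma, L$gamma); s$mg <- u$m; s$vg <- u$v; L$gamma <- u$x
      u <- upd(s$mb, s$vb, g$beta, L$beta); s$mb <- u$m; s$vb <- u$v; L$beta <- u$x
    }
    layers[[li]] <- L
    state[[li]] <- s
  }
  list(layers = layers, state = state)
}

## Snapshot / restore learnable parameters (per-epoch checkpoints).
layerParams <- function(layers) {
  lapply(layers, function(L) {
    switch(L$type,
      conv = list(W = L$W, b = L$b),
      dense = list(W = L$W, b = L$b),
      bn = list(gamma = L$gamma, beta = L$beta, rmean = L$rmean, rvar = L$rvar),
      NULL)
  })
}

setLayerParams <- function(layers, params) {
  for (li in seq_along(layers)) {
    p <- params[[li]]
    if (is.null(p)) next
    for (nm in names(p)) layers[[li]][[nm]] <- p[[nm]]
  }
  layers
}

softmaxRows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Cross-entropy L(y, yhat) = -sum_i y_i log yhat_i, averaged over the batch.
crossEntropy <- function(probs, yIdx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), yIdx)], 1e-12)))
}
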