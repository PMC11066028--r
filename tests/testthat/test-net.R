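tinyConfig <- function(nClasses = 3, seed = 9, dropout = 0, inputSize = 8) {
  networkConfig(nClasses = nClasses, nConvBlocks = 2, featureDim = 5,
                baseWidth = 3, poolAfter = c(1, 2), fcHidden = 7,
                dropout = dropout, inputSize = inputSize, epochs = 2,
                batchSize = 4, seed = seed)
}

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  net <- buildNetwork(tinyConfig())
  X <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  y <- c(1, 2, 3, 1)
  lossOf <- function(layers) {
    fw <- engineForward(layers, X, train = TRUE)
    crossEntropy(softmaxRows(fw$out), y)
  }
  fw <- engineForward(net@layers, X, train = TRUE)
  probs <- softmaxRows(fw$out)
  dL <- probs
  dL[cbind(1:4, y)] <- dL[cbind(1:4, y)] - 1
  dL <- dL / 4
  bw <- engineBackward(net@layers, fw$caches, dL)
  eps <- 1e-6
  for (li in seq_along(net@layers)) {
    g <- bw$grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      pick <- sample(length(net@layers[[li]][[nm]]),
                     min(3, length(net@layers[[li]][[nm]])))
      for (ix in pick) {
        lp <- net@layers; lp[[li]][[nm]][ix] <- lp[[li]][[nm]][ix] + eps
        lm <- net@layers; lm[[li]][[nm]][ix] <- lm[[li]][[nm]][ix] - eps
        num <- (lossOf(lp) - lossOf(lm)) / (2 * eps)
        expect_lt(abs(num - g[[nm]][ix]) /
                    max(1e-6, abs(num) + abs(g[[nm]][ix])), 1e-4)
      }
    }
  }
})

test_that("input gradients match finite differences", {
  set.seed(43)
  net <- buildNetwork(tinyConfig())
  x0 <- matrix(rnorm(64), 8, 8)
  g <- inputGradient(net, x0, 2)
  expect_equal(dim(g), c(8, 8))
  featOf <- function(x) {
    engineForward(net@layers, array(x, c(8, 8, 1, 1)),
                  train = FALSE)$features[1, 2]
  }
  num <- x0 * 0
  for (i in 1:8) for (j in 1:8) {
    xp <- x0; xp[i, j] <- xp[i, j] + 1e-5
    xm <- x0; xm[i, j] <- xm[i, j] - 1e-5
    num[i, j] <- (featOf(xp) - featOf(xm)) / 2e-5
  }
  expect_lt(max(abs(num - g)) / max(abs(num)), 1e-3)
  expect_error(inputGradient(net, x0, 99), "out of range")
})

test_that("network construction honors the contract", {
  cfg <- tinyConfig()
  net1 <- buildNetwork(cfg)
  net2 <- buildNetwork(cfg)
  ## identical initial weights under the same seed
  expect_identical(layerParams(net1@layers), layerParams(net2@layers))
  ## truncated-normal init stays within 2 sd = 0.2
  convW <- net1@layers[[1]]$W
  expect_true(all(abs(convW) <= 0.2))
  ## forward pass on a zero image: probabilities sum to 1
  fw <- engineForward(net1@layers, array(0, c(8, 8, 2, 1)), train = FALSE)
  expect_equal(rowSums(softmaxRows(fw$out)), c(1, 1), tolerance = 1e-9)
  ## feature vector has featureDim entries (64 under package defaults)
  expect_equal(ncol(fw$features), 5)
  expect_equal(networkConfig(nClasses = 2)$featureDim, 64)
  ## loss of a perfect one-hot prediction is 0
  expect_equal(crossEntropy(matrix(c(1, 0, 0), 1), 1), 0)
})

test_that("a tiny network overfits one batch", {
  set.seed(7)
  ## 32 crops, 4 classes marked by a centered blob of class-specific size
  ## (invariant to the dihedral augmentation, survives instance
  ## normalization): expect perfect training accuracy within 200 steps
  n <- 32
  y <- rep(1:4, each = 8)
  D <- sqrt(outer((1:8 - 4.5)^2, (1:8 - 4.5)^2, "+"))
  X <- array(rnorm(8 * 8 * n, sd = 0.2), c(8, 8, n, 1))
  for (i in seq_len(n)) {
    X[, , i, 1] <- X[, , i, 1] + 3 * (D <= c(1.2, 2.2, 3.2, 4.2)[y[i]])
  }
  ## identity labels via protein ids; no pooling of classes
  crops <- CropSet(aperm(X, c(1, 2, 4, 3)),
                   data.frame(protein_id = paste0("P", y),
                              split = "train"))
  cfg <- tinyConfig(nClasses = 4, seed = 5)
  cfg$batchSize <- 32
  cfg$lr <- 3e-3
  net <- buildNetwork(cfg)
  net <- suppressWarnings(trainNetwork(net, crops, epochs = 150))
  probs <- predictProteinProbs(net, crops)
  acc <- mean(max.col(probs) == y)
  expect_equal(acc, 1)
})

test_that("an untrained network predicts at chance on balanced data", {
  set.seed(8)
  n <- 60
  y <- rep(1:3, each = 20)
  X <- array(rnorm(8 * 8 * 1 * n), c(8, 8, 1, n))
  crops <- CropSet(X, data.frame(protein_id = paste0("P", y)))
  net <- buildNetwork(tinyConfig(seed = 12))
  probs <- predictProteinProbs(net, crops)
  acc <- mean(max.col(probs, ties.method = "first") == y)
  expect_lt(abs(acc - 1 / 3), 0.25)
})

test_that("training errors on classes missing from the train split", {
  set.seed(9)
  X <- array(rnorm(8 * 8 * 1 * 6), c(8, 8, 1, 6))
  crops <- CropSet(X, data.frame(protein_id = rep(c("A", "B"), 3),
                                 split = c(rep("train", 3), rep("val", 3))))
  net <- buildNetwork(tinyConfig(nClasses = 3))
  expect_error(
    trainNetwork(net, crops, classes = c("A", "B", "C"), epochs = 1),
    "C")
})

test_that("early stopping follows the accuracy-derivative rule", {
  h <- function(acc) data.frame(epoch = seq_along(acc), test_acc = acc)
  ## increments 20, 20, 10, 0.2, 0.1, 0.05 -> three sub-threshold epochs
  ## complete at epoch 7
  expect_equal(earlyStopEpoch(h(c(10, 30, 50, 60, 60.2, 60.3, 60.35) / 100)),
               7)
  ## constant accuracy: zero increments, fires at patience + 1
  expect_equal(earlyStopEpoch(h(rep(0.5, 9))), 4)
  ## never saturates: last epoch with a warning
  expect_warning(e <- earlyStopEpoch(h(seq(0.1, 0.5, by = 0.05))),
                 "saturated")
  expect_equal(e, 9)
  expect_error(earlyStopEpoch(h(numeric(0))), "empty")
})

test_that("profile extraction is deterministic and matches an independent forward pass", {
  set.seed(10)
  net <- buildNetwork(tinyConfig(dropout = 0.5)) # dropout must not leak in
  n <- 3
  X <- array(rnorm(8 * 8 * 1 * n), c(8, 8, 1, n))
  X[, , 1, 3] <- X[, , 1, 1] # identical crops -> identical scFPs
  crops <- CropSet(X, data.frame(protein_id = c("A", "B", "A"),
                                 crop_id = c("c1", "c2", "c3")))
  p1 <- extractProfiles(net, crops)
  p2 <- extractProfiles(net, crops)
  expect_equal(profileMatrix(p1), profileMatrix(p2), tolerance = 1e-9)
  expect_equal(profileMatrix(p1)[, 1], profileMatrix(p1)[, 3],
               tolerance = 1e-9)

  ## independent plain-loop forward implementation of conv/bn/relu/pool/fc
  naiveForward <- function(layers, x) {
    cur <- list(x) # list of channel matrices
    for (L in layers) {
      if (L$type == "conv") {
        H <- nrow(cur[[1]]); W <- ncol(cur[[1]])
        outs <- vector("list", L$cout)
        for (o in seq_len(L$cout)) {
          acc <- matrix(L$b[o], H, W)
          for (ci in seq_along(cur)) {
            pad <- matrix(0, H + 2, W + 2)
            pad[2:(H + 1), 2:(W + 1)] <- cur[[ci]]
            for (di in 0:2) for (dj in 0:2) {
              wrow <- (di + dj * 3) * length(cur) + ci
              acc <- acc + L$W[wrow, o] *
                pad[di + seq_len(H), dj + seq_len(W)]
            }
          }
          outs[[o]] <- acc
        }
        cur <- outs
      } else if (L$type == "bn") {
        for (ci in seq_along(cur)) {
          cur[[ci]] <- L$gamma[ci] * (cur[[ci]] - L$rmean[ci]) /
            sqrt(L$rvar[ci] + L$eps) + L$beta[ci]
        }
      } else if (L$type == "relu" && is.list(cur)) {
        cur <- lapply(cur, pmax, 0)
      } else if (L$type == "relu") {
        cur <- pmax(cur, 0)
      } else if (L$type == "pool") {
        cur <- lapply(cur, function(m) {
          i1 <- seq(1, nrow(m), 2)
          pmax(m[i1, i1 + 0], m[i1 + 1, i1], m[i1, i1 + 1],
               m[i1 + 1, i1 + 1])[seq_along(i1), seq_along(i1)]
        })
      } else if (L$type == "flatten") {
        cur <- as.vector(unlist(lapply(cur, as.vector)))
      } else if (L$type == "dense") {
        cur <- as.vector(cur %*% L$W + L$b)
        if (identical(L$tag, "feature")) return(cur)
      }
    }
    cur
  }
  ## extractProfiles instance-normalizes internally; do the same here
  x <- X[, , 1, 1]
  xn <- (x - mean(x)) / sqrt(mean(x^2) - mean(x)^2)
  naive <- naiveForward(net@layers, xn)
  expect_equal(naive, as.vector(profileMatrix(p1)[, 1]), tolerance = 1e-8)
})

test_that("average profiles are component-wise means", {
  m <- matrix(rnorm(5 * 4), 5, 4)
  m[, 4] <- -m[, 3] # symmetric pair averages to zero
  fps <- FeatureProfileSet(m, data.frame(
    protein_id = c("A", "B", "C", "C"),
    crop_id = paste0("c", 1:4)), level = "scFP")
  af <- averageProfiles(fps)
  am <- profileMatrix(af)
  expect_equal(am[, "A"], m[, 1], ignore_attr = TRUE)          # single scFP
  expect_equal(am[, "C"], rep(0, 5), ignore_attr = TRUE)       # v and -v
  expect_equal(colData(af)$n_cells, c(1L, 1L, 2L), ignore_attr = TRUE)
  set.seed(11)
  m2 <- matrix(rnorm(5 * 6), 5, 6)
  fps2 <- FeatureProfileSet(m2, data.frame(
    protein_id = rep(c("X", "Y"), each = 3),
    crop_id = paste0("c", 1:6)), level = "scFP")
  am2 <- profileMatrix(averageProfiles(fps2))
  expect_equal(am2[, "X"], rowMeans(m2[, 1:3]), ignore_attr = TRUE)
  ## aFP-of-scFP mean invariant to 1e-6
  expect_lt(max(abs(am2[, "Y"] - rowMeans(m2[, 4:6]))), 1e-6)
})
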