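#' Network configuration
#'
#' Defaults give the full-scale architecture: eight convolutional blocks (conv
#' 3x3, batch normalization, ReLU; 2x2 max-pool after every second block,
#' channel width doubling every second block) followed by three
#' fully-connected layers, with the 64-dimensional second FC layer as the
#' feature-profile layer and 5% dropout after it. Training uses Adam at
#' learning rate 1e-3 with a cosine-decay schedule and the cross-entropy
#' objective on protein identity.
#'
#' @param nClasses number of protein classes (>= 2).
#' @param nConvBlocks number of convolutional blocks.
#' @param featureDim dimensionality of the feature profile layer.
#' @param baseWidth channels of the first block; widths double every second
#'   block.
#' @param poolAfter blocks followed by a 2x2 max-pool (default every second
#'   block).
#' @param fcHidden width of the first FC layer.
#' @param nFcLayers 3 (identity-pretext network) or 2 (auxiliary
#'   classifiers such as the cell-cycle ensemble members).
#' @param dropout dropout rate after the feature layer.
#' @param lr Adam learning rate.
#' @param epochs schedule horizon for cosine decay (and default training
#'   length).
#' @param batchSize minibatch size.
#' @param inputSize crop side length.
#' @param channels which crop channels feed the network (default channel 1,
#'   the tagged protein).
#' @param seed integer seed controlling initialization and batching.
#' @return A named list of class `NetworkConfig`.
#' @export
networkConfig <- function(nClasses, nConvBlocks = 8, featureDim = 64,
                          baseWidth = 16, poolAfter = NULL, fcHidden = 128,
                          nFcLayers = 3, dropout = 0.05, lr = 1e-3,
                          epochs = 30, batchSize = 128, inputSize = 64,
                          channels = 1L, seed = 1) {
  stopifnot(nClasses >= 2, featureDim >= 1, dropout >= 0, dropout < 1,
            nConvBlocks >= 1)
  if (is.null(poolAfter)) poolAfter <- seq(2, nConvBlocks, by = 2)
  sz <- inputSize / 2^length(poolAfter)
  if (sz < 1 || sz != round(sz)) {
    stop("pooling schedule does not divide the input size")
  }
  structure(list(nClasses = as.integer(nClasses), nConvBlocks = nConvBlocks,
                 featureDim = featureDim, baseWidth = baseWidth,
                 poolAfter = poolAfter, fcHidden = fcHidden,
                 nFcLayers = nFcLayers, dropout = dropout, lr = lr,
                 epochs = epochs, batchSize = batchSize,
                 inputSize = inputSize, channels = as.integer(channels),
                 seed = seed),
            class = "NetworkConfig")
}

#' FeatNet: the protein-identity convolutional network
#'
#' S4 wrapper around the layer stack, its configuration, per-epoch training
#' history and per-epoch parameter checkpoints.
#'
#' @slot layers list of layer objects.
#' @slot config a `NetworkConfig`.
#' @slot history data.frame with per-epoch `epoch`, `train_loss`,
#'   `val_acc`, `test_acc`.
#' @slot checkpoints list of per-epoch parameter snapshots.
#' @slot selectedEpoch integer; epoch whose weights are loaded.
#' @export
setClass("FeatNet",
  representation(layers = "list", config = "list", history = "data.frame",
                 checkpoints = "list", selectedEpoch = "integer"))

setMethod("show", "FeatNet", function(object) {
  cfg <- object@config
  cat(sprintf("FeatNet: %d conv blocks, featureDim %d, %d classes%s\n",
              cfg$nConvBlocks, cfg$featureDim, cfg$nClasses,
              if (nrow(object@history))
                sprintf(" (trained %d epochs, selected %d)",
                        nrow(object@history), object@selectedEpoch) else
                " (untrained)"))
})

#' Build a protein-identity network
#'
#' Weights are initialized from a truncated normal distribution with
#' standard deviation 0.1; two builds with the same seed produce identical
#' initial weights.
#'
#' @param config a [networkConfig()].
#' @return A [FeatNet-class] object.
#' @export
buildNetwork <- function(config) {
  stopifnot(inherits(config, "NetworkConfig"))
  withSeed(config$seed, {
    layers <- list()
    cin <- length(config$channels)
    for (b in seq_len(config$nConvBlocks)) {
      cout <- config$baseWidth * 2^((b - 1) %/% 2)
      layers <- c(layers, list(layerConv(cin, cout), layerBN(cout),
                               layerReLU()))
      if (b %in% config$poolAfter) layers <- c(layers, list(layerPool()))
      cin <- cout
    }
    sz <- config$inputSize / 2^length(config$poolAfter)
    flatDim <- sz * sz * cin
    layers <- c(layers, list(layerFlatten()))
    if (config$nFcLayers == 3) {
      layers <- c(layers, list(
        layerDense(flatDim, config$fcHidden), layerReLU(),
        layerDense(config$fcHidden, config$featureDim, tag = "feature"),
        layerReLU(), layerDropout(config$dropout),
        layerDense(config$featureDim, config$nClasses)))
    } else if (config$nFcLayers == 2) {
      layers <- c(layers, list(
        layerDense(flatDim, config$fcHidden, tag = "feature"), layerReLU(),
        layerDropout(config$dropout),
        layerDense(config$fcHidden, config$nClasses)))
    } else stop("nFcLayers must be 2 or 3")
    new("FeatNet", layers = layers, config = unclass(config),
        history = data.frame(), checkpoints = list(), selectedEpoch = 0L)
  })
}

## Crop array -> network input (H, W, N, C), instance-normalized per crop
## and channel (mean 0, variance 1; constant channels become zeros).
netInput <- function(crops, channels = 1L) {
  a <- cropArray(crops)[, , channels, , drop = FALSE] # H W C N
  a <- aperm(a, c(1, 2, 4, 3)) # H W N C
  normalizeArray(a)
}

normalizeArray <- function(a) {
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3] * d[4])
  mu <- colMeans(m)
  sdv <- sqrt(colVarsPop(m))
  m <- sweep(m, 2, mu)
  nz <- sdv > 1e-12
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sdv[nz], "/")
  m[, !nz] <- 0
  array(m, d)
}

classAccuracy <- function(layers, X, yIdx, batchSize = 256) {
  n <- dim(X)[3]
  correct <- 0
  for (s in seq(1, n, by = batchSize)) {
    e <- min(s + batchSize - 1, n)
    fw <- engineForward(layers, X[, , s:e, , drop = FALSE], train = FALSE)
    correct <- correct + sum(max.col(fw$out, ties.method = "first") == yIdx[s:e])
  }
  correct / n
}

#' Train the network on protein-identity prediction
#'
#' Cross-entropy objective, Adam with cosine learning-rate decay, dihedral
#' augmentation (random horizontal/vertical flips and 0/90/180/270-degree
#' rotations) on every training batch, and a parameter checkpoint after
#' every epoch. History records train loss and validation/test accuracy per
#' epoch.
#'
#' @param net a [FeatNet-class] from [buildNetwork()].
#' @param crops a [CropSet-class] whose `info$split` labels train/val/test,
#'   with `info$protein_id` (or `label` column, see `labelColumn`) as class.
#' @param epochs training epochs (default `config$epochs`).
#' @param labelColumn info column holding the class label.
#' @param classes explicit class levels (default: sorted unique labels).
#' @param selection checkpoint selection: `"derivative"` applies the
#'   accuracy-saturation rule of [earlyStopEpoch()]; `"maxval"` picks the
#'   epoch with maximal validation accuracy.
#' @param verbose print per-epoch progress.
#' @return The trained [FeatNet-class] with history, per-epoch checkpoints
#'   and `selectedEpoch` set by the early-stopping rule
#'   ([earlyStopEpoch()]).
#' @export
trainNetwork <- function(net, crops, epochs = NULL, labelColumn = "protein_id",
                         classes = NULL, selection = c("derivative", "maxval"),
                         verbose = FALSE) {
  selection <- match.arg(selection)
  stopifnot(is(net, "FeatNet"), is(crops, "CropSet"))
  cfg <- net@config
  if (is.null(epochs)) epochs <- cfg$epochs
  info <- cropInfo(crops)
  split <- if ("split" %in% colnames(info)) info$split else
    rep("train", length(crops))
  labs <- as.character(info[[labelColumn]])
  if (is.null(classes)) classes <- sort(unique(labs))
  missing <- setdiff(classes, labs[split == "train"])
  if (length(missing)) {
    stop("classes absent from training data: ",
         paste(missing, collapse = ", "))
  }
  yIdx <- match(labs, classes)
  Xall <- netInput(crops, cfg$channels)
  trI <- which(split == "train"); vaI <- which(split == "val")
  teI <- which(split == "test")
  Xtr <- Xall[, , trI, , drop = FALSE]
  ytr <- yIdx[trI]
  layers <- net@layers
  state <- adamInit(layers)
  stepsPerEpoch <- ceiling(length(trI) / cfg$batchSize)
  totalSteps <- max(1, stepsPerEpoch * epochs)
  step <- 0
  hist <- list()
  ckpts <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(deriveSeed(cfg$seed, 7000 + ep), sample(length(trI)))
    losses <- numeric(0)
    for (s in seq(1, length(trI), by = cfg$batchSize)) {
      e <- min(s + cfg$batchSize - 1, length(trI))
      idx <- ord[s:e]
      step <- step + 1
      Xb <- withSeed(deriveSeed(cfg$seed, 90000 + step),
                     augmentArray(Xtr[, , idx, , drop = FALSE],
                                  mode = cfg$augment))
      fw <- withSeed(deriveSeed(cfg$seed, 500000 + step),
                     engineForward(layers, Xb, train = TRUE))
      layers <- fw$layers
      probs <- softmaxRows(fw$out)
      yb <- ytr[idx]
      losses <- c(losses, crossEntropy(probs, yb))
      dLogits <- probs
      dLogits[cbind(seq_along(yb), yb)] <-
        dLogits[cbind(seq_along(yb), yb)] - 1
      dLogits <- dLogits / length(yb)
      bw <- engineBackward(layers, fw$caches, dLogits)
      lrT <- cfg$lr * 0.5 * (1 + cos(pi * (step - 1) / totalSteps))
      st <- adamStep(layers, state, bw$grads, lrT, step)
      layers <- st$layers
      state <- st$state
    }
    valAcc <- if (length(vaI))
      classAccuracy(layers, Xall[, , vaI, , drop = FALSE], yIdx[vaI]) else NA
    testAcc <- if (length(teI))
      classAccuracy(layers, Xall[, , teI, , drop = FALSE], yIdx[teI]) else NA
    hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                             val_acc = valAcc, test_acc = testAcc)
    ckpts[[ep]] <- layerParams(layers)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f val %.3f test %.3f", ep,
                      mean(losses), valAcc, testAcc))
    }
  }
  net@layers <- layers
  net@history <- do.call(rbind, hist)
  net@checkpoints <- ckpts
  net@config$classes <- classes
  sel <- if (selection == "maxval" && any(!is.na(net@history$val_acc))) {
    which.max(net@history$val_acc)
  } else {
    earlyStopEpoch(net@history)
  }
  net <- restoreCheckpoint(net, sel)
  net
}

#' Early-stopping epoch selection
#'
#' Returns the first epoch at which the per-epoch increment of the accuracy
#' curve stayed below `derivThreshold` (percentage points) for `patience`
#' consecutive epochs; if the rule never fires, the last epoch is returned
#' with a warning.
#'
#' @param history data.frame with `epoch` and an accuracy column (values in
#'   \[0, 1\]).
#' @param derivThreshold threshold on the accuracy increment, in percentage
#'   points per epoch.
#' @param patience number of consecutive sub-threshold epochs required.
#' @param metric which history column to use (the default protocol uses
#'   test accuracy; set to `"val_acc"` for stricter hygiene).
#' @return Integer epoch index.
#' @export
earlyStopEpoch <- function(history, derivThreshold = 0.5, patience = 3,
                           metric = "test_acc") {
  if (is.null(history) || !nrow(history)) stop("empty training history")
  acc <- history[[metric]]
  if (all(is.na(acc))) acc <- history$val_acc
  n <- nrow(history)
  if (all(is.na(acc))) return(n) # no held-out curve: keep the last epoch
  if (n < patience + 1) return(n)
  inc <- diff(acc) * 100 # percentage points per epoch
  below <- inc < derivThreshold
  run <- 0
  for (e in seq_along(below)) {
    run <- if (below[e]) run + 1 else 0
    if (run >= patience) return(e + 1L) # epoch index of the increment
  }
  warning("accuracy never saturated; returning last epoch")
  n
}

#' Restore a per-epoch checkpoint
#' @param net trained [FeatNet-class].
#' @param epoch epoch index to load.
#' @return The network with that epoch's weights active.
#' @export
restoreCheckpoint <- function(net, epoch) {
  stopifnot(epoch >= 1, epoch <= length(net@checkpoints),
            !is.null(net@checkpoints[[epoch]]))
  net@layers <- setLayerParams(net@layers, net@checkpoints[[epoch]])
  net@selectedEpoch <- as.integer(epoch)
  net
}

#' Extract single-cell feature profiles
#'
#' Runs crops through the network in evaluation mode (dropout disabled,
#' batch-norm running statistics) and returns the activations of the
#' feature layer (the second FC layer, pre-activation) as scFPs.
#'
#' @param net a [FeatNet-class].
#' @param crops a [CropSet-class].
#' @param epoch optional checkpoint override (default: the selected epoch's
#'   weights already loaded in the network).
#' @param batchSize forward batch size.
#' @return A [FeatureProfileSet-class] at level `"scFP"`.
#' @export
extractProfiles <- function(net, crops, epoch = NULL, batchSize = 256) {
  stopifnot(is(net, "FeatNet"), is(crops, "CropSet"))
  if (!is.null(epoch)) net <- restoreCheckpoint(net, epoch)
  X <- netInput(crops, net@config$channels)
  n <- dim(X)[3]
  feats <- matrix(0, net@config$featureDim, n)
  for (s in seq(1, n, by = batchSize)) {
    e <- min(s + batchSize - 1, n)
    fw <- engineForward(net@layers, X[, , s:e, , drop = FALSE], train = FALSE)
    feats[, s:e] <- t(fw$features)
  }
  info <- cropInfo(crops)
  FeatureProfileSet(feats,
    info = DataFrame(protein_id = info$protein_id,
                     crop_id = if ("crop_id" %in% colnames(info))
                       info$crop_id else sprintf("crop%05d", seq_len(n))),
    level = "scFP")
}

#' Per-class probabilities for crops
#' @param net a [FeatNet-class].
#' @param crops a [CropSet-class].
#' @param batchSize forward batch size.
#' @return n x nClasses matrix of softmax probabilities (columns named by
#'   class).
#' @export
predictProteinProbs <- function(net, crops, batchSize = 256) {
  X <- netInput(crops, net@config$channels)
  n <- dim(X)[3]
  P <- matrix(0, n, net@config$nClasses)
  for (s in seq(1, n, by = batchSize)) {
    e <- min(s + batchSize - 1, n)
    fw <- engineForward(net@layers, X[, , s:e, , drop = FALSE], train = FALSE)
    P[s:e, ] <- softmaxRows(fw$out)
  }
  if (!is.null(net@config$classes)) colnames(P) <- net@config$classes
  P
}

#' Gradient of one feature with respect to the input image
#'
#' Backpropagates a unit gradient from feature `featureIndex` of the
#' feature layer down to the input pixels.
#'
#' @param net a [FeatNet-class].
#' @param crop normalized input crop: matrix (H x W) or (H, W, C) array
#'   matching the network's input channels.
#' @param featureIndex feature to differentiate (1-based).
#' @return Gradient array with the same spatial shape as the crop (H x W
#'   matrix for single-channel networks).
#' @export
inputGradient <- function(net, crop, featureIndex) {
  cfg <- net@config
  if (featureIndex < 1 || featureIndex > cfg$featureDim) {
    stop("featureIndex out of range")
  }
  C <- length(cfg$channels)
  X <- array(crop, c(cfg$inputSize, cfg$inputSize, 1, C))
  featLi <- which(vapply(net@layers, function(L)
    identical(L$tag, "feature"), logical(1)))
  fw <- engineForward(net@layers, X, train = FALSE)
  dF <- matrix(0, 1, cfg$featureDim)
  dF[1, featureIndex] <- 1
  bw <- engineBackward(net@layers, fw$caches, dF, from = featLi)
  g <- bw$dX
  if (C == 1) matrix(g, cfg$inputSize, cfg$inputSize) else
    array(g[, , 1, ], c(cfg$inputSize, cfg$inputSize, C))
}
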