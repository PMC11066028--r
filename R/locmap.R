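## Linear evaluation protocol: adapt frozen feature profiles to
## localization labels with a multinomial logistic-regression head, and
## interpret features (coefficient importance, accuracy-vs-feature-count,
## SmoothGrad gradient maps).

#' Train a localization head on frozen feature profiles
#'
#' Multinomial logistic regression (softmax) trained with Adam (lr 1e-3)
#' and cross-entropy for 5 epochs on fixed scFPs; the epoch with maximal
#' validation accuracy is selected.
#'
#' @param features n x d matrix of scFPs (or a
#'   [FeatureProfileSet-class], transposed internally).
#' @param labels length-n localization labels.
#' @param valFeatures,valLabels optional validation set; when omitted a
#'   `valFraction` stratified split of the input is held out.
#' @param epochs,lr,batchSize optimizer settings.
#' @param valFraction held-out fraction when no validation set is given.
#' @param seed integer seed.
#' @return A `LocalizationModel`: list with `W` (d x K), `b`, `classes`,
#'   `history` (per-epoch validation accuracy), `selectedEpoch`.
#' @export
trainLocalizationHead <- function(features, labels, valFeatures = NULL,
                                  valLabels = NULL, epochs = 5, lr = 1e-3,
                                  batchSize = 128, valFraction = 0.1,
                                  seed = 1) {
  if (is(features, "FeatureProfileSet")) features <- t(profileMatrix(features))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 localization classes")
  counts <- table(labels)
  if (any(counts == 0)) stop("class with zero samples")
  if (is.null(valFeatures)) {
    idx <- withSeed(deriveSeed(seed, 1), {
      unlist(lapply(split(seq_along(labels), labels), function(ix) {
        sample(ix, max(1, round(length(ix) * valFraction)))
      }))
    })
    valFeatures <- features[idx, , drop = FALSE]
    valLabels <- labels[idx]
    features <- features[-idx, , drop = FALSE]
    labels <- labels[-idx]
  }
  y <- match(labels, classes)
  yv <- match(as.character(valLabels), classes)
  d <- ncol(features); K <- length(classes)
  W <- withSeed(deriveSeed(seed, 2),
                matrix(rtruncnorm2(d * K, 0.1), d, K))
  b <- numeric(K)
  mW <- W * 0; vW <- W * 0; mb <- b; vb <- b
  t <- 0
  hist <- numeric(epochs)
  snaps <- vector("list", epochs)
  n <- nrow(features)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(deriveSeed(seed, 100 + ep), sample(n))
    for (s in seq(1, n, by = batchSize)) {
      e <- min(s + batchSize - 1, n)
      ix <- ord[s:e]
      t <- t + 1
      logits <- sweep(features[ix, , drop = FALSE] %*% W, 2, b, "+")
      P <- softmaxRows(logits)
      dL <- P
      dL[cbind(seq_along(ix), y[ix])] <- dL[cbind(seq_along(ix), y[ix])] - 1
      dL <- dL / length(ix)
      gW <- crossprod(features[ix, , drop = FALSE], dL)
      gb <- colSums(dL)
      mW <- 0.9 * mW + 0.1 * gW; vW <- 0.999 * vW + 0.001 * gW^2
      mb <- 0.9 * mb + 0.1 * gb; vb <- 0.999 * vb + 0.001 * gb^2
      W <- W - lr * (mW / (1 - 0.9^t)) / (sqrt(vW / (1 - 0.999^t)) + 1e-8)
      b <- b - lr * (mb / (1 - 0.9^t)) / (sqrt(vb / (1 - 0.999^t)) + 1e-8)
    }
    Pv <- softmaxRows(sweep(valFeatures %*% W, 2, b, "+"))
    hist[ep] <- mean(max.col(Pv, ties.method = "first") == yv)
    snaps[[ep]] <- list(W = W, b = b)
  }
  sel <- max(which(hist >= max(hist) - 1e-9)) # ties -> later epoch
  structure(list(W = snaps[[sel]]$W, b = snaps[[sel]]$b, classes = classes,
                 history = data.frame(epoch = seq_len(epochs),
                                      val_acc = hist),
                 selectedEpoch = sel),
            class = "LocalizationModel")
}

#' @export
print.LocalizationModel <- function(x, ...) {
  cat(sprintf("LocalizationModel: %d features -> %d classes (epoch %d, val acc %.3f)\n",
              nrow(x$W), length(x$classes), x$selectedEpoch,
              x$history$val_acc[x$selectedEpoch]))
  invisible(x)
}

#' Predict localization probabilities
#'
#' @param model a `LocalizationModel`.
#' @param features n x d matrix (or single profile vector, or a
#'   [FeatureProfileSet-class]).
#' @return n x K matrix of softmax probabilities, columns named by class.
#' @export
predictLocalization <- function(model, features) {
  if (is(features, "FeatureProfileSet")) features <- t(profileMatrix(features))
  if (is.null(dim(features))) features <- matrix(features, 1)
  if (anyNA(features)) stop("NaN/NA in input features")
  if (ncol(features) != nrow(model$W)) stop("feature length mismatch")
  P <- softmaxRows(sweep(features %*% model$W, 2, model$b, "+"))
  colnames(P) <- model$classes
  P
}

#' Per-protein localization call
#'
#' The protein-level localization is the class with the maximal prediction
#' across all of its scFPs (default), or the class with the maximal mean
#' probability.
#'
#' @param model a `LocalizationModel`.
#' @param features n x d matrix of one protein's scFPs.
#' @param method `"max"` (maximal single-cell score) or `"mean"`.
#' @return Single class name.
#' @export
callProteinLocalization <- function(model, features,
                                    method = c("max", "mean")) {
  method <- match.arg(method)
  P <- predictLocalization(model, features)
  if (method == "max") {
    model$classes[which.max(apply(P, 2, max))]
  } else {
    model$classes[which.max(colMeans(P))]
  }
}

#' Feature-to-localization importance table
#'
#' Maps each feature to the localization of its maximal coefficient (ties
#' broken by lowest class index) and sorts features by that coefficient in
#' descending order; features with coefficient > 5 are flagged as strongly
#' predictive.
#'
#' @param model a `LocalizationModel`.
#' @param strongThreshold coefficient threshold for the strong flag.
#' @return data.frame (feature, localization, coefficient, strong), sorted
#'   descending.
#' @export
featureImportance <- function(model, strongThreshold = 5) {
  W <- model$W
  cls <- max.col(W, ties.method = "first")
  coef <- W[cbind(seq_len(nrow(W)), cls)]
  out <- data.frame(feature = seq_len(nrow(W)),
                    localization = model$classes[cls],
                    coefficient = coef,
                    strong = coef > strongThreshold,
                    stringsAsFactors = FALSE)
  out[order(-out$coefficient), , drop = FALSE]
}

#' Classification accuracy versus number of features
#'
#' Retrains the localization head on the top-N features (by the importance
#' ranking) for each N in the grid, repeating `repeats` times with
#' different seeds; reports per-localization and overall accuracy with
#' standard deviations. N = 0 fits the bias-only model (chance level).
#'
#' @param features n x d scFP matrix.
#' @param labels length-n localization labels.
#' @param ranking feature indices in decreasing importance (default: from
#'   a full-model [featureImportance()]).
#' @param grid feature counts to evaluate.
#' @param repeats runs per N.
#' @param epochs,lr,batchSize probe training settings per fit.
#' @param seed integer seed.
#' @return data.frame (n_features, localization, mean_acc, sd_acc);
#'   localization `"overall"` rows give the pooled accuracy.
#' @export
accuracyVsFeatureCount <- function(features, labels, ranking = NULL,
                                   grid = NULL, repeats = 5, epochs = 5,
                                   lr = 1e-3, batchSize = 128, seed = 1) {
  if (is(features, "FeatureProfileSet")) features <- t(profileMatrix(features))
  d <- ncol(features)
  if (is.null(grid)) grid <- unique(pmin(c(1, 2, 4, 8, 16, 32, 64), d))
  if (any(grid > d)) stop("feature count exceeds feature dimension")
  if (is.null(ranking)) {
    full <- trainLocalizationHead(features, labels, seed = seed)
    ranking <- featureImportance(full)$feature
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  rows <- list()
  for (N in grid) {
    accs <- matrix(NA_real_, repeats, length(classes) + 1,
                   dimnames = list(NULL, c(classes, "overall")))
    for (r in seq_len(repeats)) {
      sd2 <- deriveSeed(seed, N * 100 + r)
      if (N == 0) {
        f0 <- matrix(0, nrow(features), 1)
        m <- trainLocalizationHead(f0, labels, epochs = epochs, lr = lr,
                                   batchSize = batchSize, seed = sd2)
        P <- predictLocalization(m, f0)
      } else {
        fN <- features[, ranking[seq_len(N)], drop = FALSE]
        m <- trainLocalizationHead(fN, labels, epochs = epochs, lr = lr,
                                   batchSize = batchSize, seed = sd2)
        P <- predictLocalization(m, fN)
      }
      pred <- colnames(P)[max.col(P, ties.method = "first")]
      accs[r, "overall"] <- mean(pred == labels)
      for (cl in classes) {
        accs[r, cl] <- mean(pred[labels == cl] == cl)
      }
    }
    for (cl in colnames(accs)) {
      rows[[length(rows) + 1]] <- data.frame(
        n_features = N, localization = cl,
        mean_acc = mean(accs[, cl]), sd_acc = sd(accs[, cl]))
    }
  }
  do.call(rbind, rows)
}

#' SmoothGrad feature gradient map
#'
#' Averages `n` input-gradient maps of feature `featureIndex` computed on
#' noisy copies of the crop (`x + N(0, sigma^2)`, noise in
#' normalized-intensity units). With `sigma = 0, n = 1` this is the plain
#' gradient of the feature with respect to the input image.
#'
#' @param net a trained [FeatNet-class].
#' @param crop normalized input crop (H x W matrix for single-channel
#'   networks).
#' @param featureIndex feature to interpret (1-based).
#' @param n number of noisy samples.
#' @param sigma noise standard deviation.
#' @param seed integer seed (recorded in the output attributes).
#' @return Gradient map with the same spatial shape as the crop;
#'   attributes `feature`, `n`, `sigma`, `seed`.
#' @export
smoothGradMap <- function(net, crop, featureIndex, n = 100, sigma = 0.05,
                          seed = 1) {
  if (featureIndex < 1 || featureIndex > net@config$featureDim) {
    stop("featureIndex out of range")
  }
  acc <- withSeed(seed, {
    out <- NULL
    for (i in seq_len(n)) {
      x <- if (sigma > 0) crop + rnorm(length(crop), 0, sigma) else crop
      g <- inputGradient(net, x, featureIndex)
      out <- if (is.null(out)) g else out + g
    }
    out / n
  })
  attr(acc, "feature") <- featureIndex
  attr(acc, "n") <- n
  attr(acc, "sigma") <- sigma
  attr(acc, "seed") <- seed
  acc
}

#' Write a gradient map as TIFF
#' @param map gradient map from [smoothGradMap()].
#' @param file output path.
#' @return The path, invisibly; intensities are min-max scaled to \[0, 1\].
#' @export
writeGradientMap <- function(map, file) {
  rng <- range(map)
  sc <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  tiff::writeTIFF(sc, file, bits.per.sample = 32L)
  invisible(file)
}
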