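## Field images -> filtered, normalized, split 64x64 single-cell crops.
##
## Coordinates are 0-based in all user-facing tables; a crop of size 64
## around center c covers the half-open pixel window [c-32, c+32) in each
## dimension, so the cell center sits at the crop midpoint.

#' Detect cell centers from the nuclear channel
#'
#' Otsu threshold, distance transform and watershed on the nuclear marker
#' channel; one center (segment centroid) per detected nucleus. Centers
#' closer than `margin` pixels to the image border are discarded.
#'
#' @param nuclear 2-D nonnegative image matrix.
#' @param margin border margin in pixels (default 10).
#' @param minArea minimum segment area in pixels (speckle rejection).
#' @return data.frame with 0-based `x` (row) and `y` (column) centers;
#'   empty for flat or empty images.
#' @export
detectCellCenters <- function(nuclear, margin = 10, minArea = 12) {
  stopifnot(is.matrix(nuclear))
  empty <- data.frame(x = numeric(0), y = numeric(0))
  rng <- range(nuclear)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-12) return(empty)
  img <- (nuclear - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  bw <- img > thr
  if (!any(bw)) return(empty)
  bw <- EBImage::opening(bw, EBImage::makeBrush(3, shape = "box"))
  dm <- EBImage::distmap(bw)
  labels <- EBImage::watershed(dm, tolerance = 1)
  labs <- as.integer(labels)
  keep <- which(labs > 0)
  if (!length(keep)) return(empty)
  rows <- (keep - 1) %% nrow(img)        # 0-based row
  cols <- (keep - 1) %/% nrow(img)       # 0-based col
  sp <- split(data.frame(r = rows, c = cols), labs[keep])
  cent <- do.call(rbind, lapply(sp, function(d) {
    if (nrow(d) < minArea) return(NULL)
    data.frame(x = round(mean(d$r)), y = round(mean(d$c)))
  }))
  if (is.null(cent)) return(empty)
  H <- nrow(img); W <- ncol(img)
  ok <- cent$x >= margin & cent$x <= H - 1 - margin &
        cent$y >= margin & cent$y <= W - 1 - margin
  cent <- cent[ok, , drop = FALSE]
  rownames(cent) <- NULL
  cent
}

#' Extract crops around cell centers
#'
#' Cuts `cropSize` x `cropSize` windows `[c - s/2, c + s/2)` (0-based,
#' half-open) around each center from all channels of a field. Centers too
#' close to the border for a full window are skipped (logged via
#' `getOption("featscope.verbose")`).
#'
#' @param field (H, W, C) array or (H, W) matrix.
#' @param centers data.frame of 0-based `x`, `y` centers.
#' @param cropSize crop side length (even).
#' @param info optional data.frame of per-center metadata carried into the
#'   crop info (recycled row-wise with `centers`).
#' @param proteinId protein identifier recorded for every crop when `info`
#'   has no `protein_id`.
#' @param channels channel names of the field.
#' @return A [CropSet-class]; zero centers give a zero-crop set.
#' @export
extractCrops <- function(field, centers, cropSize = 64, info = NULL,
                         proteinId = NA_character_, channels = NULL) {
  if (is.matrix(field)) field <- array(field, c(dim(field), 1))
  H <- dim(field)[1]; W <- dim(field)[2]; C <- dim(field)[3]
  half <- cropSize %/% 2
  ok <- centers$x >= half & centers$x <= H - half &
        centers$y >= half & centers$y <= W - half
  if (any(!ok)) {
    fsLog(sum(!ok), " centers skipped: too close to field border")
  }
  centers <- centers[ok, , drop = FALSE]
  if (!is.null(info)) info <- info[ok, , drop = FALSE]
  n <- nrow(centers)
  crops <- array(0, c(cropSize, cropSize, C, max(n, 1)))
  for (i in seq_len(n)) {
    rs <- (centers$x[i] - half + 1):(centers$x[i] + half) # 1-based rows
    cs <- (centers$y[i] - half + 1):(centers$y[i] + half)
    crops[, , , i] <- field[rs, cs, , drop = FALSE]
  }
  if (n == 0) crops <- crops[, , , 0, drop = FALSE]
  base <- data.frame(crop_id = sprintf("crop%04d", seq_len(n)),
                     protein_id = rep(proteinId, n),
                     x = centers$x, y = centers$y,
                     stringsAsFactors = FALSE)
  if (!is.null(info)) {
    for (nm in colnames(info)) base[[nm]] <- info[[nm]]
  }
  CropSet(crops, base, channels = channels)
}

#' Filter low-signal and background-dominated crops
#'
#' Implements two quality rules on the tagged-protein channel (channel 1):
#' crops whose total intensity falls strictly below the dataset-wide
#' `intensityPercentile` (default 5th percentile) are rejected, and crops
#' whose pixel variance falls below `varianceFloor` are rejected as
#' background-dominated (uniform signal). Ties at the percentile boundary
#' are kept.
#'
#' @param crops a [CropSet-class] (>= 1 crop).
#' @param intensityPercentile percentile in (0, 100).
#' @param varianceFloor variance threshold for the background rule.
#' @return list with `kept` (a CropSet) and `rejected` (data.frame of
#'   crop_id and reason).
#' @export
filterCrops <- function(crops, intensityPercentile = 5,
                        varianceFloor = 1e-4) {
  stopifnot(length(crops) >= 1, intensityPercentile > 0,
            intensityPercentile < 100)
  a <- cropArray(crops)
  n <- length(crops)
  g <- matrix(a[, , 1, ], ncol = n)
  totals <- colSums(g)
  vars <- colVarsPop(g)
  thr <- quantile(totals, intensityPercentile / 100, names = FALSE)
  lowInt <- totals < thr
  lowVar <- vars < varianceFloor
  reason <- ifelse(lowInt, "below_intensity_percentile",
                   ifelse(lowVar, "background_dominated", NA))
  rej <- which(!is.na(reason))
  rejected <- data.frame(crop_id = cropInfo(crops)$crop_id[rej],
                         reason = reason[rej], stringsAsFactors = FALSE)
  fsLog("filterCrops: rejected ", nrow(rejected), " of ", n)
  list(kept = crops[setdiff(seq_len(n), rej)], rejected = rejected)
}

#' Drop proteins with too few surviving crops
#'
#' @param crops a [CropSet-class].
#' @param minCells minimum crops per protein (default 10); proteins with
#'   fewer are removed entirely.
#' @return A filtered CropSet; an error if no protein survives.
#' @export
dropSparseProteins <- function(crops, minCells = 10) {
  pid <- as.character(cropInfo(crops)$protein_id)
  counts <- table(pid)
  keepP <- names(counts)[counts >= minCells]
  if (!length(keepP)) stop("all proteins dropped: empty dataset")
  dropped <- setdiff(names(counts), keepP)
  if (length(dropped)) {
    fsLog("dropSparseProteins: dropped ", length(dropped), " proteins (",
          paste(dropped, collapse = ", "), ")")
  }
  crops[pid %in% keepP]
}

#' Stratified train/validation/test split
#'
#' Splits each protein's crops independently in the given ratios (default
#' 8:1:1) using a protein-id-salted seed, so the assignment is
#' deterministic and independent of dataset ordering.
#'
#' @param crops a [CropSet-class].
#' @param ratios length-3 positive weights for train/val/test.
#' @param seed integer seed.
#' @return The CropSet with a `split` column added to its info.
#' @export
splitCrops <- function(crops, ratios = c(8, 1, 1), seed = 1) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  p <- ratios / sum(ratios)
  info <- cropInfo(crops)
  pid <- as.character(info$protein_id)
  split <- character(length(crops))
  for (prot in unique(pid)) {
    idx <- which(pid == prot)
    n <- length(idx)
    ord <- withSeed(deriveSeed(seed, idSalt(prot)), sample(n))
    nTest <- round(n * p[3])
    nVal <- round(n * p[2])
    nTrain <- n - nVal - nTest
    lab <- rep(c("train", "val", "test"), c(nTrain, nVal, nTest))
    split[idx[ord]] <- lab
  }
  info$split <- split
  new("CropSet", crops = cropArray(crops), info = info,
      channels = cropChannels(crops))
}

#' Normalize crops (instance normalization)
#'
#' Standardizes every channel of every crop to mean 0 and variance 1;
#' constant channels become all zeros.
#'
#' @param crops a [CropSet-class] or a (H, W, C, N) array.
#' @return Same type as the input, normalized.
#' @export
normalizeCrops <- function(crops) {
  if (is(crops, "CropSet")) {
    a <- cropArray(crops)
    d <- dim(a)
    m <- matrix(a, d[1] * d[2], d[3] * d[4])
    mu <- colMeans(m)
    sdv <- sqrt(colVarsPop(m))
    m <- sweep(m, 2, mu)
    nz <- sdv > 1e-12
    m[, nz] <- sweep(m[, nz, drop = FALSE], 2, sdv[nz], "/")
    m[, !nz] <- 0
    new("CropSet", crops = array(m, d), info = cropInfo(crops),
        channels = cropChannels(crops))
  } else {
    normalizeArray(crops)
  }
}

## The 8 dihedral transforms of a square matrix.
dihedral8 <- function(m, k) {
  switch(k,
    m,                       # identity
    t(m)[, nrow(m):1],       # rotate 90
    m[nrow(m):1, ncol(m):1], # rotate 180
    t(m)[ncol(m):1, ],       # rotate 270
    m[, ncol(m):1],          # horizontal flip
    m[nrow(m):1, ],          # vertical flip
    t(m),                    # transpose
    t(m)[ncol(m):1, nrow(m):1]) # anti-transpose
}

#' Dihedral augmentation of a crop
#'
#' Applies one of the eight dihedral transforms (random flips combined with
#' rotations by 0/90/180/270 degrees), uniformly at random, to a square
#' crop.
#'
#' @param crop square matrix or (H, W, C) array.
#' @param transform optional transform index 1..8 (1 = identity, 2..4 =
#'   rotations, 5/6 = flips, 7/8 = transposes); sampled uniformly when NULL.
#' @param seed optional seed for the draw.
#' @return Transformed crop of the same shape.
#' @export
augmentCrop <- function(crop, transform = NULL, seed = NULL) {
  d <- dim(crop)
  if (d[1] != d[2]) stop("augmentCrop requires a square crop")
  if (is.null(transform)) {
    transform <- if (is.null(seed)) sample(8, 1) else
      withSeed(seed, sample(8, 1))
  }
  if (is.matrix(crop)) return(dihedral8(crop, transform))
  out <- crop
  for (c in seq_len(d[3])) out[, , c] <- dihedral8(crop[, , c], transform)
  out
}

## Batch augmentation on the (H, W, N, C) network layout; one independent
## transform per crop (draws from the current RNG stream). "dihedral" is
## the identity-pretext protocol; "affine" (arbitrary rotation, flips,
## zoom within 0.02, shifts up to 9 px) is the cell-cycle protocol.
augmentArray <- function(X, mode = c("dihedral", "affine")) {
  mode <- if (is.null(mode)) "dihedral" else match.arg(mode)
  d <- dim(X)
  if (mode == "dihedral") {
    ks <- sample(8, d[3], replace = TRUE)
    for (i in seq_len(d[3])) {
      if (ks[i] == 1) next
      for (c in seq_len(d[4])) {
        X[, , i, c] <- dihedral8(X[, , i, c], ks[i])
      }
    }
  } else {
    for (i in seq_len(d[3])) {
      ang <- runif(1, 0, 2 * pi)
      zoom <- runif(1, 0.98, 1.02)
      sh <- runif(2, -9, 9)
      flips <- sample(c(1, 5, 6), 1) # identity / horizontal / vertical flip
      for (c in seq_len(d[4])) {
        m <- affineResample(X[, , i, c], ang, zoom, sh[1], sh[2])
        X[, , i, c] <- dihedral8(m, flips)
      }
    }
  }
  X
}

## Bilinear resampling of a rotation/zoom/shift about the crop center;
## out-of-field pixels are zero.
affineResample <- function(m, angle, zoom, dx, dy) {
  H <- nrow(m); W <- ncol(m)
  cx <- (H + 1) / 2; cy <- (W + 1) / 2
  gx <- matrix(seq_len(H), H, W) - cx
  gy <- matrix(seq_len(W), H, W, byrow = TRUE) - cy
  ct <- cos(angle); st <- sin(angle)
  sx <- (gx * ct - gy * st) / zoom + cx - dx
  sy <- (gx * st + gy * ct) / zoom + cy - dy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  pick <- function(ix, iy) {
    ok <- ix >= 1 & ix <= H & iy >= 1 & iy <= W
    v <- numeric(length(ix))
    v[ok] <- m[cbind(ix[ok], iy[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * pick(x0, y0) +
       fx * (1 - fy) * pick(x0 + 1, y0) +
       (1 - fx) * fy * pick(x0, y0 + 1) +
       fx * fy * pick(x0 + 1, y0 + 1)
  matrix(v, H, W)
}

#' Prepare crops from a synthetic (or compatible) dataset
#'
#' Runs the full preprocessing pipeline: per-field nuclear watershed center
#' detection, crop extraction (GFP, nuclear, cytosolic channels plus the
#' truth foreground mask when available), matching of detected cells to the
#' truth manifest (nearest center), intensity/variance filtering, sparse
#' protein removal and the stratified 8:1:1 split.
#'
#' @param dataset return value of [generateDataset()] or [readDataset()].
#' @param cropSize crop side length.
#' @param margin border margin for center detection.
#' @param intensityPercentile,varianceFloor see [filterCrops()].
#' @param minCells see [dropSparseProteins()].
#' @param ratios,seed see [splitCrops()].
#' @param matchTolerance maximum distance (pixels) between a detected
#'   center and its manifest cell.
#' @return A [CropSet-class] with channels gfp/nuclear/cyto (+ mask), info
#'   columns crop_id, protein_id, replicate, field_id, x, y, stage, split;
#'   the rejection log is attached as `attr(x, "rejected")`.
#' @export
prepareCrops <- function(dataset, cropSize = 64, margin = 10,
                         intensityPercentile = 5, varianceFloor = 1e-4,
                         minCells = 10, ratios = c(8, 1, 1), seed = 1,
                         matchTolerance = 12) {
  sets <- list()
  for (fid in names(dataset$fields)) {
    fld <- dataset$fields[[fid]]
    man <- dataset$manifest[dataset$manifest$field_id == fid, , drop = FALSE]
    cent <- detectCellCenters(fld$field[, , 2], margin = margin)
    if (!nrow(cent)) next
    ## nearest manifest cell (nuclei can sit off the cell center in budded
    ## stages, hence the tolerance)
    dmat <- outer(cent$x, man$x, "-")^2 + outer(cent$y, man$y, "-")^2
    nearest <- apply(dmat, 1, which.min)
    dist <- sqrt(dmat[cbind(seq_len(nrow(cent)), nearest)])
    okm <- dist <= matchTolerance
    if (any(!okm)) fsLog(sum(!okm), " unmatched centers in ", fid)
    cent <- cent[okm, , drop = FALSE]
    nearest <- nearest[okm]
    if (!nrow(cent)) next
    field <- fld$field
    if (!is.null(fld$foreground)) {
      field <- array(c(field, fld$foreground), dim = dim(field) + c(0, 0, 1))
    }
    info <- data.frame(crop_id = man$crop_id[nearest],
                       protein_id = man$protein_id[nearest],
                       replicate = man$replicate[nearest],
                       field_id = fid, stage = man$stage[nearest],
                       stringsAsFactors = FALSE)
    cs <- extractCrops(field, cent, cropSize = cropSize, info = info,
                       channels = c("gfp", "nuclear", "cyto",
                                    "mask")[seq_len(dim(field)[3])])
    sets[[fid]] <- cs
  }
  if (!length(sets)) stop("no cells detected in any field")
  all <- Reduce(function(a, b) {
    new("CropSet", crops = abind4(cropArray(a), cropArray(b)),
        info = rbind(cropInfo(a), cropInfo(b)), channels = cropChannels(a))
  }, sets)
  filt <- filterCrops(all, intensityPercentile, varianceFloor)
  kept <- dropSparseProteins(filt$kept, minCells)
  kept <- splitCrops(kept, ratios = ratios, seed = seed)
  attr(kept, "rejected") <- filt$rejected
  kept
}

## bind two (H, W, C, N) stacks along N
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}
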