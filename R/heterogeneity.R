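## Localization heterogeneity calling (single / AND / OR / undetermined)
## from per-crop localization probabilities, and cell-cycle association of
## localization changes.

#' Heterogeneity calling parameters
#'
#' @param alphaConf low-confidence threshold: crops with
#'   `p1 + p2 < alphaConf` are set aside.
#' @param beta margin for a confident single-localization call:
#'   class 1 when `p1 > p2 + beta`, class 2 symmetrically, mixed
#'   otherwise.
#' @param orThreshold OR-calling threshold on the secondary-localization
#'   fraction (elbow point 0.08).
#' @param undeterminedFraction proteins whose low-confidence fraction
#'   exceeds this are called undetermined.
#' @param orStatistic `"c2"` applies the rule `min(1, c2) > orThreshold`
#'   (which equals `c2 > orThreshold` since fractions are in \[0, 1\]);
#'   `"min_c1_c2"` uses `min(c1, c2)` instead.
#' @return Parameter list.
#' @export
heterogeneityParams <- function(alphaConf = 0.5, beta = 0.5,
                                orThreshold = 0.08,
                                undeterminedFraction = 0.5,
                                orStatistic = c("c2", "min_c1_c2")) {
  stopifnot(alphaConf >= 0, alphaConf <= 1, beta >= 0, beta <= 1,
            orThreshold >= 0, orThreshold <= 1,
            undeterminedFraction > 0, undeterminedFraction <= 1)
  list(alphaConf = alphaConf, beta = beta, orThreshold = orThreshold,
       undeterminedFraction = undeterminedFraction,
       orStatistic = match.arg(orStatistic))
}

#' Two most frequent localizations of a protein
#'
#' Ranks localization classes by their mean probability across the
#' protein's crops (ties broken by class index) and extracts the per-crop
#' probability pairs `[p_i1, p_i2]` of the top two classes.
#'
#' @param probs n x K matrix of per-crop localization probabilities
#'   (columns named by class).
#' @return list with `loc1`, `loc2` and `pairs` (n x 2 matrix).
#' @export
topLocalizations <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1)
  if (ncol(probs) < 2) stop("need at least 2 localization classes")
  mu <- colMeans(probs)
  ord <- order(-mu, seq_along(mu)) # ties broken by class index
  loc1 <- colnames(probs)[ord[1]]
  loc2 <- colnames(probs)[ord[2]]
  list(loc1 = loc1, loc2 = loc2,
       pairs = cbind(p1 = probs[, ord[1]], p2 = probs[, ord[2]]))
}

#' Classify a protein's localization heterogeneity
#'
#' Rule cascade on the per-crop probability pairs of the top two
#' localizations: crops with `p1 + p2 < alphaConf` are low-confidence;
#' remaining crops are class 1 if `p1 > p2 + beta`, class 2 if
#' `p2 > p1 + beta`, mixed otherwise. With category fractions c1, c2, m,
#' k_lc (summing to 1): undetermined if k_lc exceeds
#' `undeterminedFraction`; AND if `m > c1 + c2`; otherwise OR if
#' `min(1, c2) > orThreshold`; otherwise single.
#'
#' @param pairs n x 2 matrix of `[p1, p2]` per crop (from
#'   [topLocalizations()]).
#' @param params a [heterogeneityParams()] list.
#' @return list with `verdict` (`single`/`AND`/`OR`/`undetermined`),
#'   fractions `c1`, `c2`, `m`, `k_lc`, and the per-crop `categories`
#'   (`class1`/`class2`/`mixed`/`low_confidence`).
#' @export
classifyHeterogeneity <- function(pairs, params = heterogeneityParams()) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, 1)
  stopifnot(nrow(pairs) >= 1, ncol(pairs) == 2)
  p1 <- pairs[, 1]; p2 <- pairs[, 2]
  cat <- rep("mixed", nrow(pairs))
  cat[p1 > p2 + params$beta] <- "class1"
  cat[p2 > p1 + params$beta] <- "class2"
  cat[p1 + p2 < params$alphaConf] <- "low_confidence"
  n <- length(cat)
  c1 <- sum(cat == "class1") / n
  c2 <- sum(cat == "class2") / n
  m <- sum(cat == "mixed") / n
  k <- sum(cat == "low_confidence") / n
  orStat <- if (params$orStatistic == "c2") min(1, c2) else min(c1, c2)
  verdict <- if (k > params$undeterminedFraction) "undetermined"
    else if (m > c1 + c2) "AND"
    else if (orStat > params$orThreshold) "OR"
    else "single"
  list(verdict = verdict, c1 = c1, c2 = c2, m = m, k_lc = k,
       categories = cat)
}

#' Heterogeneity calls for a whole panel
#'
#' @param probs n x K matrix of per-crop localization probabilities.
#' @param proteinIds length-n protein ids.
#' @param params a [heterogeneityParams()] list.
#' @return list with `calls` (data.frame protein_id, verdict, loc1, loc2,
#'   c1, c2, m, k_lc) and `categories` (per-crop category vector aligned
#'   with the input rows).
#' @export
heterogeneityCalls <- function(probs, proteinIds,
                               params = heterogeneityParams()) {
  proteinIds <- as.character(proteinIds)
  categories <- character(nrow(probs))
  loc12 <- character(nrow(probs))
  rows <- lapply(unique(proteinIds), function(p) {
    ix <- which(proteinIds == p)
    top <- topLocalizations(probs[ix, , drop = FALSE])
    cl <- classifyHeterogeneity(top$pairs, params)
    categories[ix] <<- cl$categories
    loc12[ix] <<- ifelse(cl$categories == "class1", top$loc1,
                         ifelse(cl$categories == "class2", top$loc2, NA))
    data.frame(protein_id = p, verdict = cl$verdict, loc1 = top$loc1,
               loc2 = top$loc2, c1 = cl$c1, c2 = cl$c2, m = cl$m,
               k_lc = cl$k_lc, stringsAsFactors = FALSE)
  })
  list(calls = do.call(rbind, rows), categories = categories,
       crop_localization = loc12)
}

## ---- cell-cycle ensemble ----------------------------------------------

#' Train the cell-cycle classification ensemble
#'
#' Three CNNs (four convolutional blocks, two FC layers by default) on the
#' nuclear and cytosolic channels, predicting the stages G1, S, MA
#' (metaphase/anaphase) and T (telophase). Members are assigned the three
#' folds of a stratified 3-fold cross-validation as their validation sets
#' and selected at their maximal validation accuracy. Training uses affine
#' augmentation: rotation by an arbitrary angle, flips, zoom within 0.02
#' and shifts of up to 9 pixels.
#'
#' @param crops a [CropSet-class] with `stage` in its info and nuclear +
#'   cytosolic channels.
#' @param nConvBlocks,baseWidth,fcHidden,epochs,lr member architecture and
#'   training settings (full-scale protocol: 4 blocks, 150 epochs, Adam
#'   5e-4, dropout 0.05; scale down for small synthetic runs).
#' @param nMembers ensemble size.
#' @param augment `"affine"` is the full protocol (arbitrary
#'   rotation, flips, zoom, shifts); `"dihedral"` restricts to flips and
#'   right-angle rotations, which trains markedly faster at short epoch
#'   budgets.
#' @param perClass optional cap on labeled crops per stage (use when
#'   stage labels are scarce); sampled deterministically under `seed`.
#' @param seed integer seed.
#' @return A `CellCycleEnsemble`: list of [FeatNet-class] members plus
#'   stage classes and fold assignment.
#' @export
trainCellCycleEnsemble <- function(crops, nConvBlocks = 4, baseWidth = 8,
                                   fcHidden = 32, epochs = 15, lr = 5e-4,
                                   nMembers = 3,
                                   augment = c("affine", "dihedral"),
                                   perClass = NULL, seed = 1) {
  augment <- match.arg(augment)
  info <- cropInfo(crops)
  stopifnot("stage" %in% colnames(info))
  stages <- c("G1", "S", "MA", "T")
  missing <- setdiff(stages, unique(info$stage))
  if (length(missing)) {
    stop("missing cell-cycle class(es): ", paste(missing, collapse = ", "))
  }
  if (dim(cropArray(crops))[3] < 3) {
    stop("need nuclear and cytosolic channels for cell-cycle training")
  }
  if (!is.null(perClass)) {
    keep <- withSeed(deriveSeed(seed, 3), {
      unlist(lapply(stages, function(s) {
        ix <- which(info$stage == s)
        sample(ix, min(perClass, length(ix)))
      }))
    })
    crops <- crops[sort(keep)]
    info <- cropInfo(crops)
  }
  n <- length(crops)
  folds <- withSeed(deriveSeed(seed, 11), {
    f <- integer(n)
    for (s in stages) {
      ix <- which(info$stage == s)
      f[ix] <- sample(rep(seq_len(nMembers), length.out = length(ix)))
    }
    f
  })
  members <- vector("list", nMembers)
  for (memb in seq_len(nMembers)) {
    ## pool after every block: bud-size morphology survives aggressive
    ## downsampling and the activation footprint stays small
    cfg <- networkConfig(nClasses = 4, nConvBlocks = nConvBlocks,
                         featureDim = fcHidden, baseWidth = baseWidth,
                         poolAfter = seq_len(nConvBlocks),
                         fcHidden = fcHidden, nFcLayers = 2, dropout = 0.05,
                         lr = lr, epochs = epochs,
                         batchSize = min(64, n), channels = c(2L, 3L),
                         seed = deriveSeed(seed, 20 + memb))
    cfg$augment <- augment
    split <- ifelse(folds == memb, "val", "train")
    ci <- info
    ci$split <- split
    cs <- new("CropSet", crops = cropArray(crops), info = ci,
              channels = cropChannels(crops))
    net <- buildNetwork(cfg)
    net <- trainNetwork(net, cs, epochs = epochs, labelColumn = "stage",
                        classes = stages, selection = "maxval")
    members[[memb]] <- net
  }
  structure(list(members = members, classes = stages, folds = folds),
            class = "CellCycleEnsemble")
}

#' Predict cell-cycle stage probabilities
#'
#' The ensemble probability is the mean of the member probability vectors;
#' reporting merges T and G1 into one class, so the merged columns are
#' T/G1 (= T + G1), S/G2 (= S) and M/A (= MA).
#'
#' @param ensemble a `CellCycleEnsemble`.
#' @param crops a [CropSet-class] with nuclear and cytosolic channels.
#' @return list with `raw` (n x 4, G1/S/MA/T) and `merged` (n x 3,
#'   T/G1, S/G2, M/A); rows sum to 1.
#' @export
predictCellCycle <- function(ensemble, crops) {
  if (dim(cropArray(crops))[3] < 3) {
    stop("crops lack nuclear/cytosolic channels")
  }
  Ps <- lapply(ensemble$members, function(m) predictProteinProbs(m, crops))
  raw <- Reduce(`+`, Ps) / length(Ps)
  colnames(raw) <- ensemble$classes
  merged <- cbind("T/G1" = raw[, "T"] + raw[, "G1"], "S/G2" = raw[, "S"],
                  "M/A" = raw[, "MA"])
  list(raw = raw, merged = merged)
}

#' Associate localization changes with cell-cycle stages
#'
#' For a protein with two populated localizations, tests, per merged
#' cell-cycle stage, whether the stage's per-crop probability distribution
#' differs between the crops assigned to the primary and to the secondary
#' localization (two-sided Mann-Whitney U test). The null hypothesis is
#' that the stage is equally represented among both localizations.
#'
#' @param cropLocalization per-crop localization assignment (values equal
#'   to `loc1`/`loc2` from the heterogeneity call; others ignored).
#' @param loc1,loc2 the protein's two localizations.
#' @param stageProbs n x 3 matrix of merged stage probabilities.
#' @param pThreshold significance level (default 1e-3).
#' @return data.frame (stage, U, p, significant); NULL (with a warning)
#'   when one localization group is empty.
#' @export
cellCycleAssociation <- function(cropLocalization, loc1, loc2, stageProbs,
                                 pThreshold = 1e-3) {
  g1 <- which(cropLocalization == loc1)
  g2 <- which(cropLocalization == loc2)
  if (!length(g1) || !length(g2)) {
    warning("a localization group is empty; protein skipped")
    return(NULL)
  }
  out <- lapply(colnames(stageProbs), function(st) {
    wt <- suppressWarnings(
      wilcox.test(stageProbs[g1, st], stageProbs[g2, st],
                  alternative = "two.sided", exact = FALSE))
    p <- wt$p.value
    if (is.na(p)) p <- 1 # degenerate (constant) probabilities: no signal
    data.frame(stage = st, U = unname(wt$statistic), p = p,
               significant = p < pThreshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
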