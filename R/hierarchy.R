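## Whole-panel profile dendrogram, biologically-guided threshold selection
## (AMI-derivative rule), sub-compartment silhouette survey, 2-D embedding
## with KDE annotation.

#' Build the profile dendrogram
#'
#' Agglomerative hierarchical clustering of feature profiles with
#' correlation distance (1 - Pearson) and average linkage.
#'
#' @param fps a [FeatureProfileSet-class] or a feature x item matrix with
#'   column names.
#' @return An `hclust` object; labels are protein ids (aFP level) or crop
#'   ids (scFP level).
#' @export
profileDendrogram <- function(fps) {
  if (is(fps, "FeatureProfileSet")) {
    m <- profileMatrix(fps)
    colnames(m) <- if (profileLevel(fps) == "aFP") proteinIds(fps) else
      colData(fps)$crop_id
    pid <- proteinIds(fps)
  } else {
    m <- fps
    pid <- colnames(m)
  }
  if (ncol(m) < 2) stop("need at least 2 profiles")
  sds <- sqrt(colVarsPop(m))
  if (any(sds < 1e-12)) {
    stop("constant profile vector(s): correlation undefined for ",
         paste(colnames(m)[sds < 1e-12], collapse = ", "))
  }
  hc <- hclust(as.dist(1 - cor(m)), method = "average")
  attr(hc, "protein_id") <- pid
  hc
}

## AMI between a flat clustering and labels restricted to labeled items.
amiVsLabels <- function(cl, labels) {
  ok <- !is.na(labels)
  if (sum(ok) < 2) return(NA_real_)
  amiScore(cl[ok], labels[ok])
}

#' Select a dendrogram cutoff by the AMI-derivative rule
#'
#' Computes the AMI between flat clusters and standard labels on a fine
#' threshold grid (step 0.01 by default). The scan starts at correlation 1
#' (distance 0) and coarsens: the chosen cutoff is the first threshold at
#' which the AMI gain over the preceding `window` (finer) steps falls
#' below `derivThreshold` — the diminishing-returns elbow at which the
#' clusters already cover the standard's groups. AMI is evaluated on the
#' proteins with a single annotation.
#'
#' @param dend `hclust` from [profileDendrogram()].
#' @param standard an [annotationStandard()]; or a named character vector
#'   of single labels.
#' @param step threshold grid step.
#' @param window derivative window, in steps.
#' @param derivThreshold slope threshold (AMI units per unit distance).
#' @return A `CutoffReport` list: `threshold`, `clusters` (named integer
#'   vector at the chosen cut), `curve` (threshold, ami), `standard`.
#'   If the rule never fires the max-AMI threshold is returned with a
#'   warning.
#' @export
selectCutoff <- function(dend, standard, step = 0.01, window = 20,
                         derivThreshold = 0.1) {
  labsAll <- dend$labels
  if (inherits(standard, "AnnotationStandard")) {
    single <- standard$mapping[lengths(standard$mapping) == 1]
    labels <- rep(NA_character_, length(labsAll))
    hit <- labsAll %in% names(single)
    labels[hit] <- vapply(single[labsAll[hit]], `[[`, character(1), 1)
    sname <- standard$name
  } else {
    labels <- as.character(standard[labsAll])
    sname <- "labels"
  }
  if (sum(!is.na(labels)) < 2) {
    stop("standard must cover at least 2 proteins with single labels")
  }
  ## ascend from correlation 1 (distance 0); skip the region before the
  ## first merge, where the all-singleton clustering is flat and
  ## uninformative
  start <- max(0, ceiling(min(dend$height) / step) * step)
  grid <- seq(start, 1, by = step)
  ami <- vapply(grid, function(t)
    amiVsLabels(cutree(dend, h = t), labels), numeric(1))
  curve <- data.frame(threshold = grid, ami = ami)
  chosen <- amiDerivativeCutoff(ami, grid, step, window, derivThreshold)
  cl <- cutree(dend, h = chosen)
  structure(list(standard = sname, threshold = chosen, clusters = cl,
                 curve = curve, window = window,
                 derivThreshold = derivThreshold),
            class = "CutoffReport")
}

## The elbow rule on a precomputed AMI curve indexed by ascending
## correlation-distance thresholds (the scan starts at correlation 1,
## i.e. distance 0): pick the first threshold whose AMI gain over the
## preceding `window` finer grid steps falls below `derivThreshold`; fall
## back to the max-AMI threshold (with a warning) if the rule never fires.
amiDerivativeCutoff <- function(ami, grid, step, window, derivThreshold) {
  for (i in seq_along(grid)) {
    if (i <= window) next # no full window on the finer side yet
    slope <- (ami[i] - ami[i - window]) / (window * step)
    if (!is.na(slope) && slope < derivThreshold) return(grid[i])
  }
  warning("AMI-derivative rule never satisfied; returning max-AMI threshold")
  grid[which.max(ami)]
}

#' @export
print.CutoffReport <- function(x, ...) {
  cat(sprintf("CutoffReport (%s): threshold %.2f, %d clusters, AMI %.3f\n",
              x$standard, x$threshold, length(unique(x$clusters)),
              x$curve$ami[match(x$threshold, x$curve$threshold)]))
  invisible(x)
}

#' Sub-compartment clustering with a silhouette survey
#'
#' Clusters each localization group's profiles separately (average linkage,
#' correlation distance), surveys a grid of cut thresholds, and picks the
#' threshold with the maximal median silhouette score
#' `(b - a) / max(a, b)` across localizations.
#'
#' @param fps a [FeatureProfileSet-class] (aFP level).
#' @param localizations named character vector: protein -> localization.
#' @param grid correlation-distance thresholds to survey.
#' @param minGroup minimum profiles per localization group (smaller groups
#'   are skipped with a warning).
#' @return list with `best_threshold`, `silhouettes` (threshold x median
#'   table), `clusters` (named vector localization.cluster at the best
#'   threshold).
#' @export
subcompartmentClusters <- function(fps, localizations,
                                   grid = seq(0.25, 0.75, by = 0.05),
                                   minGroup = 3) {
  m <- profileMatrix(fps)
  colnames(m) <- proteinIds(fps)
  locs <- localizations[colnames(m)]
  groups <- split(colnames(m), locs)
  small <- names(groups)[lengths(groups) < minGroup]
  if (length(small)) {
    warning("skipping small localization groups: ",
            paste(small, collapse = ", "))
  }
  groups <- groups[lengths(groups) >= minGroup]
  if (!length(groups)) stop("no localization group large enough")
  trees <- lapply(groups, function(g) {
    D <- 1 - cor(m[, g, drop = FALSE])
    list(hc = hclust(as.dist(D), method = "average"), D = D, g = g)
  })
  medSil <- vapply(grid, function(t) {
    sils <- vapply(trees, function(tr) {
      cl <- cutree(tr$hc, h = t)
      if (length(unique(cl)) < 2 || length(unique(cl)) >= length(cl)) {
        return(NA_real_)
      }
      mean(cluster::silhouette(cl, dmatrix = tr$D)[, "sil_width"])
    }, numeric(1))
    if (all(is.na(sils))) NA_real_ else stats::median(sils, na.rm = TRUE)
  }, numeric(1))
  tab <- data.frame(threshold = grid, median_silhouette = medSil)
  best <- if (all(is.na(medSil))) 0.5 else grid[which.max(medSil)]
  clusters <- unlist(lapply(names(trees), function(nm) {
    cl <- cutree(trees[[nm]]$hc, h = best)
    setNames(paste0(nm, "-", cl), trees[[nm]]$g)
  }))
  list(best_threshold = best, silhouettes = tab, clusters = clusters)
}

#' Embed profiles in 2-D and annotate with per-label densities
#'
#' t-SNE embedding of the profiles, plus, per label, a Gaussian kernel
#' density estimate (Scott's rule bandwidth) computed after removing points
#' more than two standard deviations from the label's mean along either
#' embedding axis.
#'
#' @param fps a [FeatureProfileSet-class].
#' @param labels per-column labels (NA = unlabeled); optional.
#' @param perplexity t-SNE perplexity (use ~40 for per-protein profiles,
#'   ~200 for large single-cell sets).
#' @param kde compute per-label KDEs.
#' @param file optional PNG path for the annotated map.
#' @param seed integer seed.
#' @param gridSize KDE grid resolution.
#' @return list with `coords` (data.frame x, y, label), `kdes` (per label:
#'   `MASS::kde2d` output), `outliers` (logical vector of removed points).
#' @export
embedAnnotate <- function(fps, labels = NULL, perplexity = 40, kde = TRUE,
                          file = NULL, seed = 1, gridSize = 50) {
  m <- t(profileMatrix(fps))
  Y <- tsneEmbed(m, perplexity = perplexity, seed = seed)
  coords <- data.frame(x = Y[, 1], y = Y[, 2],
                       label = if (is.null(labels)) NA_character_ else
                         as.character(labels),
                       protein_id = proteinIds(fps),
                       stringsAsFactors = FALSE)
  kdes <- list()
  outliers <- rep(FALSE, nrow(coords))
  if (kde && !is.null(labels)) {
    for (lab in setdiff(unique(coords$label), NA)) {
      idx <- which(coords$label == lab)
      if (length(idx) < 3) next
      pts <- coords[idx, c("x", "y")]
      keep <- abs(pts$x - mean(pts$x)) <= 2 * sd(pts$x) &
              abs(pts$y - mean(pts$y)) <= 2 * sd(pts$y)
      outliers[idx[!keep]] <- TRUE
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) < 3) next
      n <- nrow(pts)
      ## Scott's rule sigma * n^(-1/6) in 2-D; kde2d divides h by 4
      h <- 4 * c(sd(pts$x), sd(pts$y)) * n^(-1 / 6)
      h[h <= 0] <- 1e-3
      pad <- 3 * max(h)
      kdes[[lab]] <- MASS::kde2d(pts$x, pts$y, h = h, n = gridSize,
                                 lims = c(range(pts$x) + c(-pad, pad),
                                          range(pts$y) + c(-pad, pad)))
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 800)
    on.exit(grDevices::dev.off())
    labs <- factor(coords$label)
    cols <- grDevices::rainbow(max(1, nlevels(labs)))
    graphics::plot(coords$x, coords$y, pch = 19, cex = 0.7,
                   col = if (nlevels(labs)) cols[as.integer(labs)] else 1,
                   xlab = "tSNE 1", ylab = "tSNE 2")
    for (k in seq_along(kdes)) {
      graphics::contour(kdes[[k]], add = TRUE, col = cols[k], nlevels = 4,
                        drawlabels = FALSE)
    }
    if (nlevels(labs)) {
      graphics::legend("topright", legend = levels(labs), col = cols,
                       pch = 19, cex = 0.8)
    }
  }
  list(coords = coords, kdes = kdes, outliers = outliers)
}
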