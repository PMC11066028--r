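## Benchmark feature profiles against annotation standards:
## ranked co-annotation pairs (average precision, max F-score) and
## clustering agreement (adjusted mutual information).

#' Annotation standard
#'
#' Maps proteins to label sets (cellular component, bioprocess, pathway or
#' complex membership) together with the overlap rule that defines a
#' positive co-annotated pair: `exact` label-set equality (pathways,
#' complexes) or `half_overlap`, at least 50% of the labels shared
#' (GO-style standards with many labels per protein).
#'
#' @param mapping data.frame with columns `protein_id`, `label` (one row
#'   per annotation), or a named list of character label vectors.
#' @param name standard name.
#' @param rule overlap rule for positives.
#' @param halfDenominator for `half_overlap`: `"min"` requires
#'   `|A ∩ B| >= 0.5 * min(|A|, |B|)` (permissive default); `"jaccard"`
#'   requires Jaccard similarity >= 0.5.
#' @return An `AnnotationStandard` list.
#' @export
annotationStandard <- function(mapping, name = "standard",
                               rule = c("exact", "half_overlap"),
                               halfDenominator = c("min", "jaccard")) {
  rule <- match.arg(rule)
  halfDenominator <- match.arg(halfDenominator)
  if (is.data.frame(mapping)) {
    mapping <- split(as.character(mapping$label),
                     as.character(mapping$protein_id))
  }
  mapping <- lapply(mapping, unique)
  if (any(lengths(mapping) == 0)) stop("empty label set in standard")
  structure(list(name = name, mapping = mapping, rule = rule,
                 halfDenominator = halfDenominator),
            class = "AnnotationStandard")
}

#' Read an annotation standard from TSV
#' @param file TSV with columns protein_id, label (and optionally
#'   standard_name).
#' @param ... passed to [annotationStandard()].
#' @return An `AnnotationStandard`.
#' @export
readStandard <- function(file, ...) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  annotationStandard(df, ...)
}

isPositivePair <- function(A, B, rule, halfDenominator = "min") {
  if (rule == "exact") return(setequal(A, B))
  ov <- length(intersect(A, B))
  if (halfDenominator == "min") ov >= 0.5 * min(length(A), length(B)) && ov > 0
  else ov / length(union(A, B)) >= 0.5
}

#' Rank co-annotation pairs by profile distance
#'
#' All unordered pairs of annotated proteins, sorted by ascending
#' correlation distance (1 - Pearson) between their averaged feature
#' profiles, labeled positive/negative by the standard's overlap rule.
#' Unannotated proteins are left out.
#'
#' @param afps a [FeatureProfileSet-class] at level `"aFP"` (or a
#'   feature x protein matrix with column names).
#' @param standard an [annotationStandard()].
#' @return data.frame (protein_a, protein_b, distance, is_positive),
#'   ascending by distance.
#' @export
coannotationPairs <- function(afps, standard) {
  m <- if (is(afps, "FeatureProfileSet")) {
    x <- profileMatrix(afps); colnames(x) <- proteinIds(afps); x
  } else afps
  prots <- intersect(colnames(m), names(standard$mapping))
  if (length(prots) < 2) stop("need at least 2 annotated proteins")
  m <- m[, prots, drop = FALSE]
  D <- 1 - cor(m)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  pos <- vapply(seq_len(nrow(idx)), function(i) {
    isPositivePair(standard$mapping[[prots[idx[i, 1]]]],
                   standard$mapping[[prots[idx[i, 2]]]],
                   standard$rule, standard$halfDenominator)
  }, logical(1))
  out <- data.frame(protein_a = prots[idx[, 1]], protein_b = prots[idx[, 2]],
                    distance = D[idx], is_positive = pos,
                    stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Average precision of a ranked pair list
#'
#' Standard AP: the mean, over positive pairs, of the precision at the rank
#' where each positive is retrieved. Invariant to monotone transforms of
#' the distances.
#'
#' @param ranked data.frame from [coannotationPairs()] or a logical vector
#'   of positives in rank order.
#' @return AP in \[0, 1\]; error if there are no positives.
#' @export
averagePrecision <- function(ranked) {
  pos <- if (is.data.frame(ranked)) ranked$is_positive else as.logical(ranked)
  if (!any(pos)) stop("average precision undefined: no positive pairs")
  prec <- cumsum(pos) / seq_along(pos)
  mean(prec[pos])
}

#' Maximum F1 score over ranking cut points
#'
#' @inheritParams averagePrecision
#' @return max over cut points k of the F1 of "predict positive for the
#'   first k pairs".
#' @export
maxFScore <- function(ranked) {
  pos <- if (is.data.frame(ranked)) ranked$is_positive else as.logical(ranked)
  P <- sum(pos)
  if (P == 0) stop("F-score undefined: no positive pairs")
  tp <- cumsum(pos)
  f1 <- 2 * tp / (seq_along(pos) + P)
  max(f1)
}

## ---- adjusted mutual information --------------------------------------

entropyOf <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

mutualInfo <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  mi <- 0
  ai <- rowSums(tab); bj <- colSums(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (ai[i] * bj[j]))
  }
  mi
}

## Expected MI under the hypergeometric (permutation) model.
expectedMutualInfo <- function(a, b) {
  n <- length(a)
  ai <- as.integer(table(a)); bj <- as.integer(table(b))
  emi <- 0
  for (x in ai) for (y in bj) {
    lo <- max(1L, x + y - n); hi <- min(x, y)
    if (hi < lo) next
    for (nij in lo:hi) {
      lp <- lchoose(y, nij) + lchoose(n - y, x - nij) - lchoose(n, x)
      emi <- emi + exp(lp) * nij / n * log(n * nij / (x * y))
    }
  }
  emi
}

#' Adjusted mutual information between two labelings
#'
#' Chance-corrected agreement: `(MI - E[MI]) / (max(H(a), H(b)) - E[MI])`,
#' with the expectation under the permutation (hypergeometric) model and
#' max-entropy normalization.
#'
#' @param a,b label vectors of equal length.
#' @return AMI in (-1, 1\]; 1 for identical partitions, ~0 for independent
#'   ones.
#' @export
amiScore <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  mi <- mutualInfo(a, b)
  emi <- expectedMutualInfo(a, b)
  hmax <- max(entropyOf(a), entropyOf(b))
  denom <- hmax - emi
  if (abs(denom) < 1e-12) return(if (abs(mi - emi) < 1e-12) 1 else 0)
  unname((mi - emi) / denom)
}

#' AMI of hierarchical clusterings over a threshold grid
#'
#' Clusters averaged profiles by hierarchical clustering (average linkage,
#' correlation distance), cuts the tree at each threshold, drops clusters
#' of size < 2, and scores AMI against the standard's labels on the subset
#' of proteins with a single annotation.
#'
#' @param afps a [FeatureProfileSet-class] (aFP level) or labeled matrix.
#' @param standard an [annotationStandard()].
#' @param thresholds correlation-distance cut heights.
#' @return list with `best_ami`, `best_threshold` and `curve`
#'   (data.frame threshold, ami, n_clusters).
#' @export
amiOverThresholds <- function(afps, standard,
                              thresholds = seq(0.1, 0.95, by = 0.05)) {
  m <- if (is(afps, "FeatureProfileSet")) {
    x <- profileMatrix(afps); colnames(x) <- proteinIds(afps); x
  } else afps
  single <- names(standard$mapping)[lengths(standard$mapping) == 1]
  prots <- intersect(colnames(m), single)
  if (length(prots) < 2) {
    stop("need at least 2 singly-annotated proteins for AMI")
  }
  labels <- vapply(standard$mapping[prots], `[[`, character(1), 1)
  hc <- hclust(as.dist(1 - cor(m)), method = "average")
  curve <- do.call(rbind, lapply(thresholds, function(t) {
    cl <- cutree(hc, h = t)[match(prots, colnames(m))]
    sizes <- table(cl)
    keep <- cl %in% as.integer(names(sizes)[sizes >= 2])
    ami <- if (sum(keep) >= 2) amiScore(cl[keep], labels[keep]) else NA_real_
    data.frame(threshold = t, ami = ami, n_clusters = sum(sizes >= 2))
  }))
  if (all(is.na(curve$ami))) {
    warning("degenerate clustering at all thresholds")
    return(list(best_ami = NA_real_, best_threshold = NA_real_,
                curve = curve))
  }
  b <- which.max(curve$ami)
  list(best_ami = curve$ami[b], best_threshold = curve$threshold[b],
       curve = curve)
}
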