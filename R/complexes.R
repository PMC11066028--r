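## Functional-module discovery from single-cell feature profiles:
## adaptive dendrogram thresholding with plateau detection and the
## s = c * d / k score, pairwise-F1 benchmarking, fold enrichment, and
## baseline clustering grids (k-means, DBSCAN, flat hierarchical).

#' Trace a scFP dendrogram across thresholds
#'
#' Cuts the dendrogram top-to-bottom on a fixed grid of correlation
#' distance thresholds (step 0.05) and records flat cluster memberships
#' and unique-protein counts at each threshold.
#'
#' @param dend `hclust` over scFPs (see [profileDendrogram()]); must carry
#'   a `protein_id` attribute or `proteinIds` must be given.
#' @param step threshold grid step.
#' @param proteinIds per-leaf protein ids (defaults to the dendrogram
#'   attribute).
#' @return A `DendrogramTrace` list: `thresholds` (descending),
#'   `assignments` (list of integer membership vectors per threshold),
#'   `proteinIds`.
#' @export
traceDendrogram <- function(dend, step = 0.05, proteinIds = NULL) {
  if (is.null(proteinIds)) proteinIds <- attr(dend, "protein_id")
  stopifnot(!is.null(proteinIds))
  maxH <- max(dend$height)
  thresholds <- seq(ceiling(maxH / step) * step, step, by = -step)
  assignments <- lapply(thresholds, function(t) cutree(dend, h = t))
  structure(list(thresholds = thresholds, assignments = assignments,
                 proteinIds = as.character(proteinIds)),
            class = "DendrogramTrace")
}

#' Unique-protein counts per cluster along the trace
#' @param trace a `DendrogramTrace`.
#' @return data.frame (threshold, cluster, n_cells, n_proteins).
#' @export
traceProteinCounts <- function(trace) {
  do.call(rbind, lapply(seq_along(trace$thresholds), function(i) {
    cl <- trace$assignments[[i]]
    agg <- tapply(trace$proteinIds, cl, function(p)
      c(n_cells = length(p), n_proteins = length(unique(p))))
    data.frame(threshold = trace$thresholds[i],
               cluster = as.integer(names(agg)),
               n_cells = vapply(agg, `[[`, numeric(1), "n_cells"),
               n_proteins = vapply(agg, `[[`, numeric(1), "n_proteins"))
  }))
}

## Jaccard similarity of two protein sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Find root-cluster candidates (composition plateaus)
#'
#' Scans every cluster at every trace threshold. A cluster is a plateau
#' candidate when at least `plateauTolerance` of its composition (scFP
#' membership, i.e. cell-weighted protein composition) persists into its
#' largest child across each of the next `plateauSteps` evaluated
#' thresholds. Single-protein branches are not candidates (complex
#' discovery targets multi-protein clusters). Candidates are nested along
#' branches; [resolveRootClusters()] reduces them to disjoint scored
#' roots.
#'
#' @param trace a `DendrogramTrace`.
#' @param plateauTolerance composition fraction that must persist
#'   (default 0.95).
#' @param plateauSteps number of consecutive finer thresholds over which
#'   the composition must persist.
#' @return list of unscored plateau candidates (`members` = scFP indices,
#'   `proteins`, `threshold`, `level` = trace index); empty with a warning
#'   when no plateau exists.
#' @export
findRootClusters <- function(trace, plateauTolerance = 0.95,
                             plateauSteps = 2) {
  nT <- length(trace$thresholds)
  pid <- trace$proteinIds
  roots <- list()
  for (i in seq_len(max(0, nT - plateauSteps))) {
    cl <- trace$assignments[[i]]
    for (c in unique(cl)) {
      mem <- which(cl == c)
      prots <- unique(pid[mem])
      if (length(prots) < 2) next
      stable <- TRUE
      cur <- mem
      for (s in seq_len(plateauSteps)) {
        sub <- trace$assignments[[i + s]][cur]
        big <- as.integer(names(which.max(table(sub))))
        child <- cur[sub == big]
        ## per-transition persistence of the composition
        if (length(child) / length(cur) < plateauTolerance) {
          stable <- FALSE
          break
        }
        cur <- child
      }
      if (stable) {
        roots[[length(roots) + 1]] <-
          list(members = mem, proteins = prots,
               threshold = trace$thresholds[i], level = i)
      }
    }
  }
  if (!length(roots)) warning("no plateau root clusters found")
  roots
}

#' Resolve plateau candidates into disjoint scored roots
#'
#' Scores every candidate ([scoreRootCluster()]) and greedily keeps the
#' highest-scoring ones whose scFP memberships do not overlap an already
#' accepted root, so nested plateau candidates along a branch resolve to
#' the best-scoring cut.
#'
#' @param candidates list from [findRootClusters()].
#' @param trace the `DendrogramTrace`.
#' @param ... passed to [scoreRootCluster()].
#' @return list of disjoint scored roots, sorted by score descending.
#' @export
resolveRootClusters <- function(candidates, trace, ...) {
  scored <- lapply(candidates, scoreRootCluster, trace = trace, ...)
  ord <- order(-vapply(scored, `[[`, numeric(1), "s"))
  taken <- logical(length(trace$proteinIds))
  out <- list()
  for (i in ord) {
    r <- scored[[i]]
    if (any(taken[r$members])) next
    taken[r$members] <- TRUE
    out[[length(out) + 1]] <- r
  }
  out
}

#' Score a root cluster
#'
#' Cell ratio `c`: mean over member proteins of the fraction of that
#' protein's scFPs captured by the cluster. Elbow point `k`: the
#' correlation distance at the root cut (floored at `kFloor` for
#' identical-profile clusters). Descendant ratio `d`: among flat clusters
#' at the next `descendantSteps` finer thresholds that contain at least
#' one scFP of the root's proteins, the cell-weighted fraction annotated
#' to the root — a descendant agrees when at least 50% of its scFPs lie
#' inside the root AND its protein composition still matches the root's
#' (protein-set Jaccard > 0.5). Pure or partitioned descendants signal
#' that the root is morphologically separable, which lowers `d`; cell
#' weighting makes a supercluster's large divergent halves count fully
#' while a genuine complex's occasional tiny pure fragments barely
#' register. Final score `s = c * d / k`.
#'
#' @param root one root from [findRootClusters()].
#' @param trace the `DendrogramTrace`.
#' @param descendantSteps finer thresholds over which descendants are
#'   collected; the default `Inf` surveys the whole remaining trace, so a
#'   root that eventually resolves into pure per-protein fragments is
#'   penalized even when the split happens several levels down.
#' @param kFloor lower bound for k.
#' @return The root augmented with `c`, `d`, `k`, `s` and `n_proteins`.
#' @export
scoreRootCluster <- function(root, trace, descendantSteps = Inf,
                             kFloor = 1e-4) {
  if (length(root$proteins) < 2) stop("root must contain >= 2 proteins")
  pid <- trace$proteinIds
  inRoot <- logical(length(pid))
  inRoot[root$members] <- TRUE
  cfrac <- vapply(root$proteins, function(p) {
    ofP <- pid == p
    sum(ofP & inRoot) / sum(ofP)
  }, numeric(1))
  cc <- mean(cfrac)
  rootProt <- pid %in% root$proteins
  agree <- 0; total <- 0
  maxSteps <- min(descendantSteps, length(trace$thresholds) - root$level)
  for (s in seq_len(maxSteps)) {
    li <- root$level + s
    cl <- trace$assignments[[li]]
    for (c in unique(cl[rootProt])) {
      mem <- which(cl == c)
      total <- total + length(mem)
      if (mean(inRoot[mem]) >= 0.5 &&
          jaccard(unique(pid[mem]), root$proteins) > 0.5) {
        agree <- agree + length(mem)
      }
    }
  }
  d <- if (total > 0) agree / total else 0
  k <- max(root$threshold, kFloor)
  if (root$threshold <= kFloor) {
    fsLog("root cut at distance <= ", kFloor, "; k floored")
  }
  root$c <- cc; root$d <- d; root$k <- k
  root$s <- cc * d / k
  root$n_proteins <- length(root$proteins)
  root
}

#' Filter high-confidence clusters
#' @param roots list of scored roots.
#' @param cutoff minimal final score s (default 0.6).
#' @return Scored roots with `s >= cutoff`, sorted by s descending.
#' @export
highConfidenceClusters <- function(roots, cutoff = 0.6) {
  s <- vapply(roots, `[[`, numeric(1), "s")
  keep <- roots[s >= cutoff]
  keep[order(-vapply(keep, `[[`, numeric(1), "s"))]
}

#' Pairwise F1 of a clustering against a complex standard
#'
#' Every pair of scFPs is labeled positive when both belong to proteins of
#' the same complex, and predicted positive when both sit in the same
#' cluster; precision, recall and F1 are computed over all pairs.
#'
#' @param clusterIds per-scFP cluster assignment (NA = unclustered).
#' @param complexIds per-scFP complex membership of the protein (NA = not
#'   in the standard).
#' @return list(precision, recall, F1, TP, predicted_pairs,
#'   positive_pairs).
#' @export
pairwiseComplexF1 <- function(clusterIds, complexIds) {
  pairsOf <- function(x) sum(choose(table(x[!is.na(x)]), 2))
  positives <- pairsOf(complexIds)
  if (positives == 0) stop("standard contains no co-complex pair")
  predicted <- pairsOf(clusterIds)
  joint <- paste(clusterIds, complexIds, sep = "\r")
  joint[is.na(clusterIds) | is.na(complexIds)] <- NA
  tp <- pairsOf(joint)
  precision <- if (predicted > 0) tp / predicted else 0
  recall <- tp / positives
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, F1 = f1, TP = tp,
       predicted_pairs = predicted, positive_pairs = positives)
}

## Median over clusters of the best set-overlap F1 against any complex
## (the per-cluster benchmark used for method comparison).
medianClusterF1 <- function(clusterIds, complexIds) {
  cls <- setdiff(unique(clusterIds), NA)
  cxs <- setdiff(unique(complexIds), NA)
  if (!length(cls) || !length(cxs)) return(0)
  f1s <- vapply(cls, function(cl) {
    inC <- which(clusterIds == cl)
    max(vapply(cxs, function(cx) {
      inX <- which(complexIds == cx)
      tp <- length(intersect(inC, inX))
      if (tp == 0) return(0)
      p <- tp / length(inC); r <- tp / length(inX)
      2 * p * r / (p + r)
    }, numeric(1)))
  }, numeric(1))
  stats::median(f1s)
}

#' Fold enrichment of a cluster in a complex standard
#'
#' One-sided Fisher's exact test of the cluster's proteins against each
#' complex, with a same-localization background set; fold =
#' (hits / cluster size) / (complex size / background size). The
#' best-enriched complex is reported.
#'
#' @param clusterProteins character vector of the cluster's proteins.
#' @param standard named list complex_id -> protein set.
#' @param background protein universe (must contain the cluster).
#' @return list(best_complex, fold, p, table of all complexes).
#' @export
foldEnrichment <- function(clusterProteins, standard, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  if (!all(clusterProteins %in% background)) {
    stop("background must contain all cluster proteins")
  }
  n <- length(background)
  k <- length(clusterProteins)
  rows <- lapply(names(standard), function(cx) {
    cxp <- intersect(standard[[cx]], background)
    hits <- length(intersect(clusterProteins, cxp))
    fold <- if (length(cxp)) (hits / k) / (length(cxp) / n) else NA_real_
    tab <- matrix(c(hits, k - hits, length(cxp) - hits,
                    n - k - length(cxp) + hits), 2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(complex_id = cx, hits = hits, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best <- order(-tab$fold, tab$p)[1]
  list(best_complex = tab$complex_id[best], fold = tab$fold[best],
       p = tab$p[best], table = tab)
}

## ---- baselines ---------------------------------------------------------

## Plain DBSCAN on a precomputed distance matrix (no dbscan package in
## the supported stack; O(n^2) is fine at these scales). Returns cluster
## ids with NA for noise points.
dbscanClusters <- function(D, eps, minPts = 5) {
  n <- nrow(D)
  adj <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(adj) >= minPts
  labels <- rep(NA_integer_, n)
  visited <- logical(n)
  cl <- 0
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (visited[j]) {
        if (is.na(labels[j])) labels[j] <- cl
        next
      }
      visited[j] <- TRUE
      labels[j] <- cl
      if (core[j]) queue <- c(queue, adj[[j]][!visited[adj[[j]]]])
    }
  }
  labels
}

#' Baseline clustering grids for complex discovery
#'
#' Benchmarks the adaptive-thresholding clusters against three clustering
#' families on the same scFPs: k-means (k from 5 to 500, step 5), DBSCAN
#' (epsilon from 0.1 to 5, step 0.1) and flat hierarchical clustering
#' (correlation threshold from 0.05 to 0.5, step 0.025). Grids are clipped
#' to the dataset size. Each method reports the hyperparameter maximizing
#' the median per-cluster F1 against the complex standard.
#'
#' @param scfps a [FeatureProfileSet-class] (scFP level).
#' @param complexIds per-scFP complex ids (NA = not in the standard).
#' @param minPts DBSCAN minimum neighborhood size.
#' @return list with `best` (data.frame method, parameter, median_F1,
#'   pairwise_F1) and `grids` (per-method full tables).
#' @export
baselineGrid <- function(scfps, complexIds, minPts = 5) {
  X <- t(profileMatrix(scfps))
  n <- nrow(X)
  evalCl <- function(cl) {
    c(median_F1 = medianClusterF1(cl, complexIds),
      pairwise_F1 = tryCatch(pairwiseComplexF1(cl, complexIds)$F1,
                             error = function(e) NA_real_))
  }
  kGrid <- seq(5, 500, by = 5)
  kGrid <- kGrid[kGrid <= n - 1]
  if (!length(kGrid)) stop("k-means grid empty after clipping")
  kmTab <- do.call(rbind, lapply(kGrid, function(k) {
    cl <- withSeed(k, kmeans(X, centers = k, nstart = 1,
                             iter.max = 30)$cluster)
    data.frame(parameter = k, t(evalCl(cl)))
  }))
  D <- as.matrix(dist(X))
  eGrid <- seq(0.1, 5, by = 0.1)
  dbTab <- do.call(rbind, lapply(eGrid, function(eps) {
    cl <- dbscanClusters(D, eps, minPts)
    data.frame(parameter = eps, t(evalCl(cl)))
  }))
  Dc <- 1 - cor(t(X))
  hcl <- hclust(as.dist(Dc), method = "average")
  hGrid <- seq(0.05, 0.5, by = 0.025)
  hcTab <- do.call(rbind, lapply(hGrid, function(t) {
    cl <- cutree(hcl, h = t)
    ## singleton clusters carry no pair information
    sizes <- table(cl)
    cl[cl %in% as.integer(names(sizes)[sizes < 2])] <- NA
    data.frame(parameter = t, t(evalCl(cl)))
  }))
  pickBest <- function(tab, method) {
    b <- which.max(tab$median_F1)
    data.frame(method = method, parameter = tab$parameter[b],
               median_F1 = tab$median_F1[b],
               pairwise_F1 = tab$pairwise_F1[b], stringsAsFactors = FALSE)
  }
  best <- rbind(pickBest(kmTab, "kmeans"), pickBest(dbTab, "dbscan"),
                pickBest(hcTab, "hierarchical"))
  list(best = best, grids = list(kmeans = kmTab, dbscan = dbTab,
                                 hierarchical = hcTab))
}
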