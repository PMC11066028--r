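## profiles with planted scFP blobs: proteins A, B share a blob (complex),
## C and D have their own, E is diffuse noise
plantedScfps <- function(perProt = 12, seed = 1) {
  set.seed(seed)
  d <- 10
  centers <- list(AB = rnorm(d, sd = 3), C = rnorm(d, sd = 3),
                  D = rnorm(d, sd = 3))
  mk <- function(center, n, sd = 0.05) {
    matrix(center, d, n) + matrix(rnorm(d * n, sd = sd), d, n)
  }
  prof <- cbind(mk(centers$AB, perProt), mk(centers$AB, perProt),
                mk(centers$C, perProt), mk(centers$D, perProt),
                matrix(rnorm(d * perProt, sd = 3), d, perProt))
  pid <- rep(c("A", "B", "C", "D", "E"), each = perProt)
  colnames(prof) <- paste0(pid, "_", seq_len(ncol(prof)))
  fps <- FeatureProfileSet(prof, data.frame(protein_id = pid,
                                            crop_id = colnames(prof)),
                           level = "scFP")
  fps
}

test_that("dendrogram tracing matches brute-force flat clustering", {
  fps <- plantedScfps()
  dend <- profileDendrogram(fps)
  tr <- traceDendrogram(dend, step = 0.05)
  expect_true(all(diff(tr$thresholds) < 0))
  for (i in c(1, length(tr$thresholds) %/% 2, length(tr$thresholds))) {
    expect_equal(tr$assignments[[i]],
                 cutree(dend, h = tr$thresholds[i]))
  }
  ## protein counts are non-increasing when descending inside a branch
  counts <- traceProteinCounts(tr)
  for (i in seq_len(length(tr$thresholds) - 1)) {
    cl <- tr$assignments[[i]]
    nxt <- tr$assignments[[i + 1]]
    for (c in unique(cl)) {
      parentN <- length(unique(tr$proteinIds[cl == c]))
      for (cc in unique(nxt[cl == c])) {
        childN <- length(unique(tr$proteinIds[nxt == cc & cl == c]))
        expect_lte(childN, parentN)
      }
    }
  }
})

test_that("a singleton dataset produces a single trivial trace", {
  m <- matrix(rnorm(20), 10, 2)
  fps <- FeatureProfileSet(m, data.frame(protein_id = c("A", "A"),
                                         crop_id = c("c1", "c2")),
                           level = "scFP")
  tr <- traceDendrogram(profileDendrogram(fps), step = 0.05)
  expect_true(all(vapply(tr$assignments, max, numeric(1)) <= 2))
})

test_that("planted tight blobs yield exactly the planted roots", {
  fps <- plantedScfps()
  dend <- profileDendrogram(fps)
  tr <- traceDendrogram(dend, step = 0.05)
  cand <- findRootClusters(tr)
  roots <- resolveRootClusters(cand, tr)
  hi <- highConfidenceClusters(roots, cutoff = 0.6)
  protSets <- lapply(hi, function(r) sort(r$proteins))
  expect_true(list(c("A", "B")) %in% protSets ||
                any(vapply(protSets, identical, logical(1), c("A", "B"))))
  ## no root mixes the C and D blobs
  expect_false(any(vapply(protSets, function(s)
    all(c("C", "D") %in% s), logical(1))))
})

test_that("uniformly spread scFPs produce no roots", {
  set.seed(4)
  m <- matrix(rnorm(10 * 40, sd = 3), 10, 40)
  pid <- rep(paste0("P", 1:8), each = 5)
  fps <- FeatureProfileSet(m, data.frame(protein_id = pid,
                                         crop_id = paste0("c", 1:40)),
                           level = "scFP")
  tr <- traceDendrogram(profileDendrogram(fps), step = 0.05)
  cand <- suppressWarnings(findRootClusters(tr, plateauTolerance = 0.999))
  roots <- resolveRootClusters(cand, tr)
  ## accidental micro-plateaus in noise score far below the 0.6 cutoff
  hi <- highConfidenceClusters(roots, cutoff = 0.6)
  expect_equal(length(hi), 0)
})

test_that("plateaus survive small membership churn", {
  ## hand-built trace: a 25-cell cluster losing 1 cell (4%) per step
  assigns <- list(
    c(rep(1L, 25), rep(2L, 5)),
    c(rep(1L, 24), 3L, rep(2L, 5)),
    c(rep(1L, 23), 4L, 3L, rep(2L, 5)))
  tr <- structure(list(thresholds = c(0.3, 0.25, 0.2),
                       assignments = assigns,
                       proteinIds = rep(c("A", "B", "X"), c(13, 12, 5))),
                  class = "DendrogramTrace")
  cand <- findRootClusters(tr, plateauTolerance = 0.95, plateauSteps = 2)
  sizes <- vapply(cand, function(r) length(r$members), integer(1))
  expect_true(25 %in% sizes) # 24/25 and 23/24 both >= 95%
})

test_that("root scoring computes c, d, k and s = c*d/k exactly", {
  ## 2 proteins x 10 cells; root at threshold 0.2 contains 9 of A's and
  ## 9 of B's cells -> c = 0.9. At each finer threshold the descendants
  ## carrying 16 of the 20 relevant cells are mixed clusters inside the
  ## root (agree); a pure 1-cell fragment per protein and the 2-cell
  ## outside cluster disagree -> cell-weighted d = 16/20 = 0.8.
  rootCells <- c(1:9, 11:19) # A = 1:10, B = 11:20
  lvl <- integer(20)
  lvl[c(1:4, 11:14)] <- 1L  # mixed, inside (8 cells, agree)
  lvl[c(5:8, 15:18)] <- 2L  # mixed, inside (8 cells, agree)
  lvl[9] <- 3L              # pure A fragment (Jaccard 0.5, disagree)
  lvl[19] <- 4L             # pure B fragment (disagree)
  lvl[c(10, 20)] <- 5L      # outside the root (disagree)
  tr <- structure(list(
    thresholds = c(0.2, 0.15, 0.1),
    assignments = list(ifelse(seq_len(20) %in% rootCells, 1L, 2L),
                       lvl, lvl),
    proteinIds = rep(c("A", "B"), each = 10)),
    class = "DendrogramTrace")
  root <- list(members = rootCells, proteins = c("A", "B"),
               threshold = 0.2, level = 1)
  scored <- scoreRootCluster(root, tr)
  expect_equal(scored$c, 0.9)
  expect_equal(scored$d, 0.8)
  expect_equal(scored$k, 0.2)
  expect_equal(scored$s, 0.9 * 0.8 / 0.2) # = 3.6
  ## limit case: everything inside, all descendants agree -> s = 1/k
  rootAll <- list(members = 1:20, proteins = c("A", "B"),
                  threshold = 0.2, level = 1)
  trAll <- structure(list(
    thresholds = c(0.2, 0.15, 0.1),
    assignments = list(rep(1L, 20), rep(1:2, 10), rep(1:4, 5)),
    proteinIds = rep(c("A", "B"), each = 10)),
    class = "DendrogramTrace")
  sAll <- scoreRootCluster(rootAll, trAll)
  expect_equal(c(sAll$c, sAll$d), c(1, 1))
  expect_equal(sAll$s, 1 / 0.2)
  expect_error(scoreRootCluster(list(members = 1:3, proteins = "A",
                                     threshold = 0.1, level = 1), tr),
               ">= 2 proteins")
})

test_that("high-confidence filtering applies the 0.6 score cutoff", {
  roots <- list(list(s = 3.6, members = 1), list(s = 0.59, members = 2),
                list(s = 0.7, members = 3))
  expect_equal(length(highConfidenceClusters(roots, 0.6)), 2)
  expect_equal(vapply(highConfidenceClusters(roots, 0.6), `[[`,
                      numeric(1), "s"), c(3.6, 0.7))
  expect_equal(length(highConfidenceClusters(roots, 0)), 3)
  expect_equal(length(highConfidenceClusters(roots, 10)), 0)
})

test_that("pairwise F1 agrees with hand-counted pair confusion", {
  ## 6 scFPs: complexes X = {1,2,3}, Y = {4,5}; 6 unannotated
  cx <- c("X", "X", "X", "Y", "Y", NA)
  ## clustering puts {1,2} together, {3,4,5} together, 6 alone
  cl <- c(1, 1, 2, 2, 2, NA)
  out <- pairwiseComplexF1(cl, cx)
  ## positives: C(3,2) + C(2,2) = 4; predicted: C(2,2) + C(3,2) = 4
  ## TP: pair (1,2) from X; pair (4,5) from Y = 2
  expect_equal(out$positive_pairs, 4)
  expect_equal(out$predicted_pairs, 4)
  expect_equal(out$TP, 2)
  expect_equal(out$precision, 0.5)
  expect_equal(out$recall, 0.5)
  expect_equal(out$F1, 0.5)
  ## perfect clustering
  perf <- pairwiseComplexF1(c(1, 1, 1, 2, 2, NA), cx)
  expect_equal(perf$F1, 1)
  ## all singletons: no predicted pairs, recall 0
  sing <- pairwiseComplexF1(rep(NA, 6), cx)
  expect_equal(sing$recall, 0)
  expect_equal(sing$F1, 0)
  expect_error(pairwiseComplexF1(cl, rep(NA, 6)), "no co-complex")
})

test_that("fold enrichment and Fisher p match exact computation", {
  background <- paste0("P", 1:40)
  complexSet <- list(CPX = paste0("P", 1:4))
  cluster <- paste0("P", 1:4)
  fe <- foldEnrichment(cluster, complexSet, background)
  expect_equal(fe$fold, (4 / 4) / (4 / 40)) # = 10
  ## disjoint cluster: fold <= 1 against every complex
  fe2 <- foldEnrichment(paste0("P", 30:33), complexSet, background)
  expect_lte(fe2$fold, 1)
  ## Fisher one-sided p equals the exact hypergeometric tail sum
  tab <- matrix(c(3, 1, 2, 34), 2, 2)
  pR <- fisher.test(tab, alternative = "greater")$p.value
  ## P(X >= 3) with X ~ Hypergeom(white = 5, black = 35, drawn = 4)
  tail <- sum(vapply(3:4, function(k) {
    choose(5, k) * choose(35, 4 - k) / choose(40, 4)
  }, numeric(1)))
  expect_equal(pR, tail, tolerance = 1e-9)
  expect_error(foldEnrichment("Q", complexSet, background), "background")
})

test_that("baseline grids enumerate the prescribed hyperparameters", {
  fps <- plantedScfps(perProt = 6, seed = 5)
  cx <- setNames(c("CPX1", "CPX1", NA, NA, NA), c("A", "B", "C", "D", "E"))
  cxIds <- cx[proteinIds(fps)]
  out <- baselineGrid(fps, cxIds)
  n <- ncol(fps)
  expect_equal(out$grids$kmeans$parameter,
               seq(5, 500, by = 5)[seq(5, 500, by = 5) <= n - 1])
  expect_equal(out$grids$dbscan$parameter, seq(0.1, 5, by = 0.1))
  expect_equal(out$grids$hierarchical$parameter, seq(0.05, 0.5, by = 0.025))
  expect_setequal(out$best$method, c("kmeans", "dbscan", "hierarchical"))
})

test_that("k-means at the planted complex count is near-perfect", {
  ## two tight blobs, each a complex: k = 2 recovers them exactly
  prof <- profileBlobs(k = 2, m = 12, d = 10, sd = 0.05, seed = 6)
  pid <- rep(c("A", "B", "C", "D"), each = 6)
  cxIds <- setNames(rep(c("CPX1", "CPX2"), each = 12), NULL)
  cl <- kmeans(t(prof), centers = 2, nstart = 5)$cluster
  expect_equal(medianClusterF1(cl, cxIds), 1)
  expect_equal(pairwiseComplexF1(cl, cxIds)$F1, 1)
})
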