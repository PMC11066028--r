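## Shared fixtures. Heavy artifacts (trained networks) are built once per
## test run, lazily, and memoized in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## Small deterministic profile blobs: `k` clusters of `m` profiles each in
## `d` dimensions, cluster centers far apart, within-cluster noise `sd`.
profileBlobs <- function(k = 2, m = 5, d = 8, sd = 0.05, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d, sd = 3), k, d)
  prof <- do.call(cbind, lapply(seq_len(k), function(i) {
    matrix(centers[i, ], d, m) + matrix(rnorm(d * m, sd = sd), d, m)
  }))
  colnames(prof) <- paste0("B", rep(seq_len(k), each = m), "_", rep(seq_len(m), k))
  prof
}

## The demonstration panel used throughout the acceptance-level tests:
## 12 proteins over 4 well-separated archetypes, 2 planted complexes of 3,
## 2 AND + 2 OR proteins, ~100 cells each, reduced identity network.
demoFixture <- function() {
  memo("demo", function() {
    cfg <- defaultPipelineConfig(seed = 101)
    t0 <- Sys.time()
    res <- runPipeline(cfg)
    res$train_minutes <- as.numeric(Sys.time() - t0, units = "mins")
    c(res, demoDerivedQuantities(res))
  })
}

## Quantities the acceptance properties need beyond the pipeline report:
## the random-network baselines (linear-probe gap, ranked-pair AP) and the
## SmoothGrad foreground-mass fraction on a punctate protein.
demoDerivedQuantities <- function(res, smoothN = 100) {
  crops <- res$crops
  info <- cropInfo(crops)
  arch <- setNames(sapply(res$panel, `[[`, "archetype"),
                   sapply(res$panel, `[[`, "protein_id"))
  hetero <- setNames(sapply(res$panel, `[[`, "heterogeneity"), names(arch))
  singles <- names(hetero)[hetero == "single"]

  rndCfg <- do.call(networkConfig, modifyList(
    res$net@config[intersect(names(res$net@config),
                             names(formals(networkConfig)))],
    list(seed = 4242)))
  rndNet <- buildNetwork(rndCfg)

  probeAcc <- function(net) {
    sc <- extractProfiles(net, crops)
    f <- t(profileMatrix(sc))
    trI <- info$split == "train" & info$protein_id %in% singles
    teI <- info$split == "test" & info$protein_id %in% singles
    head <- trainLocalizationHead(f[trI, , drop = FALSE],
                                  arch[info$protein_id[trI]],
                                  epochs = 20, batchSize = 32, seed = 5)
    P <- predictLocalization(head, f[teI, , drop = FALSE])
    mean(colnames(P)[max.col(P, ties.method = "first")] ==
           arch[info$protein_id[teI]])
  }
  trainedAcc <- probeAcc(res$net)
  randomAcc <- probeAcc(rndNet)

  ## random-network aFPs on the ranked-pair benchmark
  stdRows <- do.call(rbind, lapply(res$panel, function(s) {
    data.frame(protein_id = s$protein_id,
               label = unique(c(s$archetype, s$secondary)))
  }))
  std <- annotationStandard(stdRows, rule = "exact")
  teAll <- crops[info$split == "test"]
  rndAfps <- averageProfiles(extractProfiles(rndNet, teAll))
  randomAP <- averagePrecision(coannotationPairs(rndAfps, std))

  ## SmoothGrad mass inside the true foreground of a punctate protein
  punct <- singles[arch[singles] == "punctate"][1]
  pIdx <- which(info$protein_id == punct & info$split == "test")
  pIdx <- utils::head(pIdx, 8)
  sc <- extractProfiles(res$net, crops[pIdx])
  fm <- profileMatrix(sc)
  mass <- vapply(seq_along(pIdx), function(j) {
    x <- cropArray(crops)[, , 1, pIdx[j]]
    xn <- (x - mean(x)) / sqrt(max(mean(x^2) - mean(x)^2, 1e-12))
    msk <- cropArray(crops)[, , 4, pIdx[j]] > 0.5
    feat <- which.max(abs(fm[, j]))
    g <- smoothGradMap(res$net, xn, feat, n = smoothN, sigma = 0.05,
                       seed = 6 + j)
    sum(abs(g)[msk]) / sum(abs(g))
  }, numeric(1))

  list(probeGap = trainedAcc - randomAcc,
       probeTrainedAcc = trainedAcc, probeRandomAcc = randomAcc,
       randomAP = randomAP, gradientMassInMask = mean(mass))
}

## Cell-cycle fixture: an ensemble trained on the demo crops' true stages
## plus a planted cell-cycle-dependent protein (nuclear in G1/S/T,
## cytoplasmic in MA).
ccFixture <- function() {
  memo("cc", function() {
    demo <- demoFixture()
    crops <- demo$crops
    ens <- trainCellCycleEnsemble(crops, nConvBlocks = 4, baseWidth = 8,
                                  fcHidden = 32, epochs = 10,
                                  augment = "dihedral", seed = 202)
    spec <- proteinPanel(1, seed = 33,
                         archetypes = c("nucleus", "cytoplasm"),
                         nCellCycle = 1)[[1]]
    ds <- generateDataset(structure(list(spec), class = "ProteinPanel"),
                          cellsPerProtein = 200, replicates = 2,
                          fieldsPerReplicate = 4, seed = 44)
    ccCrops <- prepareCrops(ds, seed = 45)
    list(ensemble = ens, ccCrops = ccCrops, spec = spec)
  })
}

expect_close <- function(a, b, tol = 1e-9) {
  testthat::expect_lt(max(abs(a - b)), tol)
}
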