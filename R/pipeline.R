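## End-to-end orchestration: simulate -> prep -> train -> extract ->
## benchmark -> hierarchy -> locmap -> heterogeneity -> complexes, driven
## by one (YAML-able) configuration with a global seed.

#' Default pipeline configuration
#'
#' The demonstration configuration: a 12-protein panel over 4 archetypes
#' with 2 planted complexes and 2 AND + 2 OR proteins, ~100 cells per
#' protein over 2 replicates x 4 fields, and a reduced identity network
#' (2 conv blocks, 16-dimensional feature profiles) sized for a single
#' CPU.
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = seed,
    stages = c("synthio", "prep", "train", "extract", "benchmark",
               "hierarchy", "heterogeneity", "complexes"),
    synthio = list(nProteins = 12, nComplexes = 2,
                   hetFractions = c(AND = 2 / 12, OR = 2 / 12),
                   archetypes = c("nucleus", "cytoplasm", "punctate",
                                  "peripheral-ring"),
                   cellsPerProtein = 100, replicates = 2,
                   fieldsPerReplicate = 4, noiseSd = 0.02),
    prep = list(cropSize = 64, margin = 10, intensityPercentile = 5,
                varianceFloor = 1e-4, minCells = 10, ratios = c(8, 1, 1)),
    train = list(nConvBlocks = 2, featureDim = 16, baseWidth = 8,
                 poolAfter = c(1, 2), fcHidden = 64, dropout = 0.05,
                 lr = 1e-3, epochs = 15, batchSize = 128),
    locmap = list(epochs = 20, batchSize = 32),
    heterogeneity = list(alphaConf = 0.5, beta = 0.5, orThreshold = 0.08,
                         undeterminedFraction = 0.5),
    complexes = list(step = 0.05, plateauTolerance = 0.95, cutoff = 0.6)
  )
}

#' Read and validate a pipeline configuration from YAML
#' @param file YAML file; missing fields fall back to
#'   [defaultPipelineConfig()] values.
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(file) {
  usr <- yaml::read_yaml(file)
  cfg <- defaultPipelineConfig(seed = if (!is.null(usr$seed)) usr$seed else 1)
  for (sec in intersect(names(usr), names(cfg))) {
    if (is.list(cfg[[sec]])) {
      for (nm in names(usr[[sec]])) cfg[[sec]][[nm]] <- usr[[sec]][[nm]]
    } else {
      cfg[[sec]] <- usr[[sec]]
    }
  }
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  stopifnot(is.numeric(cfg$seed),
            cfg$synthio$nProteins >= 2,
            cfg$synthio$cellsPerProtein >= 1,
            cfg$prep$intensityPercentile > 0,
            cfg$prep$intensityPercentile < 100,
            cfg$train$featureDim >= 1,
            cfg$heterogeneity$alphaConf >= 0,
            cfg$heterogeneity$alphaConf <= 1)
  invisible(TRUE)
}

#' Run the full workflow
#'
#' Executes the toggled stages in order on synthetic data and writes CSV/
#' TSV outputs (each with a provenance header carrying the configuration
#' hash and seed) into `outDir`.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or a
#'   YAML path.
#' @param outDir output directory (created if needed); NULL keeps results
#'   in memory only.
#' @param verbose print stage progress.
#' @return Run report list: per-stage key metrics plus the main artifacts
#'   (crops, net, profiles, calls, clusters).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL,
                        verbose = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  hash <- configHash(config)
  seed <- config$seed
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  say <- function(...) if (verbose) message("[stage] ", ...)
  report <- list(config_hash = hash, seed = seed)
  st <- config$stages

  say("synthio")
  sy <- config$synthio
  panel <- proteinPanel(sy$nProteins, nComplexes = sy$nComplexes,
                        hetFractions = sy$hetFractions,
                        archetypes = sy$archetypes,
                        seed = deriveSeed(seed, 1))
  dataset <- generateDataset(panel, cellsPerProtein = sy$cellsPerProtein,
                             replicates = sy$replicates,
                             fieldsPerReplicate = sy$fieldsPerReplicate,
                             noiseSd = sy$noiseSd,
                             seed = deriveSeed(seed, 2))
  report$synthio <- list(n_cells = nrow(dataset$manifest),
                         n_proteins = sy$nProteins)
  out <- list(panel = panel, dataset = dataset)
  if (!"prep" %in% st) return(c(report, out))

  say("prep")
  pp <- config$prep
  crops <- prepareCrops(dataset, cropSize = pp$cropSize, margin = pp$margin,
                        intensityPercentile = pp$intensityPercentile,
                        varianceFloor = pp$varianceFloor,
                        minCells = pp$minCells, ratios = pp$ratios,
                        seed = deriveSeed(seed, 3))
  report$prep <- list(n_crops = length(crops),
                      n_rejected = nrow(attr(crops, "rejected")))
  out$crops <- crops
  if (!"train" %in% st) return(c(report, out))

  say("train")
  tr <- config$train
  cfg <- networkConfig(nClasses = length(unique(cropInfo(crops)$protein_id)),
                       nConvBlocks = tr$nConvBlocks,
                       featureDim = tr$featureDim, baseWidth = tr$baseWidth,
                       poolAfter = tr$poolAfter, fcHidden = tr$fcHidden,
                       dropout = tr$dropout, lr = tr$lr, epochs = tr$epochs,
                       batchSize = tr$batchSize, seed = deriveSeed(seed, 4))
  net <- buildNetwork(cfg)
  net <- trainNetwork(net, crops, verbose = verbose)
  report$train <- list(
    epochs = nrow(net@history), selected_epoch = net@selectedEpoch,
    test_accuracy = net@history$test_acc[net@selectedEpoch])
  out$net <- net
  if (!is.null(outDir)) {
    writeTableWithHeader(net@history, file.path(outDir, "history.csv"),
                         hash, seed)
  }
  if (!"extract" %in% st) return(c(report, out))

  say("extract")
  testCrops <- crops[cropInfo(crops)$split == "test"]
  scfps <- extractProfiles(net, testCrops)   # benchmark hygiene: test split
  afps <- averageProfiles(scfps)
  scfpsAll <- extractProfiles(net, crops)    # analysis stages: all crops
  afpsAll <- averageProfiles(scfpsAll)
  out$scfps <- scfps
  out$afps <- afps
  out$scfpsAll <- scfpsAll
  out$afpsAll <- afpsAll
  if (!is.null(outDir)) {
    writeProfileCsv(scfps, file.path(outDir, "scfp.csv"), hash, seed)
    writeProfileCsv(afps, file.path(outDir, "afp.csv"), hash, seed)
  }

  archLabels <- setNames(
    vapply(panel, `[[`, character(1), "archetype"),
    vapply(panel, `[[`, character(1), "protein_id"))
  hetero <- setNames(vapply(panel, `[[`, character(1), "heterogeneity"),
                     names(archLabels))
  singleProts <- names(hetero)[hetero == "single"]
  ## AND/OR proteins are annotated with both compartments, so the
  ## single-annotation evaluation subset is exactly the single-localizers
  stdRows <- do.call(rbind, lapply(panel, function(s) {
    labs <- unique(c(s$archetype, s$secondary))
    data.frame(protein_id = s$protein_id, label = labs,
               stringsAsFactors = FALSE)
  }))
  standard <- annotationStandard(stdRows, name = "archetypes",
                                 rule = "exact")

  if ("benchmark" %in% st) {
    say("benchmark")
    ranked <- coannotationPairs(afps, standard)
    amis <- amiOverThresholds(afps, standard)
    report$benchmark <- list(AP = averagePrecision(ranked),
                             max_F1 = maxFScore(ranked),
                             best_AMI = amis$best_ami,
                             best_AMI_threshold = amis$best_threshold)
  }

  if ("hierarchy" %in% st) {
    say("hierarchy")
    dend <- profileDendrogram(afpsAll)
    cut <- selectCutoff(dend, standard)
    recovered <- amiScore(cut$clusters[singleProts],
                          archLabels[singleProts])
    report$hierarchy <- list(threshold = cut$threshold,
                             n_clusters = length(unique(cut$clusters)),
                             archetype_AMI = recovered)
    out$cutoff <- cut
    if (!is.null(outDir)) {
      writeTableWithHeader(
        data.frame(protein_id = names(cut$clusters),
                   cluster_id = cut$clusters,
                   threshold = cut$threshold),
        file.path(outDir, "clusters.tsv"), hash, seed, sep = "\t")
    }
  }

  say("locmap")
  sidx <- cropInfo(crops)$split == "train" &
    cropInfo(crops)$protein_id %in% singleProts
  headFeats <- t(profileMatrix(scfpsAll))[sidx, , drop = FALSE]
  headLabels <- archLabels[cropInfo(crops)$protein_id[sidx]]
  head <- trainLocalizationHead(headFeats, headLabels,
                                epochs = config$locmap$epochs,
                                batchSize = config$locmap$batchSize,
                                seed = deriveSeed(seed, 5))
  locProbs <- predictLocalization(head, t(profileMatrix(scfpsAll)))
  testIdx <- cropInfo(crops)$split == "test"
  headAcc <- mean(colnames(locProbs)[
    max.col(locProbs[testIdx, , drop = FALSE], ties.method = "first")] ==
      archLabels[proteinIds(scfpsAll)[testIdx]])
  report$locmap <- list(val_accuracy = max(head$history$val_acc),
                        test_archetype_accuracy = headAcc)
  out$head <- head
  out$locProbs <- locProbs

  if ("heterogeneity" %in% st) {
    say("heterogeneity")
    hp <- config$heterogeneity
    params <- heterogeneityParams(alphaConf = hp$alphaConf, beta = hp$beta,
                                  orThreshold = hp$orThreshold,
                                  undeterminedFraction = hp$undeterminedFraction)
    het <- heterogeneityCalls(locProbs, proteinIds(scfpsAll), params)
    truth <- hetero[het$calls$protein_id]
    report$heterogeneity <- list(
      verdicts = table(het$calls$verdict),
      agreement = mean(het$calls$verdict == truth))
    out$hetCalls <- het
    if (!is.null(outDir)) {
      writeTableWithHeader(het$calls, file.path(outDir, "heterogeneity.tsv"),
                           hash, seed, sep = "\t")
    }
  }

  if ("complexes" %in% st) {
    say("complexes")
    cx <- config$complexes
    dendSc <- profileDendrogram(scfpsAll)
    trace <- traceDendrogram(dendSc, step = cx$step)
    cand <- findRootClusters(trace, plateauTolerance = cx$plateauTolerance)
    roots <- resolveRootClusters(cand, trace)
    hi <- highConfidenceClusters(roots, cutoff = cx$cutoff)
    complexOf <- setNames(vapply(panel, function(s)
      if (is.na(s$complex_id)) NA_character_ else s$complex_id,
      character(1)), names(archLabels))
    cxIds <- complexOf[proteinIds(scfpsAll)]
    clIds <- rep(NA_integer_, ncol(scfpsAll))
    for (i in seq_along(hi)) clIds[hi[[i]]$members] <- i
    pw <- tryCatch(pairwiseComplexF1(clIds, cxIds), error = function(e) NULL)
    report$complexes <- list(
      n_roots = length(roots), n_high_confidence = length(hi),
      pairwise_F1 = if (!is.null(pw)) pw$F1 else NA_real_,
      median_F1 = medianClusterF1(clIds, cxIds))
    out$rootClusters <- roots
    out$highConfidence <- hi
    if (!is.null(outDir) && length(hi)) {
      tab <- do.call(rbind, lapply(seq_along(hi), function(i) {
        data.frame(cluster_id = i, protein_id = hi[[i]]$proteins,
                   c = hi[[i]]$c, d = hi[[i]]$d, k = hi[[i]]$k,
                   s = hi[[i]]$s)
      }))
      writeTableWithHeader(tab, file.path(outDir, "complexes.tsv"),
                           hash, seed, sep = "\t")
    }
  }
  c(report, out)
}

writeProfileCsv <- function(fps, file, hash = "", seed = NA) {
  m <- t(profileMatrix(fps))
  df <- cbind(as.data.frame(colData(fps)), as.data.frame(m))
  writeTableWithHeader(df, file, hash, seed)
}

#' Extract and export profiles for an unseen dataset
#'
#' The generalization code path: runs new crops through a trained network
#' out-of-the-box (per-crop standardization is applied internally) and
#' writes one scFP per crop plus per-protein aFPs.
#'
#' @param net a trained [FeatNet-class].
#' @param crops a [CropSet-class] (e.g. from [prepareCrops()] on a new
#'   dataset) or a dataset directory readable by [readDataset()].
#' @param outDir optional output directory for `scfp.csv` / `afp.csv`.
#' @return list with `scfps` and `afps` ([FeatureProfileSet-class]).
#' @export
exportProfiles <- function(net, crops, outDir = NULL) {
  if (is.character(crops)) {
    crops <- prepareCrops(readDataset(crops))
  }
  scfps <- extractProfiles(net, crops)
  afps <- averageProfiles(scfps)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeProfileCsv(scfps, file.path(outDir, "scfp.csv"))
    writeProfileCsv(afps, file.path(outDir, "afp.csv"))
  }
  list(scfps = scfps, afps = afps)
}
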