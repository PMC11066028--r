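test_that("protein panels honor requested composition", {
  panel <- proteinPanel(12, nComplexes = 2,
                        hetFractions = c(AND = 0.25, OR = 0.25), seed = 1)
  tab <- panelTable(panel)
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$heterogeneity == "AND"), 3)
  expect_equal(sum(tab$heterogeneity == "OR"), 3)
  cps <- table(tab$complex_id)
  expect_equal(length(cps), 2)
  expect_true(all(cps >= 2))
  ## complexes are disjoint by construction and share archetype parameters
  for (cx in names(cps)) {
    members <- panel[which(tab$complex_id == cx)]
    expect_true(all(vapply(members, function(s)
      identical(s$params, members[[1]]$params), logical(1))))
    expect_equal(length(unique(vapply(members, `[[`, character(1),
                                      "archetype"))), 1)
  }
})

test_that("degenerate and infeasible panels behave", {
  p2 <- proteinPanel(2, nComplexes = 0, hetFractions = c(), seed = 0)
  expect_equal(vapply(p2, `[[`, character(1), "heterogeneity"),
               rep("single", 2))
  expect_error(proteinPanel(3, nComplexes = 2), "infeasible")
  expect_error(proteinPanel(4, hetFractions = c(AND = 0.7, OR = 0.7)),
               "sum")
})

test_that("panels and datasets are deterministic under seed", {
  p1 <- proteinPanel(8, nComplexes = 1, seed = 42)
  p2 <- proteinPanel(8, nComplexes = 1, seed = 42)
  expect_identical(p1, p2)
  d1 <- generateDataset(p1, cellsPerProtein = 6, replicates = 1,
                        fieldsPerReplicate = 1, seed = 9)
  d2 <- generateDataset(p1, cellsPerProtein = 6, replicates = 1,
                        fieldsPerReplicate = 1, seed = 9)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$fields, d2$fields)
})

test_that("panel JSON round-trips", {
  p <- proteinPanel(6, nComplexes = 1, hetFractions = c(AND = 1 / 6),
                    seed = 3)
  f <- tempfile(fileext = ".json")
  writePanel(p, f)
  q <- readPanel(f)
  for (i in seq_along(p)) {
    expect_equal(q[[i]]$protein_id, p[[i]]$protein_id)
    expect_equal(q[[i]]$archetype, p[[i]]$archetype)
    expect_equal(unlist(q[[i]]$params), unlist(p[[i]]$params),
                 tolerance = 1e-12)
  }
})

test_that("zero-noise fields equal archetype templates exactly", {
  spec <- proteinPanel(1, seed = 2, archetypes = "nucleus")[[1]]
  f0 <- renderField(spec, nCells = 3, noiseSd = 0, seed = 7)
  f1 <- renderField(spec, nCells = 3, noiseSd = 0, seed = 7)
  expect_identical(f0$field, f1$field)
  ## foreground pixels carry exactly abundance * template; background is 0
  gfp <- f0$field[, , 1]
  expect_true(all(gfp[f0$foreground == 0 & gfp > 0] <= spec$abundance))
  expect_true(all(gfp >= 0 & gfp <= spec$abundance + 1e-12))
  expect_gt(sum(f0$foreground), 0)
})

test_that("nuclear archetype concentrates GFP inside the nuclear marker", {
  spec <- proteinPanel(1, seed = 5, archetypes = "nucleus")[[1]]
  fld <- renderField(spec, nCells = 4, noiseSd = 0, seed = 11)
  gfp <- fld$field[, , 1]
  nucmask <- fld$field[, , 2] > 0.05
  expect_gt(sum(gfp[nucmask]) / sum(gfp), 0.9)
})

test_that("peripheral-ring archetype concentrates mass at the cell edge", {
  spec <- proteinPanel(1, seed = 6, archetypes = "peripheral-ring")[[1]]
  fld <- renderField(spec, nCells = 4, noiseSd = 0, seed = 12)
  gfp <- fld$field[, , 1]
  ring <- 0; interior <- 0
  for (i in seq_len(nrow(fld$cells))) {
    cx <- fld$cells$x[i] + 1; cy <- fld$cells$y[i] + 1
    R <- fld$cells$radius[i]
    win <- round(cx + (-15:15)); wjn <- round(cy + (-15:15))
    X <- matrix(win, 31, 31); Y <- matrix(wjn, 31, 31, byrow = TRUE)
    d <- sqrt((X - cx)^2 + (Y - cy)^2)
    vals <- gfp[cbind(as.vector(X), as.vector(Y))]
    ring <- ring + sum(vals[as.vector(d) > R - 4 & as.vector(d) <= R])
    interior <- interior + sum(vals[as.vector(d) <= R - 4])
  }
  expect_gt(ring / max(interior, 1e-9), 3)
})

test_that("generated datasets have complete manifests at the right size", {
  panel <- proteinPanel(12, nComplexes = 2, seed = 1)
  ds <- generateDataset(panel, cellsPerProtein = 10, replicates = 2,
                        fieldsPerReplicate = 4, seed = 7)
  expect_equal(nrow(ds$manifest), 12 * 10)
  expect_true(all(abs(table(ds$manifest$protein_id) - 10) <= 1))
  expect_false(any(duplicated(ds$manifest$crop_id)))

  one <- generateDataset(proteinPanel(1, seed = 2), cellsPerProtein = 1,
                         replicates = 1, fieldsPerReplicate = 1, seed = 3)
  expect_equal(nrow(one$manifest), 1)
})

test_that("replicates share archetype parameters, differ by realization", {
  panel <- proteinPanel(1, seed = 8, archetypes = "punctate")
  ds <- generateDataset(panel, cellsPerProtein = 8, replicates = 2,
                        fieldsPerReplicate = 1, seed = 13)
  f1 <- ds$fields[[1]]$field[, , 1]
  f2 <- ds$fields[[2]]$field[, , 1]
  expect_false(identical(f1, f2))        # different noise/placement
  ## same intensity scale (same spec) on foreground
  expect_lt(abs(max(f1) - max(f2)), 0.1)
})

test_that("on-disk datasets round-trip through TIFF and CSV", {
  panel <- proteinPanel(2, seed = 4)
  dir <- file.path(tempdir(), "synds")
  ds <- generateDataset(panel, cellsPerProtein = 4, replicates = 1,
                        fieldsPerReplicate = 1, seed = 5, outDir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- readDataset(dir)
  expect_equal(back$manifest$crop_id, ds$manifest$crop_id)
  mem <- generateDataset(panel, cellsPerProtein = 4, replicates = 1,
                         fieldsPerReplicate = 1, seed = 5)
  fid <- names(back$fields)[1]
  expect_lt(max(abs(back$fields[[fid]]$field -
                      pmin(pmax(mem$fields[[fid]]$field, 0), 1))), 1e-6)
})

test_that("distinct archetypes separate more than replicate noise", {
  ## separability prerequisite: inter-archetype crop distance exceeds
  ## intra-archetype distance at zero noise
  specs <- proteinPanel(2, seed = 21,
                        archetypes = c("nucleus", "peripheral-ring"))
  crops <- list()
  for (s in 1:2) {
    fld <- renderField(specs[[s]], nCells = 6, noiseSd = 0, seed = 30 + s)
    cent <- data.frame(x = round(fld$cells$x), y = round(fld$cells$y))
    cs <- extractCrops(fld$field, cent, proteinId = specs[[s]]$protein_id)
    crops[[s]] <- matrix(cropArray(cs)[, , 1, ], ncol = length(cs))
  }
  dmat <- function(a, b) {
    sapply(seq_len(ncol(b)), function(j)
      sqrt(colSums((a - b[, j])^2)))
  }
  intra <- mean(c(dmat(crops[[1]], crops[[1]]), dmat(crops[[2]], crops[[2]])))
  inter <- mean(dmat(crops[[1]], crops[[2]]))
  expect_gt(inter, intra)
})

test_that("same-complex proteins produce exchangeable crops", {
  panel <- proteinPanel(2, nComplexes = 1, complexSize = 2, seed = 17,
                        archetypes = "punctate")
  ds <- generateDataset(panel, cellsPerProtein = 100, replicates = 1,
                        fieldsPerReplicate = 5, seed = 18, noiseSd = 0.02)
  feats <- list()
  for (p in c("P01", "P02")) {
    rows <- ds$manifest[ds$manifest$protein_id == p, ]
    v <- numeric(0)
    for (fid in unique(rows$field_id)) {
      fld <- ds$fields[[fid]]$field[, , 1]
      sub <- rows[rows$field_id == fid, ]
      cs <- extractCrops(fld, data.frame(x = sub$x, y = sub$y))
      g <- matrix(cropArray(cs)[, , 1, ], ncol = length(cs))
      v <- c(v, colSums(g))
    }
    feats[[p]] <- v
  }
  ## two-sample test on total crop intensity fails to reject at alpha=0.01
  expect_gt(suppressWarnings(ks.test(feats$P01, feats$P02)$p.value), 0.01)
})
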