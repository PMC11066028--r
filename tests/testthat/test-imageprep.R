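gaussBlob <- function(H, W, cx, cy, sigma = 4, amp = 1) {
  X <- matrix(seq_len(H), H, W); Y <- matrix(seq_len(W), H, W, byrow = TRUE)
  amp * exp(-(((X - cx - 1)^2 + (Y - cy - 1)^2)) / (2 * sigma^2))
}

test_that("watershed center detection finds blob centroids", {
  img <- gaussBlob(64, 64, 32, 32)
  cent <- detectCellCenters(img)
  expect_equal(nrow(cent), 1)
  expect_lt(max(abs(c(cent$x, cent$y) - 32)), 1.5)

  two <- gaussBlob(96, 96, 25, 25) + gaussBlob(96, 96, 70, 68)
  cent2 <- detectCellCenters(two)
  expect_equal(nrow(cent2), 2)
})

test_that("centers too close to the border are discarded", {
  img <- gaussBlob(64, 64, 5, 32, sigma = 2.5)
  expect_equal(nrow(detectCellCenters(img, margin = 10)), 0)
})

test_that("flat or empty images give an empty center list", {
  expect_equal(nrow(detectCellCenters(matrix(0, 32, 32))), 0)
  expect_equal(nrow(detectCellCenters(matrix(0.7, 32, 32))), 0)
})

test_that("crop windows follow the half-open 0-based convention", {
  field <- matrix(seq_len(128 * 128), 128, 128)
  cs <- extractCrops(field, data.frame(x = 64, y = 64), cropSize = 64)
  expect_equal(length(cs), 1)
  ## 0-based window [32, 96) = R rows 33:96; exact copy contract
  expect_equal(cropArray(cs)[, , 1, 1], field[33:96, 33:96],
               ignore_attr = TRUE)

  none <- extractCrops(field, data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(length(none), 0)

  ## too close to the border for a full window -> skipped
  skipped <- extractCrops(field, data.frame(x = c(10, 64), y = c(64, 64)))
  expect_equal(length(skipped), 1)
})

test_that("intensity percentile filter rejects exactly the bottom tail", {
  set.seed(1)
  n <- 100
  crops <- array(0, c(8, 8, 1, n))
  for (i in seq_len(n)) crops[, , 1, i] <- i / 10 + matrix(runif(64), 8) / 100
  cs <- CropSet(crops, data.frame(crop_id = sprintf("c%03d", 1:n),
                                  protein_id = "P"))
  out <- filterCrops(cs, intensityPercentile = 5, varianceFloor = 0)
  expect_equal(nrow(out$rejected), 5)
  expect_equal(out$rejected$crop_id, sprintf("c%03d", 1:5))
  expect_equal(length(out$kept), 95)
})

test_that("constant crops are rejected as background-dominated", {
  ## the flat crop has the HIGHEST total, so only the variance rule can
  ## catch it
  crops <- array(20, c(8, 8, 1, 3))
  crops[, , 1, 2] <- matrix(rnorm(64, 10, 1), 8)
  crops[, , 1, 3] <- matrix(rnorm(64, 10, 1), 8)
  cs <- CropSet(crops, data.frame(crop_id = c("flat", "a", "b"),
                                  protein_id = "P"))
  out <- filterCrops(cs, intensityPercentile = 5, varianceFloor = 1e-4)
  expect_true("flat" %in% out$rejected$crop_id)
  expect_equal(out$rejected$reason[out$rejected$crop_id == "flat"],
               "background_dominated")
})

test_that("identical intensities: percentile ties are kept", {
  crops <- array(0, c(4, 4, 1, 10))
  for (i in 1:10) crops[, , 1, i] <- matrix(rnorm(16, 5, 1), 4)
  tot <- colSums(matrix(crops, 16, 10))
  crops <- sweep(crops, 4, tot / mean(tot), "/") # equalize totals
  cs <- CropSet(crops, data.frame(crop_id = paste0("c", 1:10),
                                  protein_id = "P"))
  out <- filterCrops(cs, intensityPercentile = 5, varianceFloor = 0)
  expect_equal(nrow(out$rejected), 0)
})

test_that("pipeline conservation: kept + rejected = input", {
  set.seed(2)
  n <- 40
  crops <- array(runif(8 * 8 * n), c(8, 8, 1, n))
  cs <- CropSet(crops, data.frame(crop_id = paste0("c", 1:n),
                                  protein_id = "P"))
  out <- filterCrops(cs)
  expect_equal(length(out$kept) + nrow(out$rejected), n)
})

test_that("sparse proteins are dropped at the 10-cell boundary", {
  n <- 9 + 10 + 30
  crops <- array(runif(4 * 4 * n), c(4, 4, 1, n))
  pid <- rep(c("few", "edge", "many"), c(9, 10, 30))
  cs <- CropSet(crops, data.frame(crop_id = paste0("c", 1:n),
                                  protein_id = pid))
  kept <- dropSparseProteins(cs, minCells = 10)
  expect_setequal(unique(cropInfo(kept)$protein_id), c("edge", "many"))
  ## brute-force counting oracle
  expect_equal(length(kept), sum(table(pid)[table(pid) >= 10]))
  one <- CropSet(crops[, , , 1:5, drop = FALSE],
                 data.frame(crop_id = paste0("c", 1:5), protein_id = "few"))
  expect_error(dropSparseProteins(one), "empty dataset")
})

test_that("stratified split hits 8:1:1 within one crop per protein", {
  n <- 100 + 10 + 37
  crops <- array(runif(4 * 4 * n), c(4, 4, 1, n))
  pid <- rep(c("A", "B", "C"), c(100, 10, 37))
  cs <- CropSet(crops, data.frame(crop_id = paste0("c", 1:n),
                                  protein_id = pid))
  sp <- splitCrops(cs, seed = 3)
  info <- cropInfo(sp)
  tabA <- table(info$split[info$protein_id == "A"])
  expect_equal(as.integer(tabA[c("train", "val", "test")]), c(80, 10, 10))
  tabB <- table(info$split[info$protein_id == "B"])
  expect_equal(as.integer(tabB[c("train", "val", "test")]), c(8, 1, 1))
  for (p in c("A", "B", "C")) {
    np <- sum(pid == p)
    tab <- table(factor(info$split[info$protein_id == p],
                        c("train", "val", "test")))
    expect_true(all(abs(tab - np * c(.8, .1, .1)) <= 1))
  }
  ## partition: union = input, pairwise disjoint (every crop exactly one)
  expect_true(all(info$split %in% c("train", "val", "test")))
  ## deterministic and order-independent
  sp2 <- splitCrops(cs, seed = 3)
  expect_identical(cropInfo(sp2)$split, info$split)
})

test_that("instance normalization has the closed forms and idempotence", {
  half <- array(rep(c(0, 2), each = 8), c(4, 4, 1, 1))
  ncs <- normalizeCrops(CropSet(half, data.frame(protein_id = "P")))
  expect_equal(sort(unique(as.vector(cropArray(ncs)))), c(-1, 1))

  const <- CropSet(array(5, c(4, 4, 1, 1)), data.frame(protein_id = "P"))
  expect_true(all(cropArray(normalizeCrops(const)) == 0))

  set.seed(4)
  cs <- CropSet(array(rnorm(8 * 8 * 2 * 3, 5, 2), c(8, 8, 2, 3)),
                data.frame(protein_id = rep("P", 3)))
  n1 <- normalizeCrops(cs)
  a <- cropArray(n1)
  for (i in 1:3) for (c in 1:2) {
    expect_lt(abs(mean(a[, , c, i])), 1e-6)
    expect_lt(abs(mean(a[, , c, i]^2) - 1), 1e-6)
  }
  n2 <- normalizeCrops(n1)
  expect_lt(max(abs(cropArray(n2) - a)), 1e-6)
})

test_that("dihedral augmentation is a faithful group action", {
  set.seed(5)
  m <- matrix(rnorm(36), 6, 6)
  ## rotation by 180 twice is the identity
  expect_identical(augmentCrop(augmentCrop(m, 3), 3), m)
  ## all transforms preserve the pixel multiset
  for (k in 1:8) {
    expect_equal(sort(as.vector(augmentCrop(m, k))), sort(as.vector(m)))
  }
  ## the 8 transforms are distinct
  imgs <- vapply(1:8, function(k) as.vector(augmentCrop(m, k)),
                 numeric(36))
  expect_equal(nrow(unique(t(imgs))), 8)
  expect_error(augmentCrop(matrix(0, 2, 3)), "square")
})

test_that("augmentation transform draws are uniform", {
  set.seed(6)
  m <- matrix(c(1, 0, 0, 0), 2, 2) # asymmetric marker
  ## identify which transform was applied by its action on the marker
  ref <- vapply(1:8, function(k) paste(augmentCrop(m, k), collapse = ","),
                character(1))
  X <- array(m, c(2, 2, 8000, 1))
  out <- augmentArray(X)
  obs <- apply(out[, , , 1], 3, paste, collapse = ",")
  counts <- table(factor(obs, levels = unique(ref)))
  ## transforms 7/8 coincide with 2/4 for symmetric... use distinct count
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})
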