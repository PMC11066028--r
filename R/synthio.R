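## Synthetic micrograph simulation with known ground truth.
##
## Cells are circles with radius jitter plus an optional bud whose relative
## size encodes cell-cycle stage; fluorescence archetypes are parametric
## templates rendered in cell-local coordinates. The point is planted,
## recoverable structure (archetypes, complexes, AND/OR heterogeneity,
## cell-cycle dependence), not photorealism.

#' Localization archetypes available to the simulator
#' @return Character vector of archetype names.
#' @export
localizationArchetypes <- function() {
  c("nucleus", "cytoplasm", "nucleolus", "punctate", "peripheral-ring",
    "nuclear-periphery-ring", "ER-mesh", "mitochondrial-network")
}

## Per-protein archetype parameters. Proteins sharing a complex share these
## exactly; every other protein receives its own draw, which is what makes
## protein identity learnable beyond the archetype class.
drawArchetypeParams <- function(archetype) {
  ## ranges are wide enough that two independent draws differ by more than
  ## replicate noise: distinct proteins must be individually recognizable
  ## for the identity pretext task to be meaningful
  switch(archetype,
    "nucleus" = list(sigmaScale = runif(1, 0.65, 1.45)),
    "cytoplasm" = list(dimFactor = runif(1, 0.35, 0.95),
                       taper = runif(1, 0.8, 4.0)),
    "nucleolus" = list(relRadius = runif(1, 0.4, 1.0),
                       relOffset = runif(1, 0.3, 1.2)),
    "punctate" = list(nPuncta = sample(3:12, 1),
                      puncRadius = runif(1, 1.3, 3.2)),
    "peripheral-ring" = list(thickness = runif(1, 1.2, 4.5)),
    "nuclear-periphery-ring" = list(thickness = runif(1, 0.8, 2.8),
                                    relRadius = runif(1, 1.2, 2.0)),
    "ER-mesh" = list(f1 = runif(1, 0.5, 1.1), f2 = runif(1, 0.5, 1.1),
                     thr = runif(1, 0.6, 1.2)),
    "mitochondrial-network" = list(freq = runif(1, 0.2, 0.5),
                                   angle = runif(1, 0, pi),
                                   thr = runif(1, 0.4, 1.0)),
    stop("unknown archetype: ", archetype))
}

#' Create a panel of synthetic protein specifications
#'
#' Builds `nProteins` protein specs with localization archetypes, planted
#' complexes (members share archetype parameters exactly), AND/OR
#' localization heterogeneity and optional cell-cycle-dependent localization.
#'
#' @param nProteins number of proteins.
#' @param nComplexes number of planted complexes; members are
#'   single-localizing and share one archetype parameterization.
#' @param hetFractions named numeric, fractions of AND- and OR-localizing
#'   proteins, e.g. `c(AND = 0.25, OR = 0.25)`; must sum to at most 1.
#' @param seed integer seed; panels are deterministic given the seed.
#' @param archetypes archetype names to cycle over (default first 4).
#' @param complexSize members per complex (default 3).
#' @param nCellCycle number of proteins whose localization follows the cell
#'   cycle (primary archetype in G1/S/T, secondary archetype in MA).
#' @param abundanceRange range of mean foreground intensities (arbitrary
#'   units in \[0, 1\]).
#' @return An object of class `ProteinPanel`: a list of protein specs, each
#'   with fields `protein_id`, `archetype`, `abundance`, `heterogeneity`
#'   (`single`/`AND`/`OR`), `secondary`, `mixing`, `complex_id`,
#'   `cellcycle` (named stage-to-archetype map or NULL) and `params`.
#' @examples
#' panel <- proteinPanel(12, nComplexes = 2, hetFractions = c(AND = .25, OR = .25))
#' @export
proteinPanel <- function(nProteins, nComplexes = 0,
                         hetFractions = c(AND = 0, OR = 0), seed = 1,
                         archetypes = localizationArchetypes()[1:4],
                         complexSize = 3, nCellCycle = 0,
                         abundanceRange = c(0.35, 0.85)) {
  hetFractions <- hetFractions[hetFractions > 0]
  if (length(hetFractions) && sum(hetFractions) > 1) {
    stop("heterogeneity fractions must sum to at most 1")
  }
  if (nProteins < nComplexes * 2) {
    stop("infeasible panel: need at least 2 proteins per complex")
  }
  nAND <- if ("AND" %in% names(hetFractions)) round(hetFractions[["AND"]] * nProteins) else 0
  nOR <- if ("OR" %in% names(hetFractions)) round(hetFractions[["OR"]] * nProteins) else 0
  nCpx <- nComplexes * complexSize
  if (nCpx + nAND + nOR + nCellCycle > nProteins) {
    stop("infeasible panel: complexes + AND + OR + cell-cycle proteins ",
         "exceed nProteins")
  }
  withSeed(seed, {
    ids <- sprintf("P%02d", seq_len(nProteins))
    specs <- vector("list", nProteins)
    arch_of <- function(k) archetypes[((k - 1) %% length(archetypes)) + 1]
    next_arch <- function(a) {
      i <- match(a, archetypes)
      archetypes[(i %% length(archetypes)) + 1]
    }
    k <- 0
    idx <- 1
    ## complexes first: founder draws parameters, members copy them
    for (cx in seq_len(nComplexes)) {
      k <- k + 1
      arch <- arch_of(k)
      par <- drawArchetypeParams(arch)
      ## members share the full parameterization, abundance included, so
      ## their crops are statistically exchangeable
      ab <- runif(1, abundanceRange[1], abundanceRange[2])
      for (m in seq_len(complexSize)) {
        specs[[idx]] <- list(protein_id = ids[idx], archetype = arch,
                             abundance = ab,
                             heterogeneity = "single", secondary = NULL,
                             mixing = 0, complex_id = sprintf("CPX%d", cx),
                             cellcycle = NULL, params = par,
                             secondary_params = NULL)
        idx <- idx + 1
      }
    }
    mk <- function(het, mixing) {
      k <<- k + 1
      arch <- arch_of(k)
      sec <- if (het %in% c("AND", "OR")) next_arch(arch) else NULL
      spec <- list(protein_id = ids[idx], archetype = arch,
                   abundance = runif(1, abundanceRange[1], abundanceRange[2]),
                   heterogeneity = het, secondary = sec, mixing = mixing,
                   complex_id = NA_character_, cellcycle = NULL,
                   params = drawArchetypeParams(arch),
                   secondary_params = if (!is.null(sec)) drawArchetypeParams(sec))
      specs[[idx]] <<- spec
      idx <<- idx + 1
    }
    for (i in seq_len(nAND)) mk("AND", 0.5)
    for (i in seq_len(nOR)) mk("OR", 0.3)
    for (i in seq_len(nCellCycle)) {
      mk("single", 0)
      sp <- specs[[idx - 1]]
      sp$secondary <- next_arch(sp$archetype)
      sp$secondary_params <- drawArchetypeParams(sp$secondary)
      sp$cellcycle <- c(G1 = sp$archetype, S = sp$archetype,
                        MA = sp$secondary, T = sp$archetype)
      specs[[idx - 1]] <- sp
    }
    while (idx <= nProteins) mk("single", 0)
    structure(specs, class = "ProteinPanel", seed = seed)
  })
}

#' @export
print.ProteinPanel <- function(x, ...) {
  df <- panelTable(x)
  cat(sprintf("ProteinPanel: %d proteins, %d complexes, %d AND, %d OR, %d cell-cycle\n",
              nrow(df), length(unique(stats::na.omit(df$complex_id))),
              sum(df$heterogeneity == "AND"), sum(df$heterogeneity == "OR"),
              sum(df$cellcycle)))
  print(df, ...)
  invisible(x)
}

#' Tabular view of a protein panel
#' @param panel a `ProteinPanel`.
#' @return data.frame with one row per protein.
#' @export
panelTable <- function(panel) {
  do.call(rbind, lapply(panel, function(s) {
    data.frame(protein_id = s$protein_id, archetype = s$archetype,
               abundance = s$abundance, heterogeneity = s$heterogeneity,
               secondary = if (is.null(s$secondary)) NA_character_ else s$secondary,
               mixing = s$mixing, complex_id = s$complex_id,
               cellcycle = !is.null(s$cellcycle),
               stringsAsFactors = FALSE)
  }))
}

#' Write / read a protein panel as JSON
#' @param panel a `ProteinPanel`.
#' @param file path to a JSON file.
#' @return `writePanel` the path, invisibly; `readPanel` a `ProteinPanel`.
#' @export
writePanel <- function(panel, file) {
  jsonlite::write_json(lapply(unclass(panel), function(s) {
    s[!vapply(s, is.null, logical(1))]
  }), file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}

#' @rdname writePanel
#' @export
readPanel <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  specs <- lapply(raw, function(s) {
    s$params <- lapply(s$params, function(v) v)
    if (is.null(s$secondary)) s["secondary"] <- list(NULL)
    if (is.null(s$secondary_params)) s["secondary_params"] <- list(NULL)
    if (is.null(s$cellcycle)) s["cellcycle"] <- list(NULL) else s$cellcycle <- unlist(s$cellcycle)
    if (is.null(s$complex_id)) s$complex_id <- NA_character_
    s
  })
  structure(specs, class = "ProteinPanel")
}

## ---- geometry and templates -------------------------------------------

cellCycleStages <- c("G1", "S", "MA", "T")

## Relative bud radius per stage; G1 has no bud.
budFraction <- c(G1 = 0, S = 0.35, MA = 0.6, T = 0.85)

## Sample one cell's geometry: position, radius, stage-dependent bud, and
## a nucleus (elongated toward the bud in MA/T).
sampleCellGeometry <- function(x, y, stage) {
  R <- runif(1, 9, 12)
  theta <- runif(1, 0, 2 * pi)
  bf <- budFraction[[stage]]
  budR <- bf * R
  budDist <- if (bf > 0) R + 0.75 * budR else 0
  nsig <- 0.28 * R
  elong <- switch(stage, G1 = 1, S = 1.1, MA = 1.9, T = 2.6)
  nshift <- switch(stage, G1 = 0, S = 0, MA = 0.45 * R, T = 0.8 * R)
  list(cx = x, cy = y, R = R, stage = stage, theta = theta,
       budx = x + budDist * cos(theta), budy = y + budDist * sin(theta),
       budR = budR, nucx = x + nshift * cos(theta),
       nucy = y + nshift * sin(theta), nucSigma = nsig, elong = elong)
}

## Pixel grids (1-based here; user-facing coordinates are 0-based).
cellWindow <- function(g, H, W, pad = 6) {
  r <- ceiling(g$R + g$budR * 2 + pad)
  xs <- max(1, floor(g$cx) - r):min(H, ceiling(g$cx) + r)
  ys <- max(1, floor(g$cy) - r):min(W, ceiling(g$cy) + r)
  list(xs = xs, ys = ys)
}

## Signed inside-depth of the cell body (union of mother disk and bud disk):
## positive inside, value = distance to the nearest cell boundary.
insideDepth <- function(g, X, Y) {
  d1 <- g$R - sqrt((X - g$cx)^2 + (Y - g$cy)^2)
  if (g$budR > 0) {
    d2 <- g$budR - sqrt((X - g$budx)^2 + (Y - g$budy)^2)
    pmax(d1, d2)
  } else d1
}

## Nucleus intensity: anisotropic Gaussian elongated along the bud axis.
nucleusBlob <- function(g, X, Y, sigmaScale = 1) {
  ct <- cos(g$theta); st <- sin(g$theta)
  u <- (X - g$nucx) * ct + (Y - g$nucy) * st
  v <- -(X - g$nucx) * st + (Y - g$nucy) * ct
  s <- g$nucSigma * sigmaScale
  exp(-0.5 * ((u / (s * g$elong))^2 + (v / s)^2))
}

## GFP archetype template on the window grid, values in [0, 1].
## `puncta` positions are drawn from the current RNG stream.
archetypeTemplate <- function(archetype, params, g, X, Y) {
  depth <- insideDepth(g, X, Y)
  inside <- depth > 0
  switch(archetype,
    "nucleus" = {
      b <- nucleusBlob(g, X, Y, params$sigmaScale)
      ifelse(inside & b > 0.05, b, 0)
    },
    "cytoplasm" = {
      b <- nucleusBlob(g, X, Y)
      base <- pmin(1, depth / params$taper)
      ifelse(inside, base * (1 - params$dimFactor * b), 0)
    },
    "nucleolus" = {
      s <- g$nucSigma
      off <- params$relOffset * s
      nx <- g$nucx + off * cos(g$theta + 1)
      ny <- g$nucy + off * sin(g$theta + 1)
      r <- params$relRadius * s
      d <- sqrt((X - nx)^2 + (Y - ny)^2)
      ifelse(inside & d < r, 1, 0)
    },
    "punctate" = {
      out <- matrix(0, nrow(X), ncol(X))
      n <- params$nPuncta
      placed <- 0; tries <- 0
      while (placed < n && tries < 200) {
        tries <- tries + 1
        px <- g$cx + runif(1, -1, 1) * g$R
        py <- g$cy + runif(1, -1, 1) * g$R
        dd <- g$R - sqrt((px - g$cx)^2 + (py - g$cy)^2)
        if (dd < params$puncRadius + 1) next
        placed <- placed + 1
        out <- pmax(out, ifelse(sqrt((X - px)^2 + (Y - py)^2) <
                                  params$puncRadius, 1, 0))
      }
      out * inside
    },
    "peripheral-ring" = {
      ifelse(inside & depth <= params$thickness, 1, 0)
    },
    "nuclear-periphery-ring" = {
      rn <- params$relRadius * g$nucSigma
      d <- sqrt((X - g$nucx)^2 + (Y - g$nucy)^2)
      ifelse(inside & abs(d - rn) < params$thickness, 1, 0)
    },
    "ER-mesh" = {
      rn <- 1.4 * g$nucSigma
      d <- sqrt((X - g$nucx)^2 + (Y - g$nucy)^2)
      ring <- inside & abs(d - rn) < 1.2
      tex <- sin(params$f1 * X + 0.3 * Y) + sin(params$f2 * Y - 0.2 * X)
      mesh <- inside & d > rn & tex > params$thr
      ifelse(ring | mesh, 1, 0)
    },
    "mitochondrial-network" = {
      ct <- cos(params$angle); st <- sin(params$angle)
      u <- X * ct + Y * st
      v <- -X * st + Y * ct
      tex <- sin(params$freq * u + 0.8 * sin(0.2 * v))
      ifelse(inside & depth > 1.5 & tex > params$thr, 1, 0)
    },
    stop("unknown archetype: ", archetype))
}

## Pick the archetype (and parameter set) a given cell expresses, applying
## cell-cycle dependence, AND mixing and OR switching.
cellExpression <- function(spec, stage) {
  if (!is.null(spec$cellcycle)) {
    a <- spec$cellcycle[[stage]]
    if (a == spec$archetype) {
      return(list(list(arch = spec$archetype, par = spec$params, w = 1)))
    }
    return(list(list(arch = spec$secondary, par = spec$secondary_params, w = 1)))
  }
  switch(spec$heterogeneity,
    single = list(list(arch = spec$archetype, par = spec$params, w = 1)),
    AND = {
      ## per-cell partitioning varies around the mixing fraction (real
      ## dual-localizing proteins distribute continuously across cells)
      m <- spec$mixing
      w2 <- stats::rbeta(1, 8 * m, 8 * (1 - m))
      list(
        list(arch = spec$archetype, par = spec$params, w = 1 - w2),
        list(arch = spec$secondary, par = spec$secondary_params, w = w2))
    },
    OR = {
      if (runif(1) < spec$mixing) {
        list(list(arch = spec$secondary, par = spec$secondary_params, w = 1))
      } else {
        list(list(arch = spec$archetype, par = spec$params, w = 1))
      }
    })
}

#' Render one synthetic micrograph field for a protein
#'
#' Places `nCells` cells (circle with stage-dependent bud) without nuclear
#' overlap and renders three channels: the tagged protein (GFP) following the
#' protein's archetype(s), a nuclear marker (one blob per cell) and a
#' cytosolic marker (cell body). Additive Gaussian noise of standard
#' deviation `noiseSd` is applied to all channels; with `noiseSd = 0` the
#' field equals the archetype template intensities exactly.
#'
#' @param spec one protein spec from [proteinPanel()].
#' @param nCells number of cells to place (>= 1).
#' @param noiseSd non-negative noise standard deviation (intensity units).
#' @param seed integer seed.
#' @param fieldSize side length of the square field in pixels.
#' @param margin minimum distance of cell centers from the border, chosen so
#'   a full 64-pixel crop fits around every cell.
#' @param stageProbs sampling probabilities of cell-cycle stages G1/S/MA/T.
#' @return list with `field` (fieldSize x fieldSize x 3 array, channels GFP,
#'   nuclear, cytosolic), `cells` (data.frame with 0-based `x`, `y` centers,
#'   `radius`, `stage`), `foreground` (binary matrix, pixels with nonzero
#'   noiseless GFP template) and `spec`.
#' @export
renderField <- function(spec, nCells, noiseSd = 0.02, seed = 1,
                        fieldSize = 320, margin = 38,
                        stageProbs = c(G1 = 0.4, S = 0.25, MA = 0.2, T = 0.15)) {
  stopifnot(nCells >= 1, noiseSd >= 0)
  if (fieldSize < 2 * margin + 20) stop("field too small for any cell")
  withSeed(seed, {
    H <- W <- fieldSize
    ## rejection-sample centers with pairwise distance > 2.4 * max radius
    centers <- matrix(numeric(0), 0, 2)
    minDist <- 30
    tries <- 0
    while (nrow(centers) < nCells) {
      tries <- tries + 1
      if (tries > 500 * nCells) {
        stop("field too small to place ", nCells, " cells")
      }
      p <- runif(2, margin, fieldSize - margin)
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) > minDist) {
        centers <- rbind(centers, p)
      }
    }
    stages <- sample(cellCycleStages, nCells, replace = TRUE,
                     prob = stageProbs[cellCycleStages])
    gfp <- matrix(0, H, W); nuc <- matrix(0, H, W); cyt <- matrix(0, H, W)
    fg <- matrix(0, H, W)
    cells <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      g <- sampleCellGeometry(centers[i, 1], centers[i, 2], stages[i])
      win <- cellWindow(g, H, W)
      X <- matrix(win$xs, length(win$xs), length(win$ys))
      Y <- matrix(win$ys, length(win$xs), length(win$ys), byrow = TRUE)
      depth <- insideDepth(g, X, Y)
      inside <- depth > 0
      ## nuclear marker: one (possibly elongated) blob per cell
      nb <- nucleusBlob(g, X, Y)
      nuc[win$xs, win$ys] <- pmax(nuc[win$xs, win$ys], 0.8 * nb * inside)
      ## cytosolic marker: soft-edged cell body
      cyt[win$xs, win$ys] <- pmax(cyt[win$xs, win$ys],
                                  0.5 * pmin(1, pmax(depth, 0) / 2))
      ## GFP: archetype(s) scaled by abundance. For AND cells the mixing
      ## fraction is a molecule fraction: each compartment's template is
      ## normalized to unit integrated intensity before weighting, so a
      ## 50/50 split puts equal total signal in both compartments
      ## regardless of their areas; the peak is rescaled to 1.
      expr <- cellExpression(spec, stages[i])
      if (length(expr) == 1) {
        tmpl <- expr[[1]]$w *
          archetypeTemplate(expr[[1]]$arch, expr[[1]]$par, g, X, Y)
      } else {
        tmpl <- matrix(0, nrow(X), ncol(X))
        for (e in expr) {
          te <- archetypeTemplate(e$arch, e$par, g, X, Y)
          ms <- sum(te)
          if (ms > 0) tmpl <- tmpl + e$w * te / ms
        }
        if (max(tmpl) > 0) tmpl <- tmpl / max(tmpl)
      }
      tmpl <- pmin(tmpl, 1)
      gfp[win$xs, win$ys] <- pmax(gfp[win$xs, win$ys], spec$abundance * tmpl)
      fg[win$xs, win$ys] <- pmax(fg[win$xs, win$ys], as.numeric(tmpl > 0.05))
      cells[[i]] <- data.frame(x = g$cx - 1, y = g$cy - 1, radius = g$R,
                               stage = g$stage, stringsAsFactors = FALSE)
    }
    field <- array(c(gfp, nuc, cyt), dim = c(H, W, 3))
    if (noiseSd > 0) {
      field <- field + array(rnorm(length(field), 0, noiseSd), dim = dim(field))
    }
    list(field = field, cells = do.call(rbind, cells), foreground = fg,
         spec = spec)
  })
}

#' Generate a full synthetic dataset (fields plus truth manifest)
#'
#' For every protein, renders `replicates x fieldsPerReplicate` fields whose
#' cell counts sum to (approximately) `cellsPerProtein`, emulating a screen
#' in which each strain is imaged in two biological replicates of several
#' fields of view. Replicates differ only in noise and cell placement, never
#' in archetype parameters.
#'
#' @param panel a `ProteinPanel`.
#' @param cellsPerProtein target cells per protein.
#' @param replicates,fieldsPerReplicate dataset design (all >= 1).
#' @param seed master seed; the whole dataset is reproducible from it.
#' @param noiseSd per-channel additive Gaussian noise sd.
#' @param outDir if non-NULL, fields are written as multi-page 32-bit TIFF
#'   (page order GFP, nuclear, cytosolic; intensities clipped to \[0,1\]),
#'   foreground masks as separate TIFFs, the manifest as `manifest.csv` and
#'   the panel as `panel.json`.
#' @param fieldSize field side length in pixels.
#' @return list with `manifest` (one row per cell: crop_id, protein_id,
#'   replicate, field_id, x, y, stage), `fields` (named list of in-memory
#'   fields, or NULL when written to disk), `panel`, `dir`.
#' @export
generateDataset <- function(panel, cellsPerProtein = 100, replicates = 2,
                            fieldsPerReplicate = 4, seed = 7, noiseSd = 0.02,
                            outDir = NULL, fieldSize = 320) {
  stopifnot(cellsPerProtein >= 1, replicates >= 1, fieldsPerReplicate >= 1)
  nf <- replicates * fieldsPerReplicate
  base <- cellsPerProtein %/% nf
  extra <- cellsPerProtein %% nf
  if (!is.null(outDir) && !dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outDir)
  }
  manifest <- list()
  fields <- list()
  k <- 0
  for (spec in panel) {
    fi <- 0
    for (rep in seq_len(replicates)) {
      for (f in seq_len(fieldsPerReplicate)) {
        fi <- fi + 1
        k <- k + 1
        n <- base + as.integer(fi <= extra)
        if (n == 0) next
        fld <- renderField(spec, n, noiseSd = noiseSd,
                           seed = deriveSeed(seed, k), fieldSize = fieldSize)
        fieldId <- sprintf("%s_r%d_f%d", spec$protein_id, rep, f)
        rows <- data.frame(
          crop_id = sprintf("%s_c%03d", fieldId, seq_len(n)),
          protein_id = spec$protein_id, replicate = rep, field_id = fieldId,
          x = round(fld$cells$x), y = round(fld$cells$y),
          stage = fld$cells$stage, stringsAsFactors = FALSE)
        manifest[[k]] <- rows
        if (is.null(outDir)) {
          fields[[fieldId]] <- fld[c("field", "foreground")]
        } else {
          writeFieldTiff(fld, file.path(outDir, paste0(fieldId, ".tif")))
        }
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(outDir)) {
    write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
    writePanel(panel, file.path(outDir, "panel.json"))
  }
  list(manifest = manifest, fields = if (is.null(outDir)) fields,
       panel = panel, dir = outDir)
}

## TIFF IO: pages GFP, nuclear, cytosolic; mask in a sibling *_mask.tif.
writeFieldTiff <- function(fld, path) {
  pages <- lapply(1:3, function(c) pmin(pmax(fld$field[, , c], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  tiff::writeTIFF(fld$foreground, sub("\\.tif$", "_mask.tif", path),
                  bits.per.sample = 8L)
  invisible(path)
}

#' Read a synthetic dataset from disk
#' @param dir directory written by [generateDataset()].
#' @return Same structure as the in-memory return of [generateDataset()].
#' @export
readDataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  panel <- readPanel(file.path(dir, "panel.json"))
  ids <- unique(manifest$field_id)
  fields <- lapply(ids, function(fid) {
    pages <- tiff::readTIFF(file.path(dir, paste0(fid, ".tif")), all = TRUE)
    H <- nrow(pages[[1]])
    field <- array(unlist(pages), dim = c(H, ncol(pages[[1]]), 3))
    fgp <- file.path(dir, paste0(fid, "_mask.tif"))
    fg <- if (file.exists(fgp)) round(tiff::readTIFF(fgp)) else NULL
    list(field = field, foreground = fg)
  })
  names(fields) <- ids
  list(manifest = manifest, fields = fields, panel = panel, dir = dir)
}
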