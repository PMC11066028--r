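#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' CropSet: a collection of single-cell image crops
#'
#' Holds a stack of multi-channel single-cell crops together with their
#' provenance (protein identity, source field, replicate, position, split).
#' Crops are stored as a 4-D array `height x width x channel x crop`;
#' channel 1 is always the tagged-protein ("GFP") channel.
#'
#' @slot crops numeric 4-D array (H, W, C, N).
#' @slot info a [S4Vectors::DataFrame] with one row per crop. Expected
#'   columns include `crop_id`, `protein_id` and optionally `replicate`,
#'   `field_id`, `x`, `y`, `stage`, `split`.
#' @slot channels character vector naming the C channels.
#'
#' @export
setClass("CropSet",
  representation(crops = "array", info = "DataFrame", channels = "character"))

setValidity("CropSet", function(object) {
  d <- dim(object@crops)
  if (length(d) != 4) return("crops must be a 4-D array (H, W, C, N)")
  if (d[3] != length(object@channels)) {
    return("length(channels) must equal dim(crops)[3]")
  }
  if (nrow(object@info) != d[4]) {
    return("nrow(info) must equal the number of crops dim(crops)[4]")
  }
  if (!"protein_id" %in% colnames(object@info)) {
    return("info must contain a protein_id column")
  }
  TRUE
})

#' Construct a CropSet
#'
#' @param crops 4-D numeric array (H, W, C, N).
#' @param info data.frame or DataFrame with one row per crop; must contain
#'   `protein_id`.
#' @param channels channel names; defaults to `c("gfp","nuclear","cyto")[1:C]`.
#' @return A [CropSet-class] object.
#' @export
CropSet <- function(crops, info, channels = NULL) {
  if (length(dim(crops)) == 3) dim(crops) <- c(dim(crops), 1L)
  if (is.null(channels)) {
    channels <- c("gfp", "nuclear", "cyto", "mask")[seq_len(dim(crops)[3])]
  }
  new("CropSet", crops = crops, info = DataFrame(info), channels = channels)
}

#' @describeIn CropSet Number of crops.
#' @param x,object a CropSet.
#' @export
setMethod("length", "CropSet", function(x) dim(x@crops)[4])

#' Accessors for CropSet
#'
#' `cropArray` returns the raw (H, W, C, N) array, `cropInfo` the per-crop
#' metadata, `cropChannels` the channel names.
#'
#' @param x a [CropSet-class].
#' @return `cropArray`: 4-D array; `cropInfo`: DataFrame; `cropChannels`:
#'   character vector.
#' @export
cropArray <- function(x) x@crops

#' @rdname cropArray
#' @export
cropInfo <- function(x) x@info

#' @rdname cropArray
#' @export
cropChannels <- function(x) x@channels

#' @describeIn CropSet Subset crops (fourth dimension).
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CropSet", function(x, i, j, ..., drop = FALSE) {
  new("CropSet", crops = x@crops[, , , i, drop = FALSE],
      info = x@info[i, , drop = FALSE], channels = x@channels)
})

setMethod("show", "CropSet", function(object) {
  d <- dim(object@crops)
  cat(sprintf("CropSet: %d crops of %dx%d, channels: %s\n", d[4], d[1], d[2],
              paste(object@channels, collapse = ", ")))
  cat(sprintf("  proteins: %d unique\n",
              length(unique(object@info$protein_id))))
  if ("split" %in% colnames(object@info)) {
    tb <- table(object@info$split)
    cat("  split:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
})

#' FeatureProfileSet: single-cell or averaged feature profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' `profiles` is a `feature_dim x n` matrix of network feature profiles.
#' Columns are crops (level `"scFP"`) or proteins (level `"aFP"`); column
#' data carries `protein_id` and, for scFPs, `crop_id` (for aFPs,
#' `n_cells`). The profile level is stored in `metadata(x)$level`.
#'
#' @export
setClass("FeatureProfileSet", contains = "SummarizedExperiment")

#' Construct a FeatureProfileSet
#'
#' @param profiles numeric matrix, features in rows, crops/proteins in
#'   columns.
#' @param info data.frame/DataFrame of column metadata (needs `protein_id`).
#' @param level `"scFP"` (per-crop) or `"aFP"` (per-protein average).
#' @return A [FeatureProfileSet-class].
#' @export
FeatureProfileSet <- function(profiles, info, level = c("scFP", "aFP")) {
  level <- match.arg(level)
  info <- DataFrame(info)
  stopifnot(is.matrix(profiles), nrow(info) == ncol(profiles),
            "protein_id" %in% colnames(info))
  if (!all(is.finite(profiles))) stop("profiles must be finite")
  rownames(profiles) <- paste0("f", seq_len(nrow(profiles)))
  se <- SummarizedExperiment(assays = list(profiles = profiles),
                             colData = info)
  metadata(se)$level <- level
  new("FeatureProfileSet", se)
}

#' Accessors for FeatureProfileSet
#'
#' @param x a [FeatureProfileSet-class].
#' @return `profileMatrix`: the `feature_dim x n` matrix; `profileLevel`:
#'   `"scFP"` or `"aFP"`; `proteinIds`: per-column protein identifiers.
#' @export
profileMatrix <- function(x) assay(x, "profiles")

#' @rdname profileMatrix
#' @export
profileLevel <- function(x) metadata(x)$level

#' @rdname profileMatrix
#' @export
proteinIds <- function(x) colData(x)$protein_id

setMethod("show", "FeatureProfileSet", function(object) {
  cat(sprintf("FeatureProfileSet (%s): %d profiles x %d features, %d proteins\n",
              profileLevel(object), ncol(object), nrow(object),
              length(unique(proteinIds(object)))))
})

#' Average single-cell profiles into per-protein profiles
#'
#' The averaged feature profile (aFP) of a protein is the arithmetic mean of
#' its single-cell feature profiles (scFPs), component-wise.
#'
#' @param scfps a [FeatureProfileSet-class] at level `"scFP"`.
#' @return A [FeatureProfileSet-class] at level `"aFP"` with one column per
#'   protein and an `n_cells` column in its metadata.
#' @export
averageProfiles <- function(scfps) {
  stopifnot(is(scfps, "FeatureProfileSet"), profileLevel(scfps) == "scFP")
  m <- profileMatrix(scfps)
  pid <- as.character(proteinIds(scfps))
  prots <- unique(pid)
  am <- vapply(prots, function(p) rowMeans(m[, pid == p, drop = FALSE]),
               numeric(nrow(m)))
  am <- matrix(am, nrow = nrow(m), dimnames = list(NULL, prots))
  ncells <- vapply(prots, function(p) sum(pid == p), integer(1))
  FeatureProfileSet(am,
    info = DataFrame(protein_id = prots, n_cells = ncells),
    level = "aFP")
}
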