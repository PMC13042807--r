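#' Single-nucleus intensity image with its nuclear mask
#'
#' Container for one 2-D confocal plane restricted to a nucleus: a
#' nonnegative intensity grid and a binary mask of the nuclear region.
#' All condensate metrics ([segmentFoci()], [condensedFractions()],
#' [pearsonColocalization()]) operate within the mask.
#'
#' @slot intensity numeric matrix of nonnegative pixel intensities.
#' @slot mask logical matrix, same shape, `TRUE` inside the nucleus.
#' @export
setClass("NucleusImage",
  representation(intensity = "matrix", mask = "matrix"))

setValidity("NucleusImage", function(object) {
  msg <- character(0)
  if (!is.numeric(object@intensity))
    msg <- c(msg, "intensity must be numeric")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (!identical(dim(object@intensity), dim(object@mask)))
    msg <- c(msg, "intensity and mask must have identical dimensions")
  if (is.logical(object@mask) && !any(object@mask))
    msg <- c(msg, "mask is empty")
  if (is.numeric(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a NucleusImage
#'
#' @param intensity numeric matrix of nonnegative intensities.
#' @param mask logical matrix of the same shape (nuclear region).
#' @return A [NucleusImage-class] object.
#' @examples
#' img <- NucleusImage(matrix(10, 8, 8), matrix(TRUE, 8, 8))
#' @export
NucleusImage <- function(intensity, mask) {
  new("NucleusImage", intensity = intensity, mask = mask)
}

setMethod("show", "NucleusImage", function(object) {
  cat("NucleusImage:", nrow(object@intensity), "x", ncol(object@intensity),
      "px;", sum(object@mask), "px in nuclear mask\n")
  invisible(NULL)
})

#' @describeIn NucleusImage pixel dimensions of the image.
#' @param x a `NucleusImage`.
#' @export
setMethod("dim", "NucleusImage", function(x) dim(x@intensity))

#' Intensity grid of a NucleusImage
#' @param x a [NucleusImage-class].
#' @return numeric matrix.
#' @export
imageIntensity <- function(x) x@intensity

#' Nuclear mask of a NucleusImage
#' @param x a [NucleusImage-class].
#' @return logical matrix.
#' @export
nucleusMask <- function(x) x@mask

#' Labeled condensate foci within a nucleus
#'
#' Result of [segmentFoci()]: disjoint 8-connected pixel components inside
#' the nuclear mask, with per-focus area and integrated intensity.
#'
#' @slot labels integer matrix; 0 = background, k = pixels of focus k.
#' @slot foci data.frame with columns `label`, `area`,
#'   `integrated_intensity`.
#' @slot maskArea integer, number of pixels in the nuclear mask.
#' @export
setClass("FociSegmentation",
  representation(labels = "matrix", foci = "data.frame",
                 maskArea = "integer"))

setValidity("FociSegmentation", function(object) {
  msg <- character(0)
  need <- c("label", "area", "integrated_intensity")
  if (!all(need %in% names(object@foci)))
    msg <- c(msg, "foci table must have label, area, integrated_intensity")
  if (nrow(object@foci) &&
      !setequal(object@foci$label, setdiff(unique(as.vector(object@labels)), 0L)))
    msg <- c(msg, "foci table labels must match label matrix")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FociSegmentation", function(object) {
  cat("FociSegmentation:", nrow(object@foci), "foci;",
      sum(object@foci$area), "/", object@maskArea, "px condensed\n")
  invisible(NULL)
})

#' Per-focus summary table
#' @param x a [FociSegmentation-class].
#' @return data.frame with one row per focus.
#' @export
fociTable <- function(x) x@foci

#' Focus label matrix
#' @param x a [FociSegmentation-class].
#' @return integer matrix of focus labels (0 = background).
#' @export
fociLabels <- function(x) x@labels

#' Expression-matched cell pairs
#'
#' Result of [propensityMatch()]: 1:1 matched pairs of cells from two
#' construct groups, matched on the logit propensity of group membership
#' given fluorescence intensity, under a caliper.
#'
#' @slot pairs data.frame with columns `cell_a`, `cell_b`, `distance`
#'   (absolute logit-propensity difference).
#' @slot caliper numeric, the caliper actually applied (logit scale).
#' @slot records data.frame of the matched cells (both groups), with the
#'   fitted `propensity` column appended.
#' @export
setClass("MatchedSet",
  representation(pairs = "data.frame", caliper = "numeric",
                 records = "data.frame"))

setValidity("MatchedSet", function(object) {
  msg <- character(0)
  if (nrow(object@pairs)) {
    ids <- c(object@pairs$cell_a, object@pairs$cell_b)
    if (anyDuplicated(ids))
      msg <- c(msg, "each cell may be used in at most one pair")
    if (any(object@pairs$distance > object@caliper + 1e-12))
      msg <- c(msg, "pair distance exceeds caliper")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MatchedSet", function(object) {
  cat("MatchedSet:", nrow(object@pairs), "pairs; caliper",
      format(object@caliper, digits = 4), "(logit propensity)\n")
  invisible(NULL)
})

#' Matched pairs table
#' @param x a [MatchedSet-class].
#' @return data.frame of matched pairs.
#' @export
matchedPairs <- function(x) x@pairs

#' Peak-by-condition binary accessibility matrix
#'
#' A `RangedSummarizedExperiment` whose rows are the unified reference
#' peaks, whose columns are conditions in a recorded order, and whose
#' single assay `"state"` is logical (`TRUE` = open: the reference peak
#' overlapped a peak of that condition by at least the minimum overlap).
#' Built by [labelOccupancy()]; consumed by [encodePatterns()],
#' [queryTransition()] and [samplePeaks()].
#'
#' @export
setClass("OccupancyMatrix", contains = "RangedSummarizedExperiment")

setValidity("OccupancyMatrix", function(object) {
  msg <- character(0)
  if (!identical(SummarizedExperiment::assayNames(object), "state"))
    msg <- c(msg, "exactly one assay named 'state' is required")
  else if (!is.logical(SummarizedExperiment::assay(object, "state")))
    msg <- c(msg, "'state' assay must be logical (TRUE = open)")
  if (is.null(colnames(object)))
    msg <- c(msg, "conditions (colnames) are required")
  if (length(msg)) msg else TRUE
})

#' Open/closed state matrix
#' @param x an [OccupancyMatrix-class].
#' @return logical matrix, peaks x conditions, `TRUE` = open.
#' @export
occupancyStates <- function(x) SummarizedExperiment::assay(x, "state")

#' Condition labels of an occupancy matrix
#' @param x an [OccupancyMatrix-class].
#' @return character vector of condition names, in column order.
#' @export
occupancyConditions <- function(x) colnames(x)
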