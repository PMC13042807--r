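#' The 90-feature grammar vector of a sequence
#'
#' Concatenates, in fixed order: 36 binary-patterning z-scores
#' ([patterningZScores()]), 20 amino-acid fractions, 5 grouped fractions
#' and 2 pseudocounted log-ratios ([compositionFeatures()]), 7
#' charge/global properties ([chargeGlobalFeatures()]), and 19
#' residue-block fractions plus the RG-stretch fraction
#' ([blockFeatures()]). Column names are fixed (see [featureNames90()])
#' so feature matrices from different runs align.
#'
#' @param seq protein sequence.
#' @param nShuffles shuffle count for the patterning null. Default 1000.
#' @param seed integer seed for the shuffle null.
#' @param pairs optional restriction of patterning pairs (see
#'   [patterningZScores()]).
#' @return named numeric vector of length 90 with attribute `"flagged"`
#'   (logical, length 90) marking patterning entries reported as 0.
#' @export
featureVector <- function(seq, nShuffles = 1000L, seed, pairs = NULL) {
  z <- patterningZScores(seq, nShuffles = nShuffles, seed = seed,
                         pairs = pairs)
  v <- c(z, compositionFeatures(seq), chargeGlobalFeatures(seq),
         blockFeatures(seq))
  stopifnot(identical(names(v), featureNames90()))
  flagged <- c(attr(z, "flagged"), rep(FALSE, 54L))
  names(flagged) <- featureNames90()
  attr(v, "flagged") <- flagged
  v
}

#' Feature matrix for the segments of a region
#'
#' Applies [featureVector()] to each segment of an IDR (rows = segments).
#'
#' @param seq full protein sequence.
#' @param segments [IRanges::IRanges] of segments (from
#'   [segmentRegion()]).
#' @inheritParams featureVector
#' @return numeric matrix, segments x 90, with a logical attribute
#'   `"flagged"` of the same shape.
#' @export
segmentFeatureMatrix <- function(seq, segments, nShuffles = 1000L, seed,
                                 pairs = NULL) {
  chars <- .residues(seq)
  mats <- lapply(seq_along(segments), function(i) {
    sub <- paste(chars[IRanges::start(segments)[i]:IRanges::end(segments)[i]],
                 collapse = "")
    featureVector(sub, nShuffles = nShuffles, seed = seed + i - 1L,
                  pairs = pairs)
  })
  m <- do.call(rbind, mats)
  fl <- do.call(rbind, lapply(mats, attr, "flagged"))
  rownames(m) <- rownames(fl) <- paste0("segment_", seq_along(segments))
  attr(m, "flagged") <- fl
  m
}

#' Per-feature variability across a region's segments
#'
#' Population standard deviation (divisor n) of each feature across the
#' segments of one llIDR, quantifying how uniform the grammar is along
#' the region. Features flagged (uncomputable) in every segment are
#' excluded (returned as `NA` and listed in the `"excluded"` attribute).
#'
#' @param features numeric matrix, segments x features (from
#'   [segmentFeatureMatrix()]); needs >= 2 rows.
#' @return named numeric vector of per-feature SDs with attribute
#'   `"excluded"`; all-`NA` with attribute `"undefined" = TRUE` when only
#'   one segment is supplied.
#' @export
featureVariability <- function(features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
    dimnames = list(NULL, names(features)))
  if (nrow(features) < 2L) {
    out <- rep(NA_real_, ncol(features))
    names(out) <- colnames(features)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  n <- nrow(features)
  mu <- colMeans(features)
  sds <- sqrt(colMeans((features - rep(mu, each = n))^2))
  fl <- attr(features, "flagged")
  excluded <- if (!is.null(fl)) colnames(features)[apply(fl, 2L, all)]
              else character(0)
  sds[excluded] <- NA_real_
  attr(sds, "excluded") <- excluded
  sds
}

#' Column-wise z-scoring of a feature matrix for heatmap export
#'
#' Standardizes each feature across the analyzed segment set (mean 0,
#' SD 1; constant columns map to 0), the display convention for grammar
#' heatmaps.
#'
#' @param features numeric matrix, segments x features.
#' @return matrix of the same shape.
#' @export
zScoreColumns <- function(features) {
  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  out <- sweep(features, 2L, mu)
  nz <- sdv > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, sdv[nz], "/")
  out[, !nz] <- 0
  out
}
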