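#' Call intrinsically disordered regions from a disorder-score track
#'
#' Scans a per-residue disorder track (one score in \[0,1\] per residue,
#' as produced by a consensus disorder predictor) for maximal runs of
#' scores at or above `threshold`, and keeps runs strictly longer than
#' `minLen` residues. No gap tolerance is applied: smoothing is the
#' predictor's job, the track is consumed as-is.
#'
#' Coordinates are 1-based closed [IRanges::IRanges] over residue
#' positions, the native R/Bioconductor convention.
#'
#' @param scores numeric vector of per-residue disorder scores in \[0,1\].
#' @param threshold disorder cutoff; residues with score >= threshold are
#'   disordered. Default 0.5.
#' @param minLen regions must be strictly longer than this many residues.
#'   Default 30 (the conventional IDR floor).
#' @return [IRanges::IRanges] of IDRs in coordinate order.
#' @examples
#' callIDRs(c(rep(0.1, 10), rep(0.9, 40), rep(0.1, 10)))
#' @export
callIDRs <- function(scores, threshold = 0.5, minLen = 30L) {
  if (length(scores) == 0L) stop("empty disorder track")
  if (anyNA(scores) || any(scores < 0 | scores > 1))
    stop("disorder scores must lie in [0, 1]")
  r <- rle(scores >= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > minLen
  IRanges::IRanges(start = starts[keep], end = ends[keep])
}

#' Flag long linker IDRs
#'
#' A long linker IDR (llIDR) is an IDR that (1) does not reach the
#' N-terminus, (2) does not reach the C-terminus, and (3) is strictly
#' longer than `minLen` residues — i.e. an internal disordered linker
#' flanked by structured sequence on both sides.
#'
#' @param regions [IRanges::IRanges] of IDRs (from [callIDRs()]).
#' @param proteinLength total protein length in residues.
#' @param minLen llIDR length must be strictly greater. Default 1000.
#' @return `regions` with a logical metadata column `is_llidr`.
#' @examples
#' r <- IRanges::IRanges(101, 1200)
#' selectLLIDRs(r, 1500)
#' @export
selectLLIDRs <- function(regions, proteinLength, minLen = 1000L) {
  if (length(regions) &&
      (min(IRanges::start(regions)) < 1L ||
       max(IRanges::end(regions)) > proteinLength))
    stop("region exceeds protein bounds")
  flag <- IRanges::start(regions) > 1L &
    IRanges::end(regions) < proteinLength &
    IRanges::width(regions) > minLen
  S4Vectors::mcols(regions)$is_llidr <- flag
  regions
}

#' Split an IDR into fixed-size segments
#'
#' Tiles a region with consecutive `blockSize`-residue segments starting
#' at its first residue. If the final remainder is shorter than `minTail`
#' residues it is merged into the preceding segment, so no segment of a
#' region longer than `blockSize` is shorter than `minTail`.
#'
#' @param region a single-range [IRanges::IRanges] (or anything with
#'   `start`/`end`), the IDR to segment.
#' @param blockSize segment size in residues. Default 200.
#' @param minTail minimum size of the final segment before it is merged
#'   into its predecessor. Default 30.
#' @return [IRanges::IRanges] of segments tiling the region in order.
#' @examples
#' segmentRegion(IRanges::IRanges(1, 1050))  # five 200-mers + one 50-mer
#' segmentRegion(IRanges::IRanges(1, 1020))  # four 200-mers + one 220-mer
#' @export
segmentRegion <- function(region, blockSize = 200L, minTail = 30L) {
  if (length(region) != 1L) stop("exactly one region expected")
  s <- IRanges::start(region); e <- IRanges::end(region)
  len <- e - s + 1L
  if (len < minTail) stop("region shorter than ", minTail, " residues")
  nFull <- len %/% blockSize
  tail <- len %% blockSize
  if (nFull == 0L) {
    starts <- s
    ends <- e
  } else if (tail == 0L) {
    starts <- s + blockSize * (seq_len(nFull) - 1L)
    ends <- starts + blockSize - 1L
  } else if (tail < minTail) {
    starts <- s + blockSize * (seq_len(nFull) - 1L)
    ends <- c(starts[-nFull] + blockSize - 1L, e)
  } else {
    starts <- s + blockSize * (seq_len(nFull + 1L) - 1L)
    ends <- c(starts[-(nFull + 1L)] + blockSize - 1L, e)
  }
  IRanges::IRanges(start = starts, end = ends)
}

#' Read per-residue disorder tracks
#'
#' Reads a two-column table (`residue`, `score`; TSV or CSV, header
#' optional via `header`) into a numeric score vector. Residue indices
#' are 1-based and must be consecutive from 1.
#'
#' @param path path to the track file.
#' @param sep field separator; `"\t"` for TSV (default), `","` for CSV.
#' @param header logical; does the file have a header line?
#' @return numeric vector of scores.
#' @export
readDisorderTrack <- function(path, sep = "\t", header = TRUE) {
  tab <- utils::read.table(path, sep = sep, header = header)
  if (ncol(tab) < 2L) stop("expected two columns (residue, score)")
  names(tab)[1:2] <- c("residue", "score")
  if (!identical(as.integer(tab$residue), seq_len(nrow(tab))))
    stop("residue indices must be consecutive from 1 in ", path)
  as.numeric(tab$score)
}
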