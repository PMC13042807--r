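#' Merge peaks with a maximum gap
#'
#' Sorts the intervals and fuses any two whose gap is at most `maxGap`
#' base pairs (bedtools `merge -d` semantics; overlapping or book-ended
#' intervals always fuse). Strand is ignored. The operation is
#' idempotent.
#'
#' @param peaks a [GenomicRanges::GRanges] of peaks (any order, may
#'   overlap).
#' @param maxGap maximum gap in bp between intervals that still fuse.
#'   Default 100.
#' @return sorted, non-overlapping [GenomicRanges::GRanges].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 151),
#'                                                       c(100, 250)))
#' mergePeaks(gr)  # gap 50 <= 100: one interval 1-250
#' @export
mergePeaks <- function(peaks, maxGap = 100L) {
  stopifnot(is(peaks, "GRanges"))
  peaks <- GenomeInfoDb::sortSeqlevels(peaks)
  GenomicRanges::reduce(GenomicRanges::sort(peaks),
                        min.gapwidth = maxGap + 1L,
                        ignore.strand = TRUE)
}

#' Build the unified reference peak set
#'
#' Concatenates the (already per-condition merged) peak sets of all
#' conditions and merges the union with the same gap rule, yielding one
#' reference peak per accessible locus across conditions.
#'
#' @param peakSets named list of [GenomicRanges::GRanges], one per
#'   condition.
#' @param maxGap gap for the union merge. Default 100 (the same gap as
#'   the per-condition merge).
#' @return sorted reference [GenomicRanges::GRanges]; empty with a
#'   warning if all inputs are empty.
#' @export
buildReference <- function(peakSets, maxGap = 100L) {
  if (length(peakSets) < 1L) stop("at least one condition is required")
  all <- suppressWarnings(do.call(c, unname(lapply(peakSets, function(g)
    GenomicRanges::granges(g)))))
  if (length(all) == 0L) {
    warning("empty union: reference peak set is empty")
    return(all)
  }
  mergePeaks(all, maxGap = maxGap)
}

#' Label reference peaks open or closed per condition
#'
#' A reference peak is open in a condition iff it overlaps any peak of
#' that condition's merged peak file by at least `minOverlap` bp, and
#' closed otherwise.
#'
#' @param reference reference [GenomicRanges::GRanges] (from
#'   [buildReference()]).
#' @param peakSets named list of per-condition [GenomicRanges::GRanges].
#' @param minOverlap minimum overlap in bp. Default 1.
#' @return an [OccupancyMatrix-class] (peaks x conditions, logical
#'   `state` assay, `TRUE` = open).
#' @export
labelOccupancy <- function(reference, peakSets, minOverlap = 1L) {
  if (is.null(names(peakSets)) || any(!nzchar(names(peakSets))))
    stop("peakSets must be a named list of conditions")
  refChroms <- GenomeInfoDb::seqlevelsInUse(reference)
  state <- vapply(peakSets, function(g) {
    extra <- setdiff(GenomeInfoDb::seqlevelsInUse(g), refChroms)
    if (length(extra))
      warning("chromosome(s) absent from reference ignored: ",
              paste(extra, collapse = ", "))
    suppressWarnings(
      GenomicRanges::countOverlaps(reference, g, minoverlap = minOverlap,
                                   ignore.strand = TRUE)) > 0L
  }, logical(length(reference)))
  if (is.null(dim(state)))
    state <- matrix(state, nrow = length(reference),
                    dimnames = list(NULL, names(peakSets)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(state = state), rowRanges = reference,
    colData = S4Vectors::DataFrame(condition = names(peakSets),
                                   row.names = names(peakSets)))
  new("OccupancyMatrix", se)
}

#' Encode per-peak accessibility patterns
#'
#' Turns each row of the occupancy matrix into a pattern code over
#' `{C, O}` (closed/open), one character per condition in the requested
#' order — e.g. `"CCOC"` = closed, closed, open, closed — and counts
#' peaks per unique pattern. Pattern counts always sum to the number of
#' reference peaks.
#'
#' @param occupancy an [OccupancyMatrix-class].
#' @param conditionOrder character permutation of the conditions giving
#'   the code's character order.
#' @return list with `codes` (character, one per peak) and `counts`
#'   (named integer, counts per pattern).
#' @export
encodePatterns <- function(occupancy, conditionOrder) {
  st <- occupancyStates(occupancy)
  if (!setequal(conditionOrder, colnames(st)) ||
      length(conditionOrder) != ncol(st))
    stop("conditionOrder must be a permutation of the conditions")
  st <- st[, conditionOrder, drop = FALSE]
  letters <- ifelse(st, "O", "C")
  codes <- apply(letters, 1L, paste, collapse = "")
  if (length(codes) == 0L) codes <- character(0)
  counts <- table(codes)
  list(codes = as.character(codes),
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Query accessibility transitions
#'
#' Selects the reference peaks satisfying a predicate over named
#' condition states and, optionally, the conditional fraction of that
#' subset open in a further condition — e.g. of the peaks closed in FL
#' and open in TR, the fraction still open in LTR.
#'
#' @param occupancy an [OccupancyMatrix-class].
#' @param predicate a function taking the logical state matrix (peaks x
#'   conditions, `TRUE` = open) and returning a logical row selector.
#' @param fractionOpenIn optional condition name; if given, the fraction
#'   of selected peaks open in it is returned (`NA` with
#'   `flagged = TRUE` when the selection is empty).
#' @return list with `index` (selected row indices), `n`, and (when
#'   requested) `fraction` and `flagged`.
#' @export
queryTransition <- function(occupancy, predicate, fractionOpenIn = NULL) {
  st <- occupancyStates(occupancy)
  sel <- predicate(st)
  if (!is.logical(sel) || length(sel) != nrow(st))
    stop("predicate must return one logical per peak")
  idx <- which(sel)
  out <- list(index = idx, n = length(idx))
  if (!is.null(fractionOpenIn)) {
    if (!fractionOpenIn %in% colnames(st))
      stop("unknown condition: ", fractionOpenIn)
    if (length(idx) == 0L) {
      out$fraction <- NA_real_
      out$flagged <- TRUE
    } else {
      out$fraction <- mean(st[idx, fractionOpenIn])
      out$flagged <- FALSE
    }
  }
  out
}

#' Random subset of reference peaks
#'
#' Uniform sample without replacement of `n` rows of the occupancy
#' matrix (seeded), plus a long-format table (peak, condition, state)
#' ready for alluvial plotting.
#'
#' @param occupancy an [OccupancyMatrix-class].
#' @param n subset size; if it exceeds the number of peaks, all peaks
#'   are returned with a warning. Default 5000.
#' @param seed integer seed.
#' @return list with `index` (sorted row indices) and `long`
#'   (data.frame: `peak`, `condition`, `state`).
#' @export
samplePeaks <- function(occupancy, n = 5000L, seed = 1L) {
  st <- occupancyStates(occupancy)
  total <- nrow(st)
  if (n >= total) {
    if (n > total) warning("n exceeds peak count; returning all peaks")
    idx <- seq_len(total)
  } else {
    set.seed(seed)
    idx <- sort(sample.int(total, n))
  }
  conds <- colnames(st)
  long <- data.frame(
    peak = rep(idx, times = length(conds)),
    condition = factor(rep(conds, each = length(idx)), levels = conds),
    state = ifelse(as.vector(st[idx, conds]), "O", "C"))
  list(index = idx, long = long)
}

#' Read a BED3+ peak file
#'
#' @param path path to a BED file (3+ tab-separated columns; extra
#'   columns are preserved as metadata).
#' @return [GenomicRanges::GRanges].
#' @export
readPeakBed <- function(path) {
  if (!file.exists(path)) stop("no such BED file: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Write peaks as BED3
#'
#' @param peaks [GenomicRanges::GRanges].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeakBed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}
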