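## Fraction of the sequence covered by qualifying patches of residue x.
## A patch is the span between two occurrences of x such that consecutive
## occurrences inside are separated by at most maxGap non-x residues;
## it qualifies with at least minOcc occurrences. Disjoint qualifying
## patch spans are summed.
.patchFraction <- function(chars, x, minOcc = 4L, maxGap = 2L) {
  pos <- which(chars == x)
  if (length(pos) < minOcc) return(0)
  grp <- cumsum(c(0L, diff(pos) - 1L > maxGap))
  span <- 0L
  for (g in unique(grp)) {
    p <- pos[grp == g]
    if (length(p) >= minOcc) span <- span + p[length(p)] - p[1L] + 1L
  }
  span / length(chars)
}

## RG-stretch analogue over non-overlapping "RG" dimers: consecutive
## dimers at most maxGap residues apart chain into a stretch, qualifying
## with at least minOcc dimers.
.rgStretchFraction <- function(chars, minOcc = 2L, maxGap = 2L) {
  s <- paste(chars, collapse = "")
  m <- gregexpr("RG", s, fixed = TRUE)[[1L]]
  starts <- m[m > 0L]
  if (length(starts) < minOcc) return(0)
  ends <- starts + 1L
  gaps <- starts[-1L] - ends[-length(ends)] - 1L
  grp <- cumsum(c(0L, gaps > maxGap))
  span <- 0L
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (length(i) >= minOcc) span <- span + ends[i[length(i)]] - starts[i[1L]] + 1L
  }
  span / length(chars)
}

#' Residue-block (run/patch) content features
#'
#' For each of the 19 residues A..Y excluding W, the fraction of the
#' sequence lying inside contiguous runs/patches of that residue: a patch
#' must contain at least 4 occurrences, with at most 2 interrupting
#' residues between consecutive occurrences. The 20th value is the
#' RG-stretch fraction: sequence covered by chains of at least 2
#' non-overlapping "RG" dimers separated by at most 2 residues, the
#' classic Arg-Gly patches of RNA/chromatin interfaces.
#'
#' @param seq protein sequence.
#' @return named numeric vector of length 20 (`block_A` .. `block_Y`,
#'   `rg_stretch`), all in \[0,1\].
#' @examples
#' blockFeatures("EEEE")[["block_E"]]   # 1: one 4-occurrence patch
#' blockFeatures("EEE")[["block_E"]]    # 0: fewer than 4 occurrences
#' blockFeatures("RGRG")[["rg_stretch"]]  # 1
#' @export
blockFeatures <- function(seq) {
  chars <- .residues(seq)
  blockAA <- setdiff(AA20, "W")
  out <- vapply(blockAA, function(x) .patchFraction(chars, x), numeric(1))
  names(out) <- paste0("block_", blockAA)
  c(out, rg_stretch = .rgStretchFraction(chars))
}
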