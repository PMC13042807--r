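## Independent brute-force oracles used across the suite. These stay
## deliberately naive (enumeration, O(n^2) scans) so they check the
## implementations rather than mirror them.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomAASeq <- function(n, letters = AA) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

## Residue-patch oracle: mark residues covered by ANY span between two
## occurrences of x whose internal occurrence gaps are all <= maxGap and
## which contains >= minOcc occurrences; report covered fraction.
patchOracle <- function(seq, x, minOcc = 4, maxGap = 2) {
  chars <- strsplit(seq, "")[[1]]
  pos <- which(chars == x)
  covered <- rep(FALSE, length(chars))
  if (length(pos) >= minOcc) {
    for (i in seq_along(pos)) for (j in i:length(pos)) {
      occ <- pos[i:j]
      if (length(occ) >= minOcc && all(diff(occ) - 1 <= maxGap))
        covered[pos[i]:pos[j]] <- TRUE
    }
  }
  mean(covered)
}

## RG-stretch oracle over left-to-right non-overlapping RG dimers.
rgOracle <- function(seq, minOcc = 2, maxGap = 2) {
  chars <- strsplit(seq, "")[[1]]
  starts <- integer(0)
  i <- 1
  while (i < length(chars)) {
    if (chars[i] == "R" && chars[i + 1] == "G") {
      starts <- c(starts, i)
      i <- i + 2
    } else i <- i + 1
  }
  covered <- rep(FALSE, length(chars))
  if (length(starts) >= minOcc) {
    ends <- starts + 1
    for (i in seq_along(starts)) for (j in i:length(starts)) {
      if (j - i + 1 >= minOcc) {
        gaps <- starts[(i + 1):j] - ends[i:(j - 1)] - 1
        if (all(gaps <= maxGap)) covered[starts[i]:ends[j]] <- TRUE
      }
    }
  }
  mean(covered)
}

## Run-scan oracle for IDR calling: walk the track residue by residue.
runScanOracle <- function(scores, threshold = 0.5, minLen = 30) {
  out <- NULL
  start <- NA
  for (i in seq_along(scores)) {
    if (scores[i] >= threshold && is.na(start)) start <- i
    if ((scores[i] < threshold || i == length(scores)) && !is.na(start)) {
      end <- if (scores[i] < threshold) i - 1 else i
      if (end - start + 1 > minLen) out <- rbind(out, c(start, end))
      start <- NA
    }
  }
  out
}

## Pairwise-fusion merge oracle: repeatedly fuse any two intervals that
## overlap or whose gap is <= maxGap, until stable. Intervals as a
## data.frame(chrom, start, end), 1-based closed.
mergeOracle <- function(df, maxGap = 100) {
  repeat {
    fused <- FALSE
    n <- nrow(df)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j) next
        if (df$chrom[i] != df$chrom[j]) next
        gap <- max(df$start[i], df$start[j]) -
          min(df$end[i], df$end[j]) - 1
        if (gap <= maxGap) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          fused <- TRUE
          break
        }
      }
      if (fused) break
    }
    if (!fused) break
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

grToDf <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

## Two-sided Fisher p by direct enumeration with log-factorial
## probabilities (independent of dhyper), same floating-point tie guard.
fisherEnumOracle <- function(tab) {
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); n1 <- sum(tab[, 1])
  ks <- max(0, n1 - m2):min(m1, n1)
  logp <- function(a) {
    lchoose(m1, a) + lchoose(m2, n1 - a) - lchoose(m1 + m2, n1)
  }
  probs <- exp(vapply(ks, logp, numeric(1)))
  pObs <- exp(logp(tab[1, 1]))
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

## Population SD (divisor n).
popSD <- function(x) sqrt(mean((x - mean(x))^2))
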