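## Blockiness statistic on a ternary label vector (+1 class X, -1 class Y,
## 0 other): variance of the windowed charge/class asymmetry
## sigma = (f+ - f-)^2 / (f+ + f-) around the whole-sequence asymmetry,
## averaged over the window sizes. Windows where neither class occurs
## contribute sigma = 0.
.blockinessStat <- function(lab, windows = c(5L, 6L)) {
  L <- length(lab)
  ip <- as.numeric(lab > 0L)
  im <- as.numeric(lab < 0L)
  np <- sum(ip); nm <- sum(im)
  sAll <- if (np + nm > 0) ((np - nm) / L)^2 / ((np + nm) / L) else 0
  cp <- cumsum(ip); cm <- cumsum(im)
  acc <- 0; k <- 0L
  for (g in windows) {
    if (g > L) next
    wp <- cp[g:L] - c(0, cp[seq_len(L - g)])
    wm <- cm[g:L] - c(0, cm[seq_len(L - g)])
    s <- wp + wm
    sig <- numeric(length(s))
    nz <- s > 0
    sig[nz] <- ((wp[nz] - wm[nz])^2) / (g * s[nz])
    acc <- acc + mean((sig - sAll)^2)
    k <- k + 1L
  }
  if (k == 0L) stop("sequence shorter than every window size")
  acc / k
}

#' Binary patterning z-scores over residue-class pairs
#'
#' Quantifies how "blocky" versus "well-mixed" each pair of residue
#' classes is arranged along the sequence, relative to the sequence's own
#' compositional shuffle null. The eight classes are polar, hydrophobic,
#' positive, negative, aromatic, alanine, proline and glycine; all
#' unordered pairs including self-pairs give 36 scores.
#'
#' For a pair (X, Y) residues are labeled +1 (X), -1 (Y) or 0 (other;
#' for self-pairs, +1/0), the blockiness statistic (variance of windowed
#' class asymmetry, windows 5 and 6 averaged, in the kappa family) is
#' computed on the labels, and the z-score is taken against `nShuffles`
#' within-sequence permutations. Positive z = blocky clustering;
#' negative z = well-mixed. Only the z-score is reported, so the shared
#' statistic constant cancels under the null.
#'
#' Pairs where either class has fewer than 2 residues (or whose shuffle
#' SD is zero) are reported as 0 and flagged.
#'
#' @param seq protein sequence, length >= 10.
#' @param nShuffles number of within-sequence shuffles (>= 50).
#'   Default 1000.
#' @param seed integer seed for the shuffle null (mandatory: z-scores are
#'   reproducible per seed).
#' @param pairs optional character vector of pair names
#'   (e.g. `"z_pos_neg"`) to restrict computation to; others are returned
#'   as 0 and flagged uncomputed.
#' @return named numeric vector of the 36 z-scores, with a logical
#'   attribute `"flagged"` marking entries reported as 0.
#' @examples
#' z <- patterningZScores(strrep("E", 10) |> paste0(strrep("K", 10)),
#'                        nShuffles = 100, seed = 1)
#' z[["z_pos_neg"]] > 0  # a diblock is maximally blocky
#' @export
patterningZScores <- function(seq, nShuffles = 1000L, seed,
                              pairs = NULL) {
  if (nShuffles < 50L) stop("nShuffles must be at least 50")
  if (missing(seed)) stop("a seed is required")
  chars <- .residues(seq)
  L <- length(chars)
  if (L < 10L) stop("sequence must have at least 10 residues")

  cls <- names(PATTERN_CLASSES)
  member <- vapply(PATTERN_CLASSES, function(s) chars %in% s,
                   logical(L))
  pairNames <- featureNames90()[1:36]
  pairIdx <- which(upper.tri(diag(8), diag = TRUE), arr.ind = TRUE)
  pairIdx <- pairIdx[order(pairIdx[, "row"], pairIdx[, "col"]), , drop = FALSE]

  labels <- vector("list", 36L)
  eligible <- logical(36L)
  for (p in seq_len(36L)) {
    i <- pairIdx[p, "row"]; j <- pairIdx[p, "col"]
    if (i == j) {
      lab <- ifelse(member[, i], 1L, 0L)
      eligible[p] <- sum(member[, i]) >= 2L
    } else {
      lab <- ifelse(member[, i], 1L, ifelse(member[, j], -1L, 0L))
      eligible[p] <- sum(lab == 1L) >= 2L && sum(lab == -1L) >= 2L
    }
    labels[[p]] <- lab
  }
  compute <- eligible
  if (!is.null(pairs)) compute <- compute & pairNames %in% pairs

  z <- numeric(36L)
  names(z) <- pairNames
  flagged <- !compute
  idx <- which(compute)
  if (length(idx)) {
    obs <- vapply(idx, function(p) .blockinessStat(labels[[p]]), numeric(1))
    set.seed(seed)
    null <- matrix(0, nrow = nShuffles, ncol = length(idx))
    for (s in seq_len(nShuffles)) {
      perm <- sample.int(L)
      null[s, ] <- vapply(seq_along(idx), function(k)
        .blockinessStat(labels[[idx[k]]][perm]), numeric(1))
    }
    mu <- colMeans(null)
    sdv <- apply(null, 2L, stats::sd)
    for (k in seq_along(idx)) {
      if (sdv[k] > 0) {
        z[idx[k]] <- (obs[k] - mu[k]) / sdv[k]
      } else {
        flagged[idx[k]] <- TRUE
      }
    }
  }
  attr(z, "flagged") <- stats::setNames(flagged, pairNames)
  z
}
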