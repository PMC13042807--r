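#' Simulate a block-architecture protein sequence
#'
#' Draws a sequence as a concatenation of labeled blocks, each with its
#' own composition weights over the 20 amino acids — e.g. a basic
#' platform followed by an acidic charge block. The returned annotation
#' records every block's residue span and net charge sign, the ground
#' truth for charge-architecture analyses.
#'
#' @param blocks data.frame with columns `label`, `length`, and a
#'   `weights` list-column of named nonnegative weight vectors over
#'   (a subset of) the 20 amino acids, each summing to 1.
#' @param seed integer seed.
#' @return list with `sequence` (string) and `annotation` (data.frame:
#'   `label`, `start`, `end`, `ncpr`, `charge_sign`).
#' @examples
#' b <- data.frame(label = c("basic", "acidic"), length = c(30, 30))
#' b$weights <- list(c(K = 1), c(E = 1))
#' simulateSequence(b, seed = 1)$annotation
#' @export
simulateSequence <- function(blocks, seed) {
  if (!all(c("label", "length", "weights") %in% names(blocks)))
    stop("blocks needs columns label, length, weights")
  if (any(blocks$length <= 0L)) stop("zero-length block")
  set.seed(seed)
  parts <- character(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    w <- blocks$weights[[i]]
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop("block weights must be nonnegative and sum to 1")
    if (!all(names(w) %in% AA20)) stop("weights must be named by residues")
    parts[i] <- paste(sample(names(w), blocks$length[i], replace = TRUE,
                             prob = w), collapse = "")
  }
  ends <- cumsum(blocks$length)
  starts <- ends - blocks$length + 1L
  ncpr <- vapply(parts, function(p)
    unname(chargeGlobalFeatures(p)["NCPR"]), numeric(1))
  list(
    sequence = paste(parts, collapse = ""),
    annotation = data.frame(
      label = blocks$label, start = starts, end = ends,
      ncpr = unname(ncpr),
      charge_sign = sign(unname(ncpr))))
}

#' Simulate a nuclear image with Gaussian puncta
#'
#' Builds a circular nuclear mask, adds a uniform background inside it,
#' superimposes isotropic Gaussian puncta (all centers must fall inside
#' the mask), adds optional Gaussian noise, and clips at zero. The
#' ground truth marks pixels within `2 * sigma` of each center
#' (capturing >= 95% of each punctum's mass) and reports the condensed
#' area and intensity fractions of the noiseless image.
#'
#' @param shape integer length-2, image size in pixels (rows, cols).
#'   Default `c(128, 128)`.
#' @param nucleusRadius nucleus radius in pixels. Default 48.
#' @param background background intensity inside the nucleus. Default 20.
#' @param puncta data.frame with columns `row`, `col`, `sigma`,
#'   `amplitude` (amplitudes >= 0); may have zero rows.
#' @param noiseSd additive Gaussian noise SD. Default 0.
#' @param seed integer seed.
#' @return list with `image` (a [NucleusImage-class]), `truth_mask`
#'   (logical matrix), `area_fraction`, `intensity_fraction` (ground
#'   truth on the noiseless image).
#' @export
simulateNucleusImage <- function(shape = c(128L, 128L),
                                 nucleusRadius = 48,
                                 background = 20,
                                 puncta = data.frame(),
                                 noiseSd = 0, seed = 1L) {
  nr <- shape[1L]; nc <- shape[2L]
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- (rows - cr)^2 + (cols - cc)^2 <= nucleusRadius^2
  img <- matrix(0, nr, nc)
  img[mask] <- background
  truth <- matrix(FALSE, nr, nc)
  if (nrow(puncta)) {
    if (any(puncta$amplitude < 0)) stop("amplitudes must be nonnegative")
    inside <- mask[cbind(round(puncta$row), round(puncta$col))]
    if (!all(inside)) stop("puncta centers must lie inside the nucleus")
    for (i in seq_len(nrow(puncta))) {
      d2 <- (rows - puncta$row[i])^2 + (cols - puncta$col[i])^2
      img <- img + puncta$amplitude[i] * exp(-d2 / (2 * puncta$sigma[i]^2))
      if (puncta$amplitude[i] > 0)
        truth <- truth | (d2 <= (2 * puncta$sigma[i])^2 & mask)
    }
  }
  clean <- img
  if (noiseSd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
  }
  img <- pmax(img, 0)
  totalClean <- sum(clean[mask])
  list(
    image = NucleusImage(img, mask),
    truth_mask = truth,
    area_fraction = sum(truth) / sum(mask),
    intensity_fraction = if (totalClean > 0)
      sum(clean[truth]) / totalClean else 0)
}

#' Simulate a line scan across puncta
#'
#' One-dimensional analogue of the nuclear image: a constant baseline,
#' Gaussian puncta at given centers, additive noise, clipped at zero.
#'
#' @param n number of samples. Default 101.
#' @param baseline baseline intensity. Default 100.
#' @param centers punctum centers (sample index).
#' @param sigma punctum width (samples). Default 3.
#' @param amplitude punctum amplitude(s).
#' @param noiseSd additive Gaussian noise SD. Default 0.
#' @param seed integer seed.
#' @return numeric vector of intensities.
#' @export
simulateLineScan <- function(n = 101L, baseline = 100, centers = 51,
                             sigma = 3, amplitude = 50, noiseSd = 0,
                             seed = 1L) {
  x <- seq_len(n)
  y <- rep(baseline, n)
  amplitude <- rep_len(amplitude, length(centers))
  for (i in seq_along(centers))
    y <- y + amplitude[i] * exp(-(x - centers[i])^2 / (2 * sigma^2))
  if (noiseSd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(n, 0, noiseSd)
  }
  pmax(y, 0)
}

#' Simulate a FRAP measurement
#'
#' Emits the three raw ROI traces (bleach, background, total) of a FRAP
#' acquisition with a programmed mobile fraction: pre-bleach frames at
#' a plateau, an instantaneous bleach after frame `bleachFrame - 1`,
#' then single-exponential recovery
#' `I(t) = I_bleach + M * (I_pre - I_bleach) * (1 - exp(-t / tau))`.
#' Noiseless output satisfies the recovery model exactly after double
#' normalization, so [frapNormalize()] recovers `M` to numerical
#' precision.
#'
#' @param mobileFraction programmed mobile fraction in \[0,1\].
#' @param tau recovery time constant in seconds. Default 5.
#' @param nFrames number of frames. Default 85.
#' @param interval frame interval in seconds. Default 0.8.
#' @param bleachFrame first post-bleach frame. Default 6.
#' @param preLevel pre-bleach bleach-ROI intensity. Default 100.
#' @param bleachDepth immediate post-bleach fraction of `preLevel`.
#'   Default 0.2.
#' @param totalLevel total-area intensity. Default 1000.
#' @param background background intensity added to all ROIs. Default 10.
#' @param noiseSd additive Gaussian noise SD. Default 0.
#' @param seed integer seed.
#' @return data.frame with columns `time`, `bleach`, `background`,
#'   `total`.
#' @export
simulateFrapTrace <- function(mobileFraction, tau = 5, nFrames = 85L,
                              interval = 0.8, bleachFrame = 6L,
                              preLevel = 100, bleachDepth = 0.2,
                              totalLevel = 1000, background = 10,
                              noiseSd = 0, seed = 1L) {
  if (mobileFraction < 0 || mobileFraction > 1)
    stop("mobile fraction must lie in [0, 1]")
  t <- (seq_len(nFrames) - 1L) * interval
  I0 <- preLevel * bleachDepth
  I <- rep(preLevel, nFrames)
  post <- bleachFrame:nFrames
  tp <- t[post] - t[bleachFrame]
  I[post] <- I0 + mobileFraction * (preLevel - I0) * (1 - exp(-tp / tau))
  out <- data.frame(
    time = t,
    bleach = I + background,
    background = rep(background, nFrames),
    total = rep(totalLevel, nFrames) + background)
  if (noiseSd > 0) {
    set.seed(seed)
    out$bleach <- pmax(out$bleach + stats::rnorm(nFrames, 0, noiseSd), 0)
    out$total <- pmax(out$total + stats::rnorm(nFrames, 0, noiseSd), 0)
  }
  out
}

#' Simulate acceptor-photobleach FRET ROI intensities
#'
#' Generates raw ROI tables satisfying the pbFRET forward model: with
#' drift factor `b` and programmed efficiency `E`,
#' `D_post = D_pre * b / (1 - E)` and `DN_post = DN_pre * b`, each plus
#' the per-image background (and optional noise). On noiseless output
#' [pbfretEfficiency()] inverts the model exactly.
#'
#' @param efficiency programmed FRET efficiency `E` (< 1; may be
#'   negative).
#' @param drift drift factor `b` (> 0). Default 1.
#' @param n number of cells/ROIs. Default 1.
#' @param dPre donor pre-bleach intensity (bleached ROI, above
#'   background). Default 90.
#' @param dnPre donor pre-bleach intensity (negative ROI). Default 80.
#' @param background per-image background level. Default 0.
#' @param noiseSd additive Gaussian noise SD. Default 0.
#' @param seed integer seed.
#' @return data.frame with columns `D_pre`, `D_post`, `DN_pre`,
#'   `DN_post`, `bg_pre`, `bg_post`.
#' @export
simulatePbfretRois <- function(efficiency, drift = 1, n = 1L,
                               dPre = 90, dnPre = 80, background = 0,
                               noiseSd = 0, seed = 1L) {
  if (any(efficiency >= 1)) stop("efficiency must be < 1")
  if (any(drift <= 0)) stop("drift factor must be positive")
  out <- data.frame(
    D_pre = rep(dPre + background, n),
    D_post = rep(dPre * drift / (1 - efficiency) + background, n),
    DN_pre = rep(dnPre + background, n),
    DN_post = rep(dnPre * drift + background, n),
    bg_pre = rep(background, n),
    bg_post = rep(background, n))
  if (noiseSd > 0) {
    set.seed(seed)
    for (col in c("D_pre", "D_post", "DN_pre", "DN_post"))
      out[[col]] <- pmax(out[[col]] + stats::rnorm(n, 0, noiseSd), 0)
  }
  out
}

#' Simulate a two-group cell population
#'
#' Draws per-cell fluorescence intensities (normal, clipped at zero)
#' for two construct groups and assigns a binary condensate label from
#' a logistic model
#' `P(condensate) = plogis(intercept + groupEffect * [group == B] +
#' intensityEffect * intensity)`, emulating cohorts where condensation
#' may depend on the construct, on expression level, or both.
#'
#' @param nPerGroup named integer vector, cells per group (two groups).
#'   Default `c(A = 100, B = 100)`.
#' @param intensityMean,intensitySd named numeric vectors (per group) of
#'   the intensity distribution.
#' @param model list with `intercept`, `groupEffect`, `intensityEffect`.
#' @param seed integer seed.
#' @return data.frame with columns `cell_id`, `group`, `intensity`,
#'   `condensate` (logical).
#' @export
simulatePopulation <- function(nPerGroup = c(A = 100L, B = 100L),
                               intensityMean = c(A = 100, B = 100),
                               intensitySd = c(A = 20, B = 20),
                               model = list(intercept = 0,
                                            groupEffect = 0,
                                            intensityEffect = 0),
                               seed = 1L) {
  if (length(nPerGroup) != 2L || is.null(names(nPerGroup)))
    stop("nPerGroup must name exactly two groups")
  if (any(nPerGroup <= 0L)) stop("empty group")
  set.seed(seed)
  groups <- names(nPerGroup)
  rows <- lapply(groups, function(g) {
    int <- pmax(stats::rnorm(nPerGroup[[g]], intensityMean[[g]],
                             intensitySd[[g]]), 0)
    p <- stats::plogis(model$intercept +
                       model$groupEffect * (g == groups[2L]) +
                       model$intensityEffect * int)
    data.frame(group = g, intensity = int,
               condensate = stats::runif(nPerGroup[[g]]) < p)
  })
  out <- do.call(rbind, rows)
  out$cell_id <- sprintf("cell_%04d", seq_len(nrow(out)))
  out[, c("cell_id", "group", "intensity", "condensate")]
}

#' Simulate four-condition peak sets with programmed patterns
#'
#' Lays out non-overlapping reference peaks along synthetic chromosomes
#' with inter-peak gaps strictly greater than the merge gap (so merging
#' never fuses distinct ground-truth units), assigns each reference
#' peak a pattern code drawn from `patternFreq`, and emits one peak set
#' per condition containing the peaks open ("O") in it. Peaks whose
#' pattern is closed everywhere appear in no file and hence in no
#' reference.
#'
#' @param n number of reference peaks. Default 200.
#' @param conditions condition labels (pattern character order).
#'   Default `c("EV", "FL", "TR", "LTR")`.
#' @param patternFreq named numeric vector of pattern frequencies over
#'   codes of length `length(conditions)` on `{C,O}`; must sum to 1.
#' @param nChromosomes number of chromosomes. Default 2.
#' @param widthRange peak width range in bp. Default `c(200, 600)`.
#' @param gapRange inter-peak gap range in bp; the minimum must exceed
#'   `maxGap`. Default `c(150, 500)`.
#' @param maxGap merge gap the layout must defeat. Default 100.
#' @param seed integer seed.
#' @return list with `peakSets` (named list of
#'   [GenomicRanges::GRanges]), `truth` (data.frame: `chrom`, `start`,
#'   `end`, `pattern`), `pattern_counts` (named integer over emitted,
#'   i.e. not-all-closed, patterns).
#' @export
simulatePeakSets <- function(n = 200L,
                             conditions = c("EV", "FL", "TR", "LTR"),
                             patternFreq,
                             nChromosomes = 2L,
                             widthRange = c(200L, 600L),
                             gapRange = c(150L, 500L),
                             maxGap = 100L, seed = 1L) {
  if (abs(sum(patternFreq) - 1) > 1e-8)
    stop("pattern frequencies must sum to 1")
  nc <- nchar(names(patternFreq))
  if (any(nc != length(conditions)) ||
      any(!grepl("^[CO]+$", names(patternFreq))))
    stop("pattern codes must be strings over {C,O} of length ",
         length(conditions))
  if (gapRange[1L] <= maxGap)
    stop("minimum gap must exceed the merge gap (", maxGap, " bp)")
  set.seed(seed)
  chroms <- sample(paste0("chr", seq_len(nChromosomes)), n, replace = TRUE)
  widths <- sample(widthRange[1L]:widthRange[2L], n, replace = TRUE)
  gaps <- sample(gapRange[1L]:gapRange[2L], n, replace = TRUE)
  patterns <- sample(names(patternFreq), n, replace = TRUE,
                     prob = patternFreq)
  start <- integer(n)
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    start[i] <- cumsum(gaps[i]) + c(0L, cumsum(widths[i]))[seq_along(i)] + 1L
  }
  truth <- data.frame(chrom = chroms, start = start,
                      end = start + widths - 1L, pattern = patterns)
  truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  peakSets <- lapply(seq_along(conditions), function(j) {
    open <- substr(truth$pattern, j, j) == "O"
    GenomicRanges::GRanges(truth$chrom[open],
                           IRanges::IRanges(truth$start[open],
                                            truth$end[open]))
  })
  names(peakSets) <- conditions
  emitted <- truth$pattern[truth$pattern != strrep("C", length(conditions))]
  counts <- table(emitted)
  list(peakSets = peakSets, truth = truth,
       pattern_counts = stats::setNames(as.integer(counts), names(counts)))
}
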