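## 8-connected component labeling by iterative minimum-label propagation.
## Foreground pixels start with unique labels; each sweep replaces every
## label by the minimum over its 8-neighborhood until a fixed point.
.label8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  lab[fg] <- seq_len(sum(fg))
  if (!any(fg)) return(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  big <- .Machine$integer.max
  repeat {
    cur <- lab
    m <- matrix(big, nr, nc)
    m[fg] <- lab[fg]
    for (s in shifts) {
      sh <- matrix(big, nr, nc)
      rsrc <- seq_len(nr) - s[1L]
      csrc <- seq_len(nc) - s[2L]
      rok <- rsrc >= 1L & rsrc <= nr
      cok <- csrc >= 1L & csrc <= nc
      tmp <- matrix(big, nr, nc)
      tmp[rok, cok] <- ifelse(fg[rsrc[rok], csrc[cok], drop = FALSE],
                              lab[rsrc[rok], csrc[cok], drop = FALSE], big)
      m <- pmin(m, tmp)
    }
    lab[fg] <- m[fg]
    if (identical(lab, cur)) break
  }
  ## renumber components consecutively in first-appearance order
  u <- sort(unique(lab[fg]))
  lab[fg] <- match(lab[fg], u)
  lab
}

#' Segment condensate foci by intensity windowing
#'
#' Selects pixels inside the nuclear mask whose intensity lies within
#' the window `[low, high]` (the convention of intensity-window
#' thresholding on the image's native scale), groups them into
#' 8-connected components, and discards components smaller than
#' `minArea` pixels.
#'
#' @param image a [NucleusImage-class].
#' @param window numeric length-2, `(low, high)` intensity window.
#'   Default `c(10, 50)`; interpret on your image's native scale.
#' @param minArea minimum focus area in pixels. Default 4.
#' @return a [FociSegmentation-class].
#' @export
segmentFoci <- function(image, window = c(10, 50), minArea = 4L) {
  stopifnot(is(image, "NucleusImage"))
  if (!any(image@mask)) stop("empty nuclear mask")
  fg <- image@mask & image@intensity >= window[1] &
    image@intensity <= window[2]
  lab <- .label8(fg)
  if (any(lab > 0L)) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= minArea)
    lab[!(lab %in% keep)] <- 0L
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
    k <- length(keep)
    foci <- data.frame(
      label = seq_len(k),
      area = tabulate(lab[lab > 0L], nbins = k),
      integrated_intensity = vapply(seq_len(k), function(i)
        sum(image@intensity[lab == i]), numeric(1))
    )
  } else {
    foci <- data.frame(label = integer(0), area = integer(0),
                       integrated_intensity = numeric(0))
  }
  new("FociSegmentation", labels = lab, foci = foci,
      maskArea = sum(image@mask))
}

#' Condensed area and intensity fractions
#'
#' Per-nucleus condensation burden: the fraction of nuclear area covered
#' by segmented foci, and the fraction of total nuclear fluorescence
#' contained in them.
#'
#' @param image the [NucleusImage-class] the segmentation came from.
#' @param foci a [FociSegmentation-class] of `image`.
#' @return named numeric vector `c(area_fraction, intensity_fraction)`,
#'   both in \[0,1\].
#' @export
condensedFractions <- function(image, foci) {
  stopifnot(is(image, "NucleusImage"), is(foci, "FociSegmentation"))
  total <- sum(image@intensity[image@mask])
  if (total <= 0) stop("zero total nuclear fluorescence")
  c(area_fraction = sum(foci@foci$area) / sum(image@mask),
    intensity_fraction = sum(foci@foci$integrated_intensity) / total)
}

#' Number of puncta in a segmentation
#'
#' @param foci a [FociSegmentation-class].
#' @return integer count of labeled foci.
#' @export
countPuncta <- function(foci) {
  stopifnot(is(foci, "FociSegmentation"))
  nrow(foci@foci)
}

#' Pearson colocalization of two channels within a mask
#'
#' Pearson correlation of pixel intensities of two same-shaped images
#' over the masked (nuclear) pixels, the per-cell colocalization
#' statistic.
#'
#' @param imageA,imageB numeric matrices (same shape), the two channels.
#' @param mask logical matrix restricting the comparison.
#' @return Pearson r in \[-1, 1\].
#' @export
pearsonColocalization <- function(imageA, imageB, mask) {
  if (!identical(dim(imageA), dim(imageB)) ||
      !identical(dim(imageA), dim(mask)))
    stop("images and mask must share dimensions")
  a <- imageA[mask]; b <- imageB[mask]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop("zero variance within mask")
  stats::cor(a, b)
}
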