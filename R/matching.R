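#' Classify per-cell condensation state
#'
#' Three-way morphological/dynamic classification of a cell's puncta:
#' no foci means diffuse; foci that are round (circularity >= `cMin`)
#' and dynamic (FRAP mobile fraction >= `mMin`) are liquid-like (LLPS);
#' anything else is an aggregate. Thresholds are declared, configurable
#' numbers. Cells with foci but a missing mobile fraction cannot be
#' separated into LLPS vs aggregate and are flagged `unclassified`.
#'
#' @param circularity per-cell focus circularity in \[0,1\] (may be NA
#'   when `hasFoci` is FALSE).
#' @param mobileFraction per-cell FRAP mobile fraction (may be NA).
#' @param hasFoci logical; does the cell show puncta?
#' @param cMin circularity threshold. Default 0.8.
#' @param mMin mobile-fraction threshold. Default 0.5.
#' @return character vector over
#'   `{"diffuse", "LLPS", "aggregate", "unclassified"}`.
#' @export
classifyState <- function(circularity, mobileFraction, hasFoci,
                          cMin = 0.8, mMin = 0.5) {
  n <- max(length(circularity), length(mobileFraction), length(hasFoci))
  circularity <- rep_len(circularity, n)
  mobileFraction <- rep_len(mobileFraction, n)
  hasFoci <- rep_len(hasFoci, n)
  out <- character(n)
  out[!hasFoci] <- "diffuse"
  withFoci <- which(hasFoci)
  miss <- withFoci[is.na(mobileFraction[withFoci]) |
                   is.na(circularity[withFoci])]
  out[miss] <- "unclassified"
  rest <- setdiff(withFoci, miss)
  out[rest] <- ifelse(circularity[rest] >= cMin &
                      mobileFraction[rest] >= mMin, "LLPS", "aggregate")
  out
}

#' Propensity-score matching of cells on fluorescence intensity
#'
#' Removes expression-level confounding before comparing condensation
#' between two constructs: fits a logistic regression of group on
#' intensity, and greedily 1:1 matches cells across groups on the logit
#' propensity, nearest neighbor without replacement, under a caliper of
#' `caliper` standard deviations of the logit propensity (the
#' conventional reading of "caliper of 0.2"; set
#' `caliperScale = "raw"` to interpret `caliper` as an absolute logit
#' width). The processing order of the treated group is randomized by
#' `seed`, which also breaks distance ties deterministically.
#'
#' @param records data.frame with columns `cell_id`, `group` (exactly
#'   two levels), `intensity`, and any outcome columns (carried along).
#' @param caliper caliper width. Default 0.2.
#' @param seed integer seed for the processing order.
#' @param caliperScale `"sd"` (default) or `"raw"`.
#' @return a [MatchedSet-class]; empty (with a warning) when no pair
#'   fits within the caliper.
#' @export
propensityMatch <- function(records, caliper = 0.2, seed = 1L,
                            caliperScale = c("sd", "raw")) {
  caliperScale <- match.arg(caliperScale)
  need <- c("cell_id", "group", "intensity")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  groups <- sort(unique(as.character(records$group)))
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (any(table(records$group) == 0L)) stop("empty group")
  g2 <- as.integer(records$group == groups[2L])
  fit <- stats::glm(g2 ~ intensity, family = stats::binomial(),
                    data = records)
  lp <- as.numeric(stats::predict(fit, type = "link"))
  width <- if (caliperScale == "sd") caliper * stats::sd(lp) else caliper

  ## treat the smaller group; match into the larger
  sizes <- table(factor(records$group, levels = groups))
  tGroup <- groups[which.min(sizes)]
  treated <- which(records$group == tGroup)
  control <- which(records$group != tGroup)
  set.seed(seed)
  treated <- treated[sample.int(length(treated))]
  avail <- rep(TRUE, length(control))
  pairs <- vector("list", length(treated))
  for (k in seq_along(treated)) {
    d <- abs(lp[control] - lp[treated[k]])
    d[!avail] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= width) {
      avail[j] <- FALSE
      pairs[[k]] <- data.frame(
        cell_a = records$cell_id[treated[k]],
        cell_b = records$cell_id[control[j]],
        distance = d[j])
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    pairs <- data.frame(cell_a = character(0), cell_b = character(0),
                        distance = numeric(0))
  if (nrow(pairs) == 0L) warning("no pairs within caliper")
  rec <- records
  rec$propensity <- lp
  matched <- rec[rec$cell_id %in% c(pairs$cell_a, pairs$cell_b), ,
                 drop = FALSE]
  new("MatchedSet", pairs = pairs, caliper = width, records = matched)
}

## Two-sided Fisher exact p by hypergeometric enumeration over all
## tables with the observed margins: sum the probabilities of tables no
## more probable than the observed one (standard 1e-7 relative guard
## against floating-point ties).
.fisherTwoSided <- function(tab) {
  m1 <- sum(tab[1L, ]); m2 <- sum(tab[2L, ])
  n1 <- sum(tab[, 1L])
  a <- tab[1L, 1L]
  k <- max(0L, n1 - m2):min(m1, n1)
  probs <- stats::dhyper(k, m1, m2, n1)
  pObs <- stats::dhyper(a, m1, m2, n1)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Fisher's exact test for condensate formation on matched cells
#'
#' Builds the 2x2 table of group by condensate presence over the matched
#' cells and computes the two-sided exact p-value by hypergeometric
#' enumeration, plus an odds ratio (Haldane 0.5 correction when any cell
#' is zero). A degenerate table (an empty margin) carries no information
#' and is returned with p = 1 and `flagged = TRUE`.
#'
#' @param matched a [MatchedSet-class] whose records carry a logical
#'   `condensate` column, or a 2x2 integer matrix of counts.
#' @return list with `table` (2x2 counts), `odds_ratio`, `p_value`,
#'   `flagged`.
#' @export
fisherCondensateTest <- function(matched) {
  if (is(matched, "MatchedSet")) {
    rec <- matched@records
    if (nrow(matched@pairs) == 0L) stop("no matched pairs")
    if (!"condensate" %in% names(rec))
      stop("matched records need a logical 'condensate' column")
    tab <- as.matrix(table(factor(rec$group),
                           factor(rec$condensate, levels = c(TRUE, FALSE))))
  } else {
    tab <- as.matrix(matched)
    if (!identical(dim(tab), c(2L, 2L))) stop("a 2x2 table is required")
  }
  storage.mode(tab) <- "integer"
  flagged <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  p <- if (flagged) 1 else .fisherTwoSided(tab)
  orTab <- tab
  if (any(orTab == 0L)) orTab <- orTab + 0.5
  orv <- (orTab[1, 1] * orTab[2, 2]) / (orTab[1, 2] * orTab[2, 1])
  list(table = tab, odds_ratio = orv, p_value = p, flagged = flagged)
}
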