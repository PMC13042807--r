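#' Amino-acid composition features
#'
#' Computes the 27 composition features of the grammar vector: the 20
#' per-residue fractions (alphabetical A..Y), five grouped fractions
#' (K+R, D+E, polar, aliphatic, aromatic), and the two pseudocounted
#' log-ratios `log10((nK+1)/(nR+1))` and `log10((nE+1)/(nD+1))`.
#' Higher K/R means lysine-biased basicity; higher E/D means
#' glutamate-biased acidity.
#'
#' @param seq protein sequence (single string over the 20-letter alphabet).
#' @return named numeric vector of length 27.
#' @examples
#' compositionFeatures("KRKR")[["frac_KR"]]  # 1
#' @export
compositionFeatures <- function(seq) {
  chars <- .residues(seq)
  L <- length(chars)
  counts <- table(factor(chars, levels = AA20))
  frac <- as.numeric(counts) / L
  names(frac) <- paste0("frac_", AA20)
  ## grouped fractions from integer count sums, so e.g.
  ## frac_KR + frac_DE is bitwise identical to FCR
  grouped <- vapply(GROUP_SETS, function(s)
    sum(as.numeric(counts[s])) / L, numeric(1))
  names(grouped) <- paste0("frac_", names(GROUP_SETS))
  ratios <- c(
    log10_KR = log10((counts[["K"]] + 1) / (counts[["R"]] + 1)),
    log10_ED = log10((counts[["E"]] + 1) / (counts[["D"]] + 1))
  )
  c(frac, grouped, ratios)
}

#' Charge and global sequence properties
#'
#' The seven charge/global features: FCR (fraction of charged residues,
#' K+R+D+E), NCPR (net charge per residue, (K+R) - (D+E) over length),
#' mean Kyte-Doolittle hydrophobicity rescaled to \[0,1\],
#' disorder-promoting fraction, isoelectric point, chain-expanding
#' fraction, and mean polyproline-II propensity. The pI is solved by
#' bisection of the Henderson-Hasselbalch net charge (EMBOSS pKa table,
#' free termini included) to |net charge| < 1e-4.
#'
#' @param seq protein sequence.
#' @return named numeric vector of length 7:
#'   `FCR`, `NCPR`, `hydrophobicity`, `disorder_promoting`, `pI`,
#'   `chain_expanding`, `PPII`.
#' @examples
#' chargeGlobalFeatures("KKDD")[c("FCR", "NCPR")]  # 1, 0
#' @export
chargeGlobalFeatures <- function(seq) {
  chars <- .residues(seq)
  L <- length(chars)
  counts <- table(factor(chars, levels = AA20))
  fPos <- (counts[["K"]] + counts[["R"]]) / L
  fNeg <- (counts[["D"]] + counts[["E"]]) / L
  c(
    FCR = fPos + fNeg,
    NCPR = fPos - fNeg,
    hydrophobicity = mean((KYTE_DOOLITTLE[chars] + 4.5) / 9),
    disorder_promoting = mean(chars %in% DISORDER_PROMOTING),
    pI = isoelectricPoint(seq),
    chain_expanding = mean(chars %in% CHAIN_EXPANDING),
    PPII = mean(PPII_SCALE[chars])
  )
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable side chains (C, D, E, H, K,
#' R, Y) plus free amino and carboxyl termini, with the EMBOSS pKa table.
#'
#' @param seq protein sequence.
#' @param pH pH value(s).
#' @param pKa pKa table (named list); defaults to the EMBOSS values.
#' @return net charge at each pH.
#' @export
netCharge <- function(seq, pH, pKa = PKA_EMBOSS) {
  .chargeFun(seq, pKa)(pH)
}

## closure over the ionizable-group counts, so bisection does not
## recount residues at every pH evaluation
.chargeFun <- function(seq, pKa = PKA_EMBOSS) {
  chars <- .residues(seq)
  n <- tabulate(match(chars, AA20), nbins = 20L)
  names(n) <- AA20
  posN <- c(Nterm = 1, K = n[["K"]], R = n[["R"]], H = n[["H"]])
  posK <- c(pKa$Nterm, pKa$K, pKa$R, pKa$H)
  negN <- c(Cterm = 1, D = n[["D"]], E = n[["E"]], C = n[["C"]], Y = n[["Y"]])
  negK <- c(pKa$Cterm, pKa$D, pKa$E, pKa$C, pKa$Y)
  function(pH) vapply(pH, function(p) {
    sum(posN / (1 + 10^(p - posK))) - sum(negN / (1 + 10^(negK - p)))
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Solves `netCharge(seq, pH) == 0` over pH in \[0, 14\] by bisection,
#' stopping when |net charge| < `tol`. The net charge is strictly
#' decreasing in pH and the termini guarantee a sign change, so the root
#' is unique.
#'
#' @param seq protein sequence.
#' @param tol convergence tolerance on |net charge|. Default 1e-4.
#' @param pKa pKa table; defaults to the EMBOSS values.
#' @return the isoelectric point (pH units).
#' @export
isoelectricPoint <- function(seq, tol = 1e-4, pKa = PKA_EMBOSS) {
  charge <- .chargeFun(seq, pKa)
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- charge(mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}
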