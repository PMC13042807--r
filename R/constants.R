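#' @import methods
NULL

## Twenty-letter amino-acid alphabet, alphabetical. All composition features
## are reported in this order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Residue classes used by the binary-patterning z-scores. `ala` overlaps
## `hyd` deliberately: pairs are evaluated independently.
PATTERN_CLASSES <- list(
  pol = c("S", "T", "N", "Q", "C", "H"),
  hyd = c("A", "I", "L", "M", "V"),
  pos = c("R", "K"),
  neg = c("D", "E"),
  aro = c("F", "W", "Y"),
  ala = "A",
  pro = "P",
  gly = "G"
)

## Grouped-composition sets (config-exposed; Y counts as polar and aromatic).
GROUP_SETS <- list(
  KR        = c("K", "R"),
  DE        = c("D", "E"),
  polar     = c("S", "T", "N", "Q", "C", "H", "Y"),
  aliphatic = c("A", "I", "L", "M", "V"),
  aromatic  = c("F", "W", "Y")
)

## Kyte-Doolittle hydropathy; rescaled to [0,1] as (x + 4.5)/9 when averaged.
KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

## Residues counted as disorder-promoting and as chain-expanding.
DISORDER_PROMOTING <- c("A", "R", "G", "Q", "S", "P", "E", "K")
CHAIN_EXPANDING    <- c("E", "D", "R", "K", "P")

## Per-residue polyproline-II propensity (experimental host-peptide scale).
PPII_SCALE <- c(
  A = 0.37, C = 0.25, D = 0.30, E = 0.42, F = 0.17,
  G = 0.13, H = 0.20, I = 0.39, K = 0.56, L = 0.24,
  M = 0.36, N = 0.27, P = 1.00, Q = 0.53, R = 0.38,
  S = 0.24, T = 0.32, V = 0.39, W = 0.25, Y = 0.25
)

## EMBOSS pKa table for isoelectric-point bisection.
PKA_EMBOSS <- list(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

## Fixed order of the 90 grammar features.
featureNames90 <- function() {
  cls <- names(PATTERN_CLASSES)
  pairs <- character(0)
  for (i in seq_along(cls))
    for (j in i:length(cls))
      pairs <- c(pairs, paste0("z_", cls[i], "_", cls[j]))
  blockAA <- setdiff(AA20, "W")
  c(pairs,
    paste0("frac_", AA20),
    "frac_KR", "frac_DE", "frac_polar", "frac_aliphatic", "frac_aromatic",
    "log10_KR", "log10_ED",
    "FCR", "NCPR", "hydrophobicity", "disorder_promoting", "pI",
    "chain_expanding", "PPII",
    paste0("block_", blockAA),
    "rg_stretch")
}

## Validate and explode a protein sequence into uppercase residues.
.residues <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("sequence must be a single nonempty string")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  chars
}
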