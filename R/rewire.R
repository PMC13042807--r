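#' Charge-rewired sequence variants
#'
#' Designs the charge-mutant constructs used to test electrostatic
#' autoregulation of condensation, by rewriting charged residues:
#'
#' * `AtoB` — acidic to basic: D -> R, E -> K.
#' * `AtoNon` — acidic to neutral: D, E -> S (serine: small, polar,
#'   disorder-compatible).
#' * `BtoA` — basic to acidic: K -> E, R -> D.
#' * `BtoNon` — basic to neutral: K, R -> S.
#' * `BS` — balanced substitution: the minimal number of acidic residues
#'   (taken left to right, D -> R / E -> K) is converted to basic so that
#'   the |NCPR| of the result is minimized.
#'
#' Length is always preserved. `AtoB` strictly increases NCPR whenever
#' the input contains an acidic residue; `BtoA` strictly decreases it
#' symmetrically.
#'
#' @param seq protein sequence.
#' @param mode one of `"AtoB"`, `"AtoNon"`, `"BtoA"`, `"BtoNon"`, `"BS"`.
#' @param neutral the neutral substitute residue. Default `"S"`.
#' @return the rewired sequence (string).
#' @examples
#' rewireCharges("DDEE", "AtoB")    # "RRKK"
#' rewireCharges("DDDDKK", "BS")    # one D -> R gives NCPR 0
#' @export
rewireCharges <- function(seq, mode = c("AtoB", "AtoNon", "BtoA",
                                        "BtoNon", "BS"),
                          neutral = "S") {
  mode <- match.arg(mode)
  chars <- .residues(seq)
  acidToBase <- c(D = "R", E = "K")
  baseToAcid <- c(K = "E", R = "D")
  out <- switch(mode,
    AtoB = {
      i <- chars %in% names(acidToBase)
      chars[i] <- acidToBase[chars[i]]
      chars
    },
    AtoNon = {
      chars[chars %in% c("D", "E")] <- neutral
      chars
    },
    BtoA = {
      i <- chars %in% names(baseToAcid)
      chars[i] <- baseToAcid[chars[i]]
      chars
    },
    BtoNon = {
      chars[chars %in% c("K", "R")] <- neutral
      chars
    },
    BS = {
      acidPos <- which(chars %in% c("D", "E"))
      nb <- sum(chars %in% c("K", "R"))
      net <- nb - length(acidPos)
      ## each acidic->basic substitution raises the net charge by 2
      ks <- 0:length(acidPos)
      k <- ks[which.min(abs(net + 2 * ks))]
      if (k > 0) {
        sub <- acidPos[seq_len(k)]
        chars[sub] <- acidToBase[chars[sub]]
      }
      chars
    })
  paste(out, collapse = "")
}
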