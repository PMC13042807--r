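#' Drift-corrected acceptor-photobleach FRET efficiency
#'
#' Computes FRET efficiency from donor dequenching after acceptor
#' photobleaching, correcting for donor drift or acquisition bleaching
#' with an unbleached control ROI:
#' `b = DN_post / DN_pre` (drift factor),
#' `Corr_D_post = D_post / b`,
#' `E = 1 - D_pre / Corr_D_post = 1 - D_pre * b / D_post`.
#' All intensities are background-subtracted per image first. E may be
#' legitimately negative (donor dimmer post-bleach than drift predicts).
#'
#' @param rois data.frame (one row per cell/ROI) with columns `D_pre`,
#'   `D_post` (bleached-ROI donor intensities), `DN_pre`, `DN_post`
#'   (unbleached negative-control ROI donor intensities), and optional
#'   `bg_pre`, `bg_post` (per-image backgrounds, default 0).
#' @return numeric vector of FRET efficiencies, one per row.
#' @examples
#' pbfretEfficiency(data.frame(D_pre = 90, D_post = 100,
#'                             DN_pre = 50, DN_post = 50))  # 0.1
#' @export
pbfretEfficiency <- function(rois) {
  need <- c("D_pre", "D_post", "DN_pre", "DN_post")
  if (!all(need %in% names(rois)))
    stop("rois needs columns: ", paste(need, collapse = ", "))
  bgPre <- if ("bg_pre" %in% names(rois)) rois$bg_pre else 0
  bgPost <- if ("bg_post" %in% names(rois)) rois$bg_post else 0
  dPre <- rois$D_pre - bgPre
  dPost <- rois$D_post - bgPost
  dnPre <- rois$DN_pre - bgPre
  dnPost <- rois$DN_post - bgPost
  if (any(dnPre <= 0) || any(dnPost <= 0) || any(dPost <= 0))
    stop("nonpositive intensity after background subtraction")
  b <- dnPost / dnPre
  1 - dPre * b / dPost
}
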