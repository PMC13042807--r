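#' Double normalization and exponential fitting of a FRAP trace
#'
#' Takes the three-ROI FRAP measurement (bleached region, cell-free
#' background, total fluorescence area) and the bleach frame index,
#' and produces the double-normalized recovery curve plus mobile
#' fraction and half-time.
#'
#' Processing: (1) background subtraction from the bleach and total
#' ROIs; (2) double normalization
#' `I_norm(t) = (T_pre / T(t)) * (I(t) / I_pre)`, with `I_pre`, `T_pre`
#' the pre-bleach means, which corrects acquisition photobleaching and
#' sets the pre-bleach mean to 1; (3) full-scale rescaling mapping the
#' first post-bleach point to 0; (4) a single-exponential fit
#' `I(t) = M * (1 - exp(-t / tau))` on the post-bleach samples (time
#' measured from the bleach), giving the mobile fraction `M` and
#' half-time `tau * log(2)`.
#'
#' @param traces data.frame with columns `time`, `bleach`, `background`,
#'   `total` (raw ROI mean intensities per frame).
#' @param bleachFrame index of the first post-bleach frame. Default 6
#'   (bleach applied after the fifth frame).
#' @return list with `curve` (data.frame: `time`, `normalized`,
#'   `full_scale`), `mobile_fraction`, `tau`, `half_time`.
#' @export
frapNormalize <- function(traces, bleachFrame = 6L) {
  need <- c("time", "bleach", "background", "total")
  if (!all(need %in% names(traces)))
    stop("traces needs columns: ", paste(need, collapse = ", "))
  n <- nrow(traces)
  if (bleachFrame < 6L || bleachFrame > n)
    stop("at least 5 pre-bleach frames are required")
  pre <- seq_len(bleachFrame - 1L)
  I <- traces$bleach - traces$background
  Tt <- traces$total - traces$background
  Ipre <- mean(I[pre])
  Tpre <- mean(Tt[pre])
  if (Tpre <= 0 || any(Tt <= 0)) stop("non-positive pre-bleach total")
  if (Ipre <= 0) stop("non-positive pre-bleach bleach-ROI intensity")
  norm <- (Tpre / Tt) * (I / Ipre)
  I0 <- norm[bleachFrame]
  if (I0 >= 1) stop("no bleach detected: first post-bleach point >= 1")
  fullScale <- (norm - I0) / (1 - I0)
  post <- bleachFrame:n
  t <- traces$time[post] - traces$time[bleachFrame]
  y <- fullScale[post]
  if (max(abs(y)) < 1e-10) {
    ## no recovery at all: immobile pool only
    return(list(curve = data.frame(time = traces$time, normalized = norm,
                                   full_scale = fullScale),
                mobile_fraction = 0, tau = NA_real_,
                half_time = NA_real_))
  }
  ## starting values: plateau from the tail, tau from half-recovery
  M0 <- max(mean(y[max(1, length(y) - 4):length(y)]), 0.05)
  i <- which(y >= M0 / 2)[1]
  tau0 <- if (!is.na(i) && t[i] > 0) t[i] / log(2) else
    max(t[length(t)] / 5, .Machine$double.eps)
  fit <- minpack.lm::nlsLM(
    y ~ M * (1 - exp(-t / tau)),
    start = list(M = min(M0, 1), tau = tau0),
    lower = c(0, 1e-9), upper = c(2, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  list(curve = data.frame(time = traces$time, normalized = norm,
                          full_scale = fullScale),
       mobile_fraction = unname(cf["M"]),
       tau = unname(cf["tau"]),
       half_time = unname(cf["tau"]) * log(2))
}
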