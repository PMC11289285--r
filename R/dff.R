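# dF/F computation from raw fluorescence.

#' Compute dF/F from raw fluorescence traces
#'
#' `dF/F = (F - r * F_neu - F0) / F0` where `F0` is a rolling lower-percentile
#' baseline (default: 10th percentile over a 60 s window) of the
#' neuropil-corrected trace, floored at a small positive constant. With no
#' neuropil trace the coefficient is 0.
#'
#' @param raw_f Raw fluorescence matrix (neurons x frames) or vector.
#' @param neuropil Optional neuropil trace(s), same shape.
#' @param frame_rate Frame rate (Hz), used to size the baseline window.
#' @param r Neuropil coefficient (default 0.7 when `neuropil` is given).
#' @param window Baseline window (s).
#' @param prob Baseline percentile in `(0, 1)`.
#' @param f0_floor Positive floor for the baseline.
#' @return dF/F matrix of the same shape, with attribute `degenerate`: a
#'   logical vector flagging all-zero input traces (returned as all-zero
#'   dF/F with a warning, not an error).
#' @export
compute_dff <- function(raw_f, neuropil = NULL, frame_rate,
                        r = if (is.null(neuropil)) 0 else 0.7,
                        window = 60, prob = 0.1, f0_floor = 1e-6) {
  x <- if (is.matrix(raw_f)) raw_f else matrix(raw_f, nrow = 1)
  if (any(!is.finite(x))) stop("invalid input: raw_f must be finite", call. = FALSE)
  w <- round(window * frame_rate)
  if (w >= ncol(x)) stop("invalid input: baseline window longer than session", call. = FALSE)
  if (!is.null(neuropil)) {
    np <- if (is.matrix(neuropil)) neuropil else matrix(neuropil, nrow = 1)
    stopifnot(all(dim(np) == dim(x)))
    x <- x - r * np
  }
  degenerate <- apply(x, 1, function(v) all(v == 0))
  out <- x
  for (i in seq_len(nrow(x))) {
    if (degenerate[i]) {
      out[i, ] <- 0
      next
    }
    f0 <- pmax(rolling_quantile(x[i, ], w, prob), f0_floor)
    out[i, ] <- (x[i, ] - f0) / f0
  }
  if (any(degenerate)) warning("all-zero trace(s): returning all-zero dF/F", call. = FALSE)
  if (!is.matrix(raw_f)) {
    res <- out[1, ]
    attr(res, "degenerate") <- degenerate
    return(res)
  }
  attr(out, "degenerate") <- degenerate
  out
}
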