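# Significant-transient detection and the distance-normalized activity
# measure.

#' Zero-phase Butterworth low-pass filter
#'
#' Third-order Butterworth applied forwards and backwards (zero phase), per
#' neuron.
#'
#' @param dff dF/F matrix (neurons x frames) or vector.
#' @param frame_rate Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz), must be below Nyquist.
#' @param order Filter order.
#' @return Filtered traces, same shape.
#' @export
lowpass_filter <- function(dff, frame_rate, cutoff = 2, order = 3) {
  if (cutoff >= frame_rate / 2)
    stop("invalid argument: cutoff must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(order, cutoff / (frame_rate / 2), type = "low")
  filt1 <- function(v) {
    # odd-reflection padding so the filter settles before the trace starts;
    # without it the edges are pulled toward zero
    n <- length(v)
    pad <- min(n - 1L, 3L * ceiling(frame_rate / cutoff) * order)
    ext <- c(2 * v[1] - v[(pad + 1L):2L], v, 2 * v[n] - v[(n - 1L):(n - pad)])
    out <- as.numeric(signal::filtfilt(bf, ext))
    out[(pad + 1L):(pad + n)]
  }
  if (is.matrix(dff)) t(apply(dff, 1, filt1)) else filt1(dff)
}

#' Detect significant calcium transients
#'
#' A transient is a run of consecutive frames that starts when the trace
#' rises `start_k` standard deviations (sigma) above the rolling-mean
#' baseline and ends when it drops back below `end_k` sigma. Baseline and
#' sigma are re-estimated iteratively: each iteration recomputes the rolling
#' mean and the residual sd from the transient-excluded trace of the previous
#' iteration (iteration 1 uses the full trace), `n_iter` times in total.
#' Runs shorter than `min_duration` frames are discarded as single-frame
#' noise crossings.
#'
#' @param dff Filtered dF/F matrix (neurons x frames) or vector; pass the
#'   output of [lowpass_filter()].
#' @param frame_rate Sampling rate (Hz).
#' @param start_k Onset threshold in sigma units.
#' @param end_k Offset threshold in sigma units.
#' @param n_iter Number of baseline re-estimation iterations.
#' @param baseline_window Rolling-mean window (s).
#' @param min_duration Minimum transient duration (frames).
#' @return A `dg_transients` object: `intervals` (data frame `neuron`,
#'   `start`, `end`, `peak`, `integral`), `masked` (dF/F inside transients, 0
#'   elsewhere), `baseline`, `sigma` (neurons x iterations matrix of residual
#'   sd estimates), `degenerate` (flags constant traces), `frame_rate`.
#' @export
detect_transients <- function(dff, frame_rate, start_k = 2, end_k = 0.5,
                              n_iter = 3, baseline_window = 30,
                              min_duration = 3) {
  x <- if (is.matrix(dff)) dff else matrix(dff, nrow = 1)
  w <- round(baseline_window * frame_rate)
  if (ncol(x) <= w)
    stop("invalid input: trace shorter than the baseline window", call. = FALSE)
  nn <- nrow(x)
  nf <- ncol(x)
  dt <- 1 / frame_rate

  sigma_mat <- matrix(NA_real_, nn, n_iter)
  masked <- matrix(0, nn, nf)
  baseline_mat <- matrix(0, nn, nf)
  degenerate <- logical(nn)
  rows <- vector("list", nn)

  for (i in seq_len(nn)) {
    v <- x[i, ]
    in_transient <- rep(FALSE, nf)
    base <- numeric(nf)
    sigma <- 0
    for (iter in seq_len(n_iter)) {
      keep <- !in_transient
      base <- masked_rolling_mean(v, keep, w)
      resid <- v - base
      sigma <- stats::sd(resid[keep])
      sigma_mat[i, iter] <- sigma
      if (!is.finite(sigma) || sigma == 0) {
        # residual exhausted: a globally constant trace is degenerate (no
        # transients); otherwise keep the previous iteration's transients
        if (iter == 1L || !any(in_transient)) {
          degenerate[i] <- TRUE
          in_transient <- rep(FALSE, nf)
        }
        break
      }
      in_transient <- mark_transients(v, base, sigma, start_k, end_k, min_duration)
    }
    baseline_mat[i, ] <- base
    iv <- interval_table(in_transient)
    if (nrow(iv) > 0) {
      iv$neuron <- i
      iv$peak <- vapply(seq_len(nrow(iv)), function(j) max(v[iv$start[j]:iv$end[j]]), numeric(1))
      iv$integral <- vapply(seq_len(nrow(iv)), function(j) sum(v[iv$start[j]:iv$end[j]]) * dt, numeric(1))
      masked[i, in_transient] <- v[in_transient]
      rows[[i]] <- iv[, c("neuron", "start", "end", "peak", "integral")]
    }
  }
  intervals <- if (any(!vapply(rows, is.null, logical(1)))) {
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  } else {
    data.frame(neuron = integer(0), start = integer(0), end = integer(0),
               peak = numeric(0), integral = numeric(0))
  }
  rownames(intervals) <- NULL
  structure(list(
    intervals = intervals, masked = masked, baseline = baseline_mat,
    sigma = sigma_mat, degenerate = degenerate, frame_rate = frame_rate
  ), class = "dg_transients")
}

# Mark frames belonging to transients: a run opens at a crossing of
# base + start_k * sigma and closes when the trace falls below
# base + end_k * sigma.
mark_transients <- function(v, base, sigma, start_k, end_k, min_duration) {
  hi <- base + start_k * sigma
  lo <- base + end_k * sigma
  above_lo <- v > lo
  out <- rep(FALSE, length(v))
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    s <- starts[j]; e <- ends[j]
    seg <- s:e
    first_hi <- seg[v[seg] > hi[seg]][1]
    if (is.na(first_hi)) next
    if (e - first_hi + 1L >= min_duration) out[first_hi:e] <- TRUE
  }
  out
}

interval_table <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.dg_transients <- function(x, ...) {
  cat(sprintf("<dg_transients> %d transients across %d neurons (%d degenerate)\n",
              nrow(x$intervals), nrow(x$masked), sum(x$degenerate)))
  invisible(x)
}

#' Distance-normalized calcium activity
#'
#' Activity per neuron is the cumulative sum (time integral) of the
#' significant-transient trace, normalized to the total distance traveled:
#' dF/F.s per cm.
#'
#' @param tset A `dg_transients` from [detect_transients()].
#' @param session The matching `dg_session`.
#' @return Numeric vector, one nonnegative activity value per neuron.
#' @export
compute_activity <- function(tset, session) {
  dist <- session_distance(session)
  if (dist <= 0) stop("undefined activity: zero distance traveled", call. = FALSE)
  rowSums(tset$masked) / tset$frame_rate / dist
}

#' Export detected transients as CSV
#' @param tset A `dg_transients`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transients_csv <- function(tset, path) {
  iv <- tset$intervals
  iv$start_s <- (iv$start - 1) / tset$frame_rate
  iv$end_s <- (iv$end - 1) / tset$frame_rate
  utils::write.csv(iv[, c("neuron", "start_s", "end_s", "peak", "integral")],
                   path, row.names = FALSE)
  invisible(path)
}
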