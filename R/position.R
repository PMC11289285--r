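# Position reconstruction from telemetry, and spatial binning.

#' Reconstruct belt position from encoder and RFID telemetry
#'
#' Position is the cumulative sum of the encoder tick stream. Because any
#' real encoder drifts, the running estimate is re-anchored at every RFID
#' event to the tag's known belt position (choosing the unwrapped
#' representative nearest the current estimate, so laps are never lost).
#' The accumulated residual can either be applied as a hard reset at the tag
#' (`drift = "reset"`, default) or back-distributed linearly over the samples
#' since the previous event (`drift = "distribute"`). The telemetry is then
#' resampled to frame times by last observation carried forward — the encoder
#' is a counter, so interpolation would invent motion.
#'
#' @param trace A `dg_position_trace` (see [simulate_trajectory()]), or any
#'   list with `ticks`, `sample_times`, `frame_times`, `rfid_events`
#'   (`sample`, `tag`, `position`), `tag_positions`.
#' @param belt_length Belt length (cm).
#' @param drift How to apportion encoder drift at RFID events.
#' @return A list with `position` (cm, wrapped to `[0, belt_length)` per
#'   frame), `lap_index` (0-based, non-decreasing), and `drift` (the residual
#'   absorbed at each RFID event, cm).
#' @export
reconstruct_position <- function(trace, belt_length,
                                 drift = c("reset", "distribute")) {
  drift <- match.arg(drift)
  ticks <- trace$ticks
  st <- trace$sample_times
  ft <- trace$frame_times
  if (length(ticks) < 1L || length(ft) < 1L)
    stop("invalid input: need at least one sample and one frame", call. = FALSE)
  if (any(!is.finite(ticks)))
    stop("invalid input: encoder increments must be finite", call. = FALSE)
  if (any(diff(st) <= 0) || any(diff(ft) <= 0))
    stop("invalid input: times must be strictly increasing", call. = FALSE)

  u <- cumsum(ticks)
  ev <- trace$rfid_events
  residuals <- numeric(0)
  if (!is.null(ev) && nrow(ev) > 0) {
    ev <- ev[order(ev$sample), , drop = FALSE]
    registered <- trace$tag_positions %||% sort(unique(ev$position))
    if (any(ev$tag < 1L | ev$tag > length(registered)))
      stop("unknown tag: RFID tag id without a registered position", call. = FALSE)
    prev <- 0L
    residuals <- numeric(nrow(ev))
    for (j in seq_len(nrow(ev))) {
      i <- ev$sample[j]
      p <- registered[ev$tag[j]]
      target <- p + belt_length * round((u[i] - p) / belt_length)
      # the tag is crossed somewhere inside the last sampling interval, so a
      # discrepancy smaller than one increment is within the encoder's
      # sampling resolution: leave it alone (a drift-free encoder is then
      # reproduced exactly); anything larger is real drift and is corrected
      inc <- if (i > 1L) u[i] - u[i - 1L] else u[i]
      disc <- u[i] - target
      off <- if (disc >= 0 && disc <= max(inc, 0)) 0 else target - u[i]
      residuals[j] <- -off
      n <- length(u)
      if (drift == "reset") {
        u[i:n] <- u[i:n] + off
      } else {
        ramp_idx <- (prev + 1L):i
        ramp <- off * seq_along(ramp_idx) / length(ramp_idx)
        u[ramp_idx] <- u[ramp_idx] + ramp
        if (i < n) u[(i + 1L):n] <- u[(i + 1L):n] + off
      }
      prev <- i
    }
  }

  # LOCF resample of the counter to frame times
  idx <- findInterval(ft, st)
  uf <- ifelse(idx == 0, 0, u[pmax(idx, 1L)])
  uf <- pmax(uf, 0)
  lap <- cummax(pmax(floor(uf / belt_length), 0))
  list(
    position = wrap_position(uf, belt_length),
    lap_index = as.integer(lap),
    drift = residuals
  )
}

#' Assign positions to equal-width circular bins
#'
#' Half-open bins `[i L/n, (i+1) L/n)` labelled `0 .. n_bins - 1`; a position
#' exactly at `belt_length` wraps to bin 0.
#'
#' @param position Positions in cm.
#' @param n_bins Number of bins (>= 2).
#' @param belt_length Belt length (cm).
#' @return Integer bin label per position.
#' @export
bin_position <- function(position, n_bins, belt_length) {
  if (n_bins < 2) stop("invalid input: n_bins must be >= 2", call. = FALSE)
  if (any(position < 0 | position > belt_length))
    stop("invalid input: position outside [0, belt_length)", call. = FALSE)
  b <- floor(position / belt_length * n_bins)
  b[b >= n_bins] <- 0L # position exactly at belt_length wraps
  as.integer(b)
}

# Bin-center angles (radians) for n equal circular bins.
bin_centers <- function(n_bins) (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
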