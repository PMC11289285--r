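# The Session data model: aligned per-frame traces plus position/lap
# annotation. Every downstream stage consumes this object.

#' Construct a Session
#'
#' A Session holds frame-aligned data for one imaging run: dF/F traces
#' (neurons x frames), optional raw fluorescence and deconvolved rates,
#' per-frame position on the circular belt, lap index, and timing.
#'
#' @param dff Numeric matrix, neurons x frames (dF/F).
#' @param frame_times Strictly increasing frame times (s).
#' @param position Per-frame position in `[0, belt_length)` cm.
#' @param lap_index Non-decreasing integer lap label per frame, 0-based.
#' @param belt_length Belt length (cm).
#' @param frame_rate Frame rate (Hz); checked against `frame_times`.
#' @param raw_f Optional raw fluorescence matrix, same shape as `dff`.
#' @param rates Optional nonnegative deconvolved-rate matrix.
#' @param metadata List of free-form metadata (subject id, condition, seed,
#'   generating config for synthetic sessions).
#' @return An object of class `dg_session`.
#' @export
new_session <- function(dff, frame_times, position, lap_index, belt_length,
                        frame_rate, raw_f = NULL, rates = NULL,
                        metadata = list()) {
  dff <- as.matrix(dff)
  n_frames <- ncol(dff)
  s <- structure(list(
    dff = dff, raw_f = raw_f, rates = rates,
    frame_times = as.numeric(frame_times),
    position = as.numeric(position),
    lap_index = as.integer(lap_index),
    belt_length = belt_length, frame_rate = frame_rate,
    metadata = metadata
  ), class = "dg_session")
  validate_session(s)
  s
}

validate_session <- function(s) {
  stopifnot(inherits(s, "dg_session"))
  n <- ncol(s$dff)
  if (length(s$frame_times) != n || length(s$position) != n || length(s$lap_index) != n)
    stop("invalid session: per-frame arrays must share one length", call. = FALSE)
  if (any(diff(s$frame_times) <= 0))
    stop("invalid session: frame_times must be strictly increasing", call. = FALSE)
  if (any(s$position < 0 | s$position >= s$belt_length))
    stop("invalid session: position must lie in [0, belt_length)", call. = FALSE)
  if (any(diff(s$lap_index) < 0))
    stop("invalid session: lap_index must be non-decreasing", call. = FALSE)
  if (!is.null(s$raw_f) && !all(dim(s$raw_f) == dim(s$dff)))
    stop("invalid session: raw_f shape mismatch", call. = FALSE)
  if (!is.null(s$rates) && !all(dim(s$rates) == dim(s$dff)))
    stop("invalid session: rates shape mismatch", call. = FALSE)
  med_dt <- stats::median(diff(s$frame_times))
  if (abs(1 / med_dt - s$frame_rate) > 0.05 * s$frame_rate)
    stop("invalid session: frame_rate inconsistent with frame_times", call. = FALSE)
  invisible(s)
}

#' Number of neurons / frames in a session
#' @param session A `dg_session`.
#' @return Integer count.
#' @export
n_neurons <- function(session) nrow(session$dff)

#' @rdname n_neurons
#' @export
n_frames <- function(session) ncol(session$dff)

#' Total distance traveled in a session (cm)
#' @param session A `dg_session`.
#' @return Distance in cm.
#' @export
session_distance <- function(session) {
  d <- diff(session$position) %% session$belt_length
  d[d > session$belt_length / 2] <- 0 # guard against backwards jitter wraps
  sum(d)
}

#' @export
print.dg_session <- function(x, ...) {
  cat(sprintf(
    "<dg_session> %d neurons x %d frames (%.1f s at %g Hz), %d laps, belt %g cm\n",
    n_neurons(x), n_frames(x), max(x$frame_times), x$frame_rate,
    max(x$lap_index) + 1L, x$belt_length
  ))
  if (!is.null(x$metadata$condition))
    cat("  condition:", x$metadata$condition, "\n")
  invisible(x)
}
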