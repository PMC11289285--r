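# Session container I/O. The container is a versioned single-file RDS
# serialization of the Session fields (lossless, bit-exact floating point),
# with plain-text CSV export helpers for interoperability.

DG_SESSION_SCHEMA <- "dg-session-v1"

#' Write / read a Session container
#'
#' `write_session()` serializes all Session fields losslessly to a single
#' versioned container file; `read_session()` restores them. A file that is
#' not a session container, or carries a different schema version, raises an
#' explicit error rather than returning partially filled data.
#'
#' @param session A `dg_session`.
#' @param path File path (conventionally `.dgs`).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the `dg_session`.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  payload <- list(schema = DG_SESSION_SCHEMA, fields = unclass(session))
  saveRDS(payload, path, version = 3)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("format error: not a readable session container: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(payload) || is.null(payload$schema))
    stop("format error: file is not a session container", call. = FALSE)
  if (!identical(payload$schema, DG_SESSION_SCHEMA))
    stop(sprintf("schema-version mismatch: file has '%s', reader supports '%s'",
                 payload$schema, DG_SESSION_SCHEMA), call. = FALSE)
  s <- payload$fields
  class(s) <- "dg_session"
  validate_session(s)
  s
}

#' Export session tables as plain text
#'
#' Writes the per-frame annotation (time, position, lap) and each trace
#' matrix as CSV files under `dir`.
#'
#' @param session A `dg_session`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
export_session_csv <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(
    frame_time = session$frame_times,
    position = session$position,
    lap_index = session$lap_index
  ), file.path(dir, "frames.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(t(session$dff)), file.path(dir, "dff.csv"),
                   row.names = FALSE)
  if (!is.null(session$raw_f))
    utils::write.csv(as.data.frame(t(session$raw_f)), file.path(dir, "raw_f.csv"),
                     row.names = FALSE)
  if (!is.null(session$rates))
    utils::write.csv(as.data.frame(t(session$rates)), file.path(dir, "rates.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Build a Session from extraction-tool style trace matrices
#'
#' Accepts plain matrices as produced by a cell-extraction tool (raw
#' fluorescence and optional neuropil / deconvolved traces) together with
#' reconstructed position, computes dF/F, and assembles a `dg_session`.
#'
#' @param raw_f Raw fluorescence matrix (neurons x frames).
#' @param frame_times Frame times (s).
#' @param position Per-frame position (cm).
#' @param lap_index Per-frame lap index.
#' @param belt_length Belt length (cm).
#' @param frame_rate Frame rate (Hz).
#' @param neuropil Optional neuropil matrix.
#' @param rates Optional deconvolved-rate matrix.
#' @param metadata Metadata list.
#' @param ... Passed to [compute_dff()].
#' @return A `dg_session`.
#' @export
session_from_traces <- function(raw_f, frame_times, position, lap_index,
                                belt_length, frame_rate, neuropil = NULL,
                                rates = NULL, metadata = list(), ...) {
  dff <- compute_dff(raw_f, neuropil = neuropil, frame_rate = frame_rate, ...)
  attr(dff, "degenerate") <- NULL
  new_session(dff, frame_times, position, lap_index, belt_length, frame_rate,
              raw_f = raw_f, rates = rates, metadata = metadata)
}
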