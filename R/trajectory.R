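# Simulated treadmill telemetry: true belt position, a rotary-encoder tick
# stream with configurable noise/drift, and RFID events at texture
# boundaries.

#' Simulate a treadmill trajectory
#'
#' Generates per-frame true position on the circular belt together with the
#' telemetry a real rig produces: encoder increments (cm-equivalent per
#' sample, optionally corrupted by per-tick noise and a multiplicative gain
#' error) and RFID events fired whenever the true position crosses a texture
#' boundary. Speed follows a slow AR(1) around `mean_speed` with stationary
#' sd `speed_sd`, truncated at a small positive floor (the belt only moves
#' forward). The trace is cut at the frame where the `n_laps`-th lap
#' completes.
#'
#' @param config A [synthetic_config()].
#' @param encoder_noise_sd Sd of additive white noise per encoder sample (cm).
#' @param encoder_gain Multiplicative calibration error of the encoder
#'   (1 = perfect).
#' @param rfid If `FALSE`, no RFID events are emitted.
#' @return An object of class `dg_position_trace` with elements `ticks`
#'   (encoder increments per sample), `rfid_events` (data frame: `sample`,
#'   `tag`, `position`), `sample_times`, `frame_times`, `tag_positions`,
#'   `true_position` (wrapped), `true_unwrapped`, `belt_length`.
#' @export
simulate_trajectory <- function(config, encoder_noise_sd = 0,
                                encoder_gain = 1, rfid = TRUE) {
  validate_config(config)
  if (encoder_noise_sd < 0) stop("invalid config: encoder_noise_sd must be >= 0", call. = FALSE)
  L <- config$belt_length
  fr <- config$frame_rate
  dt <- 1 / fr
  total <- config$n_laps * L

  with_stream(config$seed, "trajectory", {
    # generous frame budget, then cut at lap completion
    n_guess <- ceiling(total / (config$mean_speed / 60 * dt) * 1.5) + 10L
    rho <- 0.98 # slow drift in manual belt rotation
    eps <- stats::rnorm(n_guess, 0, config$speed_sd * sqrt(1 - rho^2))
    sp <- numeric(n_guess)
    sp[1] <- config$mean_speed + stats::rnorm(1, 0, config$speed_sd)
    for (t in 2:n_guess) sp[t] <- config$mean_speed + rho * (sp[t - 1] - config$mean_speed) + eps[t]
    sp <- pmax(sp, 1) # cm/min floor
    step <- sp / 60 * dt
    u <- cumsum(step)
    n_frames <- which(u >= total)[1]
    if (is.na(n_frames)) n_frames <- n_guess # pathological config; keep what we have
    keep <- seq_len(n_frames)
    u <- u[keep]
    u[n_frames] <- min(u[n_frames], total - 1e-9)
    step <- c(u[1], diff(u))

    ticks <- step * encoder_gain
    if (encoder_noise_sd > 0) ticks <- ticks + stats::rnorm(n_frames, 0, encoder_noise_sd)

    tag_pos <- (seq_len(config$n_textures) - 1L) * (L / config$n_textures)
    rfid_events <- data.frame(sample = integer(0), tag = integer(0), position = numeric(0))
    if (rfid) {
      u0 <- c(0, u[-n_frames])
      ev <- lapply(seq_along(tag_pos), function(k) {
        # crossings of tag k (at tag_pos[k] + j*L for every lap j)
        cross <- which(floor((u - tag_pos[k]) / L) > floor((u0 - tag_pos[k]) / L))
        if (length(cross) == 0) return(NULL)
        data.frame(sample = cross, tag = k, position = tag_pos[k])
      })
      ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
      if (!is.null(ev)) rfid_events <- ev[order(ev$sample), , drop = FALSE]
      rownames(rfid_events) <- NULL
    }

    times <- (seq_len(n_frames) - 1L) * dt
    structure(list(
      ticks = ticks,
      rfid_events = rfid_events,
      sample_times = times,
      frame_times = times,
      tag_positions = tag_pos,
      true_position = wrap_position(u, L),
      true_unwrapped = u,
      belt_length = L
    ), class = "dg_position_trace")
  })
}

#' @export
print.dg_position_trace <- function(x, ...) {
  cat(sprintf(
    "<dg_position_trace> %d samples, %.1f s, %d RFID events, belt %g cm\n",
    length(x$ticks), max(x$sample_times), nrow(x$rfid_events), x$belt_length
  ))
  invisible(x)
}
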