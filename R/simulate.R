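# Synthetic session generator: von Mises place tuning, Poisson events,
# exponential calcium kernel, shared-gain noise correlations, additive noise.

#' Von Mises rate profile
#'
#' `B + A * exp(k * (cos(theta - phi) - 1))`: baseline `B`, peak amplitude
#' `A` above baseline at `theta = phi`, concentration `k`.
#'
#' @param theta Angle(s), radians.
#' @param B Offset.
#' @param A Amplitude.
#' @param k Concentration (>= 0).
#' @param phi Peak location (radians).
#' @return Profile values.
#' @export
von_mises <- function(theta, B, A, k, phi) {
  B + A * exp(k * (cos(theta - phi) - 1))
}

#' Simulate a full synthetic session with ground truth
#'
#' Draws per-neuron tuning parameters, simulates a treadmill trajectory,
#' generates Poisson events from the gain-modulated von Mises rates,
#' convolves them with a single-exponential calcium kernel, and adds Gaussian
#' noise. Raw fluorescence is emitted as `F = F0_raw * (1 + dF/F)` so the
#' dF/F recipe can be exercised on synthetic data.
#'
#' @param config A [synthetic_config()].
#' @param trajectory Optional precomputed `dg_position_trace`; defaults to
#'   [simulate_trajectory()] under the config's seed.
#' @return A list with `session` (`dg_session`) and `truth`
#'   (`dg_ground_truth`: data frame `params` with per-neuron B, A, k, phi and
#'   tuned flag; `spikes` count matrix; `shared_gain` per-frame multiplier;
#'   `config`).
#' @export
simulate_session <- function(config, trajectory = NULL) {
  validate_config(config)
  traj <- trajectory %||% simulate_trajectory(config)
  nf <- length(traj$frame_times)
  nn <- config$n_neurons
  dt <- 1 / config$frame_rate
  theta <- 2 * pi * traj$true_position / config$belt_length

  params <- with_stream(config$seed, "params", {
    n_tuned <- round(config$fraction_tuned * nn)
    tuned <- rep(FALSE, nn)
    if (n_tuned > 0) tuned[sample.int(nn, n_tuned)] <- TRUE
    data.frame(
      neuron = seq_len(nn),
      tuned = tuned,
      B = stats::runif(nn, config$baseline_range[1], config$baseline_range[2]),
      A = ifelse(tuned,
                 stats::runif(nn, config$amplitude_range[1], config$amplitude_range[2]),
                 0),
      k = ifelse(tuned,
                 stats::runif(nn, config$concentration_range[1], config$concentration_range[2]),
                 0),
      phi = stats::runif(nn, 0, 2 * pi)
    )
  })

  shared_gain <- with_stream(config$seed, "shared_gain", {
    sg <- config$shared_gain_sd
    if (sg > 0) {
      # one global latent AR(1) source, exponentiated to a mean-1 log-normal
      rho <- exp(-dt / config$shared_gain_tau)
      a <- numeric(nf)
      a[1] <- stats::rnorm(1, 0, sg)
      innov <- stats::rnorm(nf, 0, sg * sqrt(1 - rho^2))
      for (t in 2:nf) a[t] <- rho * a[t - 1] + innov[t]
      exp(a - sg^2 / 2)
    } else {
      rep(1, nf)
    }
  })

  # rate (events/s): neurons x frames
  lambda <- matrix(0, nn, nf)
  for (i in seq_len(nn)) {
    lambda[i, ] <- config$gain * shared_gain *
      von_mises(theta, params$B[i], params$A[i], params$k[i], params$phi[i])
  }

  spikes <- with_stream(config$seed, "spikes", {
    matrix(stats::rpois(nn * nf, as.vector(lambda) * dt), nn, nf)
  })

  decay <- exp(-dt / config$decay_tau)
  calcium <- t(apply(spikes * config$spike_amplitude, 1, function(s) {
    as.numeric(stats::filter(s, decay, method = "recursive"))
  }))

  noise <- with_stream(config$seed, "noise", {
    if (config$noise_sd > 0) matrix(stats::rnorm(nn * nf, 0, config$noise_sd), nn, nf)
    else matrix(0, nn, nf)
  })
  dff <- calcium + noise
  f0_raw <- 100
  raw_f <- f0_raw * (1 + dff)

  session <- new_session(
    dff = dff, frame_times = traj$frame_times,
    position = traj$true_position,
    lap_index = as.integer(floor(traj$true_unwrapped / config$belt_length)),
    belt_length = config$belt_length, frame_rate = config$frame_rate,
    raw_f = raw_f,
    metadata = list(config = config, seed = config$seed, synthetic = TRUE,
                    f0_raw = f0_raw)
  )
  truth <- structure(list(
    params = params, spikes = spikes, shared_gain = shared_gain,
    config = config, dff_clean = calcium
  ), class = "dg_ground_truth")
  list(session = session, truth = truth)
}

#' Re-simulate a synthetic session at a different global gain
#'
#' Rates are scaled by `g` before the Poisson/noise stages, holding the
#' trajectory, tuning parameters, and all random sub-streams fixed (same
#' root seed), so `g = 1` reproduces the session exactly and `g = 2` doubles
#' every neuron's expected rate without moving or widening its place field.
#'
#' @param session A synthetic `dg_session` (must carry its generating config).
#' @param g Gain multiplier (>= 0).
#' @return A new `dg_session`.
#' @export
apply_gain <- function(session, g) {
  if (g < 0) stop("invalid argument: g must be >= 0", call. = FALSE)
  cfg <- session$metadata$config
  if (is.null(cfg))
    stop("apply_gain needs a synthetic session carrying its generating config",
         call. = FALSE)
  cfg$gain <- cfg$gain * g
  simulate_session(cfg)$session
}

#' Write ground-truth parameters as CSV
#' @param truth A `dg_ground_truth`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(truth, path) {
  utils::write.csv(truth$params, path, row.names = FALSE)
  invisible(path)
}
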