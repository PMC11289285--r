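# Configuration for the synthetic-session generator.

#' Configuration for synthetic treadmill sessions
#'
#' Describes a simulated head-fixed treadmill experiment: a circular belt of
#' `belt_length` cm split into `n_textures` equal texture zones, locomotion at
#' `mean_speed` cm/min (with slow AR(1) jitter of sd `speed_sd`), and a
#' population of `n_neurons` sparsely active granule cells of which a fraction
#' `fraction_tuned` carries unimodal circular (von Mises) place tuning.
#'
#' Each neuron's instantaneous event rate is
#' \deqn{\lambda(x) = g \, G_t \,\left(B + A e^{k(\cos(\theta(x)-\varphi)-1)}\right)}
#' with \eqn{\theta(x) = 2\pi x / L}; `gain` is the global multiplier \eqn{g}
#' and \eqn{G_t} a shared log-normal per-frame gain fluctuation (mean 1):
#' one global latent Gaussian AR(1) source of stationary sd `shared_gain_sd`
#' and correlation time `shared_gain_tau` s (default 0.4, 3 s: yields mean pairwise noise correlations of a few hundredths, as typically reported for hippocampal populations), exponentiated. It multiplies
#' every neuron's rate and so induces positive noise correlations. Events
#' are Poisson per frame, convolved with a single-exponential calcium kernel
#' (`decay_tau` s, instantaneous rise, `spike_amplitude` dF/F per event), plus
#' additive Gaussian noise of sd `noise_sd`.
#'
#' @param n_neurons Number of simulated neurons.
#' @param n_laps Number of complete belt laps.
#' @param belt_length Belt length in cm.
#' @param n_textures Number of equal-length texture zones (RFID tags sit at
#'   their boundaries).
#' @param frame_rate Imaging frame rate (Hz).
#' @param mean_speed Mean treadmill speed (cm/min).
#' @param speed_sd Sd of the slow speed jitter (cm/min).
#' @param fraction_tuned Proportion of neurons with place tuning, in `[0, 1]`.
#' @param baseline_range Range of the untuned baseline rate B (events/s).
#' @param amplitude_range Range of the tuned peak amplitude A (events/s).
#' @param concentration_range Range of the von Mises concentration k.
#' @param gain Global gain multiplier g (>= 0).
#' @param decay_tau Calcium decay time constant (s).
#' @param noise_sd Additive dF/F noise sd.
#' @param shared_gain_sd Log-sd of the shared multiplicative gain fluctuation;
#'   0 gives uncorrelated trial-to-trial variability.
#' @param shared_gain_tau Correlation time of the shared gain (s).
#' @param spike_amplitude dF/F increment per event.
#' @param seed Integer root seed; identical config + seed reproduces the
#'   session bit for bit.
#' @return An object of class `dg_config`.
#' @seealso [simulate_session()], [simulate_trajectory()]
#' @export
synthetic_config <- function(n_neurons = 100L,
                             n_laps = 30L,
                             belt_length = 180,
                             n_textures = 4L,
                             frame_rate = 15,
                             mean_speed = 421,
                             speed_sd = 23,
                             fraction_tuned = 0.3,
                             baseline_range = c(0.02, 0.08),
                             amplitude_range = c(0.5, 2),
                             concentration_range = c(2, 8),
                             gain = 1,
                             decay_tau = 1,
                             noise_sd = 0.05,
                             shared_gain_sd = 0.4,
                             shared_gain_tau = 3,
                             spike_amplitude = 1,
                             seed = 1L) {
  cfg <- list(
    n_neurons = as.integer(n_neurons), n_laps = as.integer(n_laps),
    belt_length = belt_length, n_textures = as.integer(n_textures),
    frame_rate = frame_rate, mean_speed = mean_speed, speed_sd = speed_sd,
    fraction_tuned = fraction_tuned, baseline_range = baseline_range,
    amplitude_range = amplitude_range,
    concentration_range = concentration_range, gain = gain,
    decay_tau = decay_tau, noise_sd = noise_sd,
    shared_gain_sd = shared_gain_sd, shared_gain_tau = shared_gain_tau,
    spike_amplitude = spike_amplitude,
    seed = as.integer(seed)
  )
  class(cfg) <- "dg_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "dg_config"))
  if (cfg$n_neurons < 1L) stop("invalid config: n_neurons must be >= 1", call. = FALSE)
  if (cfg$n_laps < 1L) stop("invalid config: n_laps must be >= 1", call. = FALSE)
  if (cfg$frame_rate <= 0) stop("invalid config: frame_rate must be positive", call. = FALSE)
  if (cfg$mean_speed <= 0) stop("invalid config: mean_speed must be positive", call. = FALSE)
  if (cfg$belt_length <= 0) stop("invalid config: belt_length must be positive", call. = FALSE)
  if (cfg$fraction_tuned < 0 || cfg$fraction_tuned > 1)
    stop("invalid config: fraction_tuned must lie in [0, 1]", call. = FALSE)
  if (cfg$gain < 0) stop("invalid config: gain must be >= 0", call. = FALSE)
  if (cfg$noise_sd < 0) stop("invalid config: noise_sd must be >= 0", call. = FALSE)
  if (cfg$decay_tau <= 0) stop("invalid config: decay_tau must be positive", call. = FALSE)
  if (cfg$shared_gain_sd < 0) stop("invalid config: shared_gain_sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Read or write a synthetic-session configuration as YAML
#'
#' @param path File path.
#' @return `read_synthetic_config()` returns a `dg_config`;
#'   `write_synthetic_config()` returns `path` invisibly.
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(synthetic_config, vals)
}

#' @rdname read_synthetic_config
#' @param config A `dg_config`.
#' @export
write_synthetic_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.dg_config <- function(x, ...) {
  cat(sprintf(
    "<dg_config> %d neurons (%.0f%% tuned), %d laps on %g cm belt, gain %g, seed %d\n",
    x$n_neurons, 100 * x$fraction_tuned, x$n_laps, x$belt_length, x$gain, x$seed
  ))
  invisible(x)
}
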