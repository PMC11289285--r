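# Deconvolved rate estimates and occupancy-normalized circular tuning.

#' Sparse nonnegative deconvolution of calcium traces
#'
#' Inverts the first-order autoregressive calcium model
#' `c_t = gamma * c_{t-1} + a * s_t` with `gamma = exp(-dt / decay_tau)`:
#' the rate estimate is `max(0, c_t - gamma * c_{t-1}) / dt`. For a clean
#' exponential kernel this recovers a unit impulse exactly; the operator is
#' linear on the positive part, so rates scale with the trace.
#'
#' @param dff dF/F matrix (neurons x frames) or vector.
#' @param decay_tau Calcium decay time constant (s).
#' @param frame_rate Sampling rate (Hz).
#' @return Nonnegative rate matrix, same shape, with attribute `noise_sd`:
#'   a per-neuron estimate of the rate-trace noise floor, taken from the
#'   negative half of the unrectified innovations (which contains no signal).
#' @export
deconvolve <- function(dff, decay_tau, frame_rate) {
  if (decay_tau <= 0) stop("invalid argument: decay_tau must be positive", call. = FALSE)
  x <- if (is.matrix(dff)) dff else matrix(dff, nrow = 1)
  if (any(!is.finite(x))) stop("invalid input: non-finite dF/F", call. = FALSE)
  dt <- 1 / frame_rate
  gamma <- exp(-dt / decay_tau)
  innov <- x - gamma * cbind(0, x[, -ncol(x), drop = FALSE])
  rates <- pmax(innov, 0) / dt
  noise_sd <- apply(innov, 1, function(v) {
    neg <- v[v < 0]
    if (length(neg) < 2) return(0)
    sqrt(mean(neg^2)) / dt
  })
  if (!is.matrix(dff)) {
    out <- rates[1, ]
    attr(out, "noise_sd") <- noise_sd
    return(out)
  }
  attr(rates, "noise_sd") <- noise_sd
  rates
}

#' Occupancy-normalized circular tuning vector and tuning index
#'
#' Rates below `thresh_k` sigma of their noise floor are zeroed; the
#' cumulative thresholded rate in each of `n_bins` position bins is
#' normalized to the time spent in that bin (frames with locomotion below
#' `speed_threshold` are excluded from both), giving an occupancy-normalized
#' rate per bin. The tuning vector is the occupancy-weighted mean
#' resultant \eqn{\sum_b w_b e^{i\theta_b} / \sum_b w_b} over bin-center
#' angles, and the tuning index its modulus, bounded in `[0, 1]`
#' (`normalization = "resultant"`, default). `normalization = "sum"` skips
#' the division by \eqn{\sum_b w_b} and reports the unnormalized modulus.
#'
#' @param rates Nonnegative rate matrix (neurons x frames), e.g. from
#'   [deconvolve()].
#' @param session The matching `dg_session`.
#' @param n_bins Number of position bins.
#' @param thresh_k Rate threshold in units of the noise floor sd.
#' @param sigma Optional per-neuron noise-floor sd; defaults to the
#'   `noise_sd` attribute of `rates`, else a robust estimate from the
#'   sub-90th-percentile part of each trace.
#' @param speed_threshold Minimum locomotion speed (cm/s) for a frame to
#'   count.
#' @param normalization Tuning-index normalization (see above).
#' @return A `dg_tuning` object: `index` (per neuron, in `[0,1]` for the
#'   default normalization), `vector` (complex resultant per neuron),
#'   `curves` (neurons x bins occupancy-normalized rates), `occupancy`
#'   (s per bin), `theta` (bin centers), `degenerate` (all-zero thresholded
#'   neurons, whose index is defined as 0).
#' @export
tuning_vector <- function(rates, session, n_bins = 100, thresh_k = 2,
                          sigma = NULL, speed_threshold = 0.5,
                          normalization = c("resultant", "sum")) {
  normalization <- match.arg(normalization)
  r <- if (is.matrix(rates)) rates else matrix(rates, nrow = 1)
  stopifnot(ncol(r) == n_frames(session))
  if (max(session$lap_index) < 1)
    stop("invalid input: session must contain at least one full lap", call. = FALSE)
  if (is.null(sigma)) sigma <- attr(rates, "noise_sd")
  if (is.null(sigma)) {
    sigma <- apply(r, 1, function(v) {
      lowpart <- v[v <= stats::quantile(v, 0.9)]
      if (length(lowpart) < 2) 0 else stats::sd(lowpart)
    })
  }
  sigma <- rep_len(sigma, nrow(r))

  speed <- frame_speed(session$position, session$frame_times, session$belt_length)
  moving <- speed >= speed_threshold
  if (!any(moving)) stop("invalid input: no locomotion frames", call. = FALSE)
  bins <- bin_position(session$position, n_bins, session$belt_length)
  dt <- 1 / session$frame_rate
  occ_frames <- tabulate(bins[moving] + 1L, nbins = n_bins)
  occupancy <- occ_frames * dt
  visited <- occ_frames > 0
  if (!all(visited))
    warning(sprintf("%d unvisited bin(s) excluded from the tuning vector",
                    sum(!visited)), call. = FALSE)

  theta <- bin_centers(n_bins)
  nn <- nrow(r)
  curves <- matrix(NA_real_, nn, n_bins)
  vec <- complex(nn)
  index <- numeric(nn)
  degenerate <- logical(nn)
  bin_f <- factor(bins[moving], levels = 0:(n_bins - 1))
  for (i in seq_len(nn)) {
    v <- r[i, ]
    v[v < thresh_k * sigma[i]] <- 0
    # cumulative thresholded rate per bin normalized to the time spent there,
    # i.e. the occupancy-normalized (mean) rate
    w <- as.numeric(tapply(v[moving], bin_f, sum)) * dt / occupancy
    curves[i, ] <- w
    wv <- w[visited]
    tv <- theta[visited]
    if (all(!is.finite(wv)) || sum(wv, na.rm = TRUE) <= 0) {
      degenerate[i] <- TRUE
      index[i] <- 0
      vec[i] <- 0 + 0i
      next
    }
    z <- sum(wv * exp(1i * tv))
    vec[i] <- if (normalization == "resultant") z / sum(wv) else z
    index[i] <- Mod(vec[i])
  }
  structure(list(
    index = index, vector = vec, curves = curves, occupancy = occupancy,
    theta = theta, degenerate = degenerate, n_bins = n_bins,
    normalization = normalization
  ), class = "dg_tuning")
}

#' @export
print.dg_tuning <- function(x, ...) {
  cat(sprintf("<dg_tuning> %d neurons, %d bins, mean index %.3f\n",
              length(x$index), x$n_bins, mean(x$index)))
  invisible(x)
}

#' Export tuning results as CSV
#' @param tuning A `dg_tuning`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning_csv <- function(tuning, path) {
  df <- data.frame(neuron = seq_along(tuning$index), index = tuning$index)
  curves <- as.data.frame(tuning$curves)
  names(curves) <- sprintf("bin_%03d", seq_len(tuning$n_bins))
  utils::write.csv(cbind(df, curves), path, row.names = FALSE)
  invisible(path)
}

#' Polar plot of a neuron's tuning curve
#'
#' Base-graphics polar rendering of the occupancy-normalized tuning curve
#' with the tuning vector overlaid.
#'
#' @param tuning A `dg_tuning`.
#' @param neuron Neuron index.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted radii.
#' @export
plot_tuning_polar <- function(tuning, neuron, ...) {
  w <- tuning$curves[neuron, ]
  w[!is.finite(w)] <- 0
  th <- c(tuning$theta, tuning$theta[1])
  ww <- c(w, w[1])
  rmax <- max(ww, 1e-12)
  graphics::plot(ww * cos(th), ww * sin(th), type = "l", asp = 1,
                 xlab = "", ylab = "", xlim = c(-rmax, rmax), ylim = c(-rmax, rmax), ...)
  z <- tuning$vector[neuron] * rmax
  graphics::arrows(0, 0, Re(z), Im(z), length = 0.08, col = "red")
  invisible(ww)
}
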