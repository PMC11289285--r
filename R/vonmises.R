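# Von Mises tuning-curve fitting, cross-validated goodness of fit, and the
# circular-variance peak width.

#' Build a lap-by-bin tuning curve
#'
#' Maps a per-frame trace (by convention, unfiltered dF/F) to angular
#' position bins, keeping one sample per lap and bin (the mean over the
#' frames the animal spent there) plus the across-lap mean. Lap-bin cells the
#' animal never visited are marked missing and excluded from means.
#'
#' @param trace Per-frame numeric vector for one neuron.
#' @param session The matching `dg_session`.
#' @param n_bins Number of angular bins.
#' @return A `dg_tuning_curve`: `samples` (laps x bins, `NA` where missing),
#'   `mean` (per-bin across-lap mean), `theta` (bin-center angles), `n_bins`.
#' @export
build_tuning_curve <- function(trace, session, n_bins = 20) {
  stopifnot(length(trace) == n_frames(session))
  if (n_bins < 4) stop("invalid input: n_bins must be >= 4", call. = FALSE)
  if (max(session$lap_index) < 1)
    stop("invalid input: need at least 2 laps", call. = FALSE)
  bins <- bin_position(session$position, n_bins, session$belt_length)
  laps <- session$lap_index
  n_laps <- max(laps) + 1L
  samples <- matrix(NA_real_, n_laps, n_bins)
  agg <- tapply(trace, list(lap = laps, bin = bins), mean)
  samples[as.integer(rownames(agg)) + 1L, as.integer(colnames(agg)) + 1L] <- agg
  structure(list(
    samples = samples,
    mean = colMeans(samples, na.rm = TRUE),
    theta = bin_centers(n_bins),
    n_bins = n_bins
  ), class = "dg_tuning_curve")
}

#' Fit a von Mises function to a tuning curve
#'
#' Least-squares fit of `B + A exp(k (cos(theta - phi) - 1))` to the per-bin
#' means, with bounds `A >= 0`, `0 <= k <= k_max`. Initialization is
#' multi-start: `phi0` at the circular mean of the above-baseline curve mass
#' (plus rotated alternatives), `k0` from the mean resultant length, `B0` at
#' the curve minimum, `A0` at the range; each start is refined by
#' Levenberg-Marquardt and ties among optima are broken by lowest SSE, then
#' lowest k.
#'
#' @param curve A `dg_tuning_curve`, or a numeric vector of per-bin means
#'   (bin-center angles then assumed equally spaced).
#' @param k_max Upper bound on the concentration.
#' @return A `dg_vm_fit`: `B`, `A`, `k`, `phi` (in `[0, 2 pi)`), `sse`,
#'   `r2` (in-sample), `degenerate` (flat-curve flag: `A = 0`, k
#'   unidentifiable), `converged`.
#' @export
fit_von_mises <- function(curve, k_max = 50) {
  if (inherits(curve, "dg_tuning_curve")) {
    theta <- curve$theta
    y <- curve$mean
  } else {
    y <- as.numeric(curve)
    theta <- bin_centers(length(y))
  }
  ok <- is.finite(y)
  theta <- theta[ok]
  y <- y[ok]
  if (length(y) < 4) stop("invalid input: need >= 4 valid bins", call. = FALSE)

  rng <- max(y) - min(y)
  if (rng < .Machine$double.eps * max(1, abs(mean(y)))) {
    return(structure(list(B = mean(y), A = 0, k = 0, phi = 0, sse = 0, r2 = NA_real_,
                          degenerate = TRUE, converged = TRUE), class = "dg_vm_fit"))
  }

  mass <- pmax(y - min(y), 0)
  phi0 <- circular_mean(theta, mass)
  R <- resultant_length(theta, mass)
  # standard A1-inverse approximation for the concentration of a von Mises
  k0 <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
        else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
        else 1 / (R^3 - 4 * R^2 + 3 * R)
  k0 <- min(max(k0, 0.1), k_max)
  starts <- list(
    c(min(y), rng, k0, phi0),
    c(min(y), rng, 2, phi0),
    c(min(y), rng, 8, theta[which.max(y)]),
    c(min(y), rng, k0, wrap_position(phi0 + pi, 2 * pi))
  )

  sse_fun <- function(p) sum((von_mises(theta, p[1], p[2], p[3], p[4]) - y)^2)
  lower <- c(-Inf, 0, 0, -Inf)
  upper <- c(Inf, Inf, k_max, Inf)
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch({
      nls_fit <- minpack.lm::nls.lm(
        par = p0,
        fn = function(p) von_mises(theta, p[1], p[2], p[3], p[4]) - y,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
      )
      list(par = nls_fit$par, sse = sse_fun(nls_fit$par), ok = nls_fit$info %in% 1:4)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$sse < best$sse - 1e-12 ||
        (abs(fit$sse - best$sse) <= 1e-12 && fit$par[3] < best$par[3])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    p <- starts[[1]]
    return(structure(list(B = p[1], A = p[2], k = p[3],
                          phi = wrap_position(p[4], 2 * pi), sse = sse_fun(p),
                          r2 = NA_real_, degenerate = FALSE, converged = FALSE),
                     class = "dg_vm_fit"))
  }
  p <- best$par
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    B = p[1], A = p[2], k = p[3], phi = wrap_position(p[4], 2 * pi),
    sse = best$sse,
    r2 = if (ss_tot > 0) 1 - best$sse / ss_tot else NA_real_,
    degenerate = FALSE, converged = isTRUE(best$ok)
  ), class = "dg_vm_fit")
}

#' @export
print.dg_vm_fit <- function(x, ...) {
  cat(sprintf("<dg_vm_fit> B=%.4g A=%.4g k=%.4g phi=%.1f deg (sse %.3g)%s\n",
              x$B, x$A, x$k, x$phi * 180 / pi, x$sse,
              if (x$degenerate) " [flat]" else ""))
  invisible(x)
}

#' Predict from a von Mises fit
#' @param object A `dg_vm_fit`.
#' @param theta Angles (radians).
#' @param ... Ignored.
#' @return Fitted values.
#' @export
predict.dg_vm_fit <- function(object, theta, ...) {
  von_mises(theta, object$B, object$A, object$k, object$phi)
}

#' Generate stratified cross-validation splits for a tuning curve
#'
#' Within each bin, `train_frac` of the available lap-samples are assigned to
#' the training set and the remainder to the test set, independently per
#' split. Bins with fewer than 2 samples are excluded from both sets with a
#' warning.
#'
#' @param curve A `dg_tuning_curve`.
#' @param n_splits Number of random splits.
#' @param train_frac Training fraction within each bin.
#' @param seed Integer seed for the split stream.
#' @return A list of logical lap x bin matrices (`TRUE` = training sample);
#'   test samples are the non-missing `FALSE` entries in included bins.
#' @export
make_cv_splits <- function(curve, n_splits = 10, train_frac = 0.75, seed = 1L) {
  samp <- curve$samples
  avail <- is.finite(samp)
  n_avail <- colSums(avail)
  excluded <- n_avail < 2
  if (any(excluded))
    warning(sprintf("%d bin(s) with < 2 samples excluded from cross-validation",
                    sum(excluded)), call. = FALSE)
  with_stream(seed, "cv_splits", {
    lapply(seq_len(n_splits), function(s) {
      tr <- matrix(FALSE, nrow(samp), ncol(samp))
      for (b in which(!excluded)) {
        idx <- which(avail[, b])
        n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
        tr[sample(idx, n_tr), b] <- TRUE
      }
      attr(tr, "excluded_bins") <- which(excluded)
      tr
    })
  })
}

#' Cross-validated goodness of fit of the von Mises model
#'
#' For each split, the model is fitted to the per-bin means of the training
#' lap-samples and scored on the held-out samples:
#' `R2 = 1 - ss_res / ss_tot`, with `ss_res` the squared residuals of the
#' held-out samples about the model prediction and `ss_tot` their squared
#' deviations about the held-out mean (`ss_tot = "full"` uses the all-data
#' mean instead). The reported value is the mean over splits, clipped to
#' `[0, 1]` (0 = null model, 1 = oracle); the unclipped mean is kept in the
#' `unclipped` field. A cell is well fitted when `R2 > 0.5`.
#'
#' @param curve A `dg_tuning_curve`.
#' @param n_splits Number of random 75/25 splits.
#' @param train_frac Training fraction within each bin.
#' @param seed Split seed.
#' @param ss_tot Reference mean for the total sum of squares.
#' @param k_max Passed to [fit_von_mises()].
#' @return A list: `r2` (clipped mean), `unclipped`, `per_split`,
#'   `well_fitted` (`r2 > 0.5`), `seed`.
#' @export
cross_validated_r2 <- function(curve, n_splits = 10, train_frac = 0.75,
                               seed = 1L, ss_tot = c("heldout", "full"),
                               k_max = 50) {
  ss_tot <- match.arg(ss_tot)
  splits <- make_cv_splits(curve, n_splits, train_frac, seed)
  samp <- curve$samples
  theta <- curve$theta
  full_mean <- mean(samp, na.rm = TRUE)
  per_split <- vapply(splits, function(tr) {
    excluded <- attr(tr, "excluded_bins")
    test <- is.finite(samp) & !tr
    if (length(excluded)) test[, excluded] <- FALSE
    train_means <- vapply(seq_len(ncol(samp)), function(b) {
      if (!any(tr[, b])) return(NA_real_)
      mean(samp[tr[, b], b])
    }, numeric(1))
    fit <- fit_von_mises(structure(list(
      mean = train_means, theta = theta, n_bins = curve$n_bins
    ), class = "dg_tuning_curve"), k_max = k_max)
    pred <- predict(fit, theta)
    resid2 <- (samp - matrix(pred, nrow(samp), ncol(samp), byrow = TRUE))^2
    ssr <- sum(resid2[test])
    ref <- if (ss_tot == "heldout") mean(samp[test]) else full_mean
    sst <- sum((samp[test] - ref)^2)
    if (sst <= 0) return(if (ssr <= 1e-20) 1 else 0)
    1 - ssr / sst
  }, numeric(1))
  unclipped <- mean(per_split)
  r2 <- min(max(unclipped, 0), 1)
  list(r2 = r2, unclipped = unclipped, per_split = per_split,
       well_fitted = r2 > 0.5, seed = seed)
}

#' Peak width as circular variance
#'
#' `V = 1 - I1(k) / I0(k)`, the circular variance of a von Mises density of
#' concentration `k`: 1 at `k = 0` (flat), decreasing to 0 as the peak
#' narrows. Computed with exponentially scaled Bessel functions so large `k`
#' does not overflow.
#'
#' @param k Concentration(s), >= 0.
#' @return Circular variance in `[0, 1]`.
#' @export
peak_width <- function(k) {
  if (any(k < 0)) stop("invalid argument: k must be >= 0", call. = FALSE)
  1 - besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
}
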