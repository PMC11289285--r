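# Position decoding, bias-corrected linear Fisher information (d-prime
# squared), noise-correlation surrogates, and discrimination thresholds.

#' Build the (neuron, bin, lap) trial tensor
#'
#' Lap-by-bin mean responses on the unfiltered dF/F traces (or any per-frame
#' matrix passed as `trace`): entry `[i, b, t]` is neuron i's mean response
#' in position bin b on lap t, `NA` where the lap never visited the bin.
#'
#' @param session A `dg_session`.
#' @param n_bins Number of position bins.
#' @param trace Optional matrix to aggregate instead of `session$dff`.
#' @return A `dg_trial_tensor`: `responses` (array neurons x bins x laps),
#'   `n_bins`, `delta_s` (bin width, cm), `T_per_bin` (complete laps per
#'   bin), `belt_length`.
#' @export
build_trial_tensor <- function(session, n_bins = 20, trace = NULL) {
  x <- trace %||% session$dff
  stopifnot(ncol(x) == n_frames(session))
  if (max(session$lap_index) < 1)
    stop("insufficient trials: need >= 2 laps", call. = FALSE)
  bins <- bin_position(session$position, n_bins, session$belt_length)
  laps <- session$lap_index
  n_laps <- max(laps) + 1L
  nn <- nrow(x)
  nf <- ncol(x)
  g <- bins + n_bins * laps + 1L # bin-fastest cell index
  G <- n_bins * n_laps
  M <- matrix(0, nf, G)
  M[cbind(seq_len(nf), g)] <- 1
  counts <- colSums(M)
  sums <- x %*% M
  means <- sweep(sums, 2, counts, "/") # NaN where a lap never visited a bin
  means[, counts == 0] <- NA
  resp <- array(means, c(nn, n_bins, n_laps))
  structure(list(
    responses = resp, n_bins = n_bins,
    delta_s = session$belt_length / n_bins,
    T_per_bin = apply(!is.na(resp[1, , , drop = FALSE]), 2, sum),
    belt_length = session$belt_length
  ), class = "dg_trial_tensor")
}

#' @export
print.dg_trial_tensor <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<dg_trial_tensor> %d neurons x %d bins x %d laps (min T = %d)\n",
              d[1], d[2], d[3], min(x$T_per_bin)))
  invisible(x)
}

#' Subsample neurons from a trial tensor
#'
#' Draws `n_draws` random subsets of `n` neurons without replacement, so
#' downstream metrics can be averaged over equally sized populations across
#' animals. If the tensor holds fewer than `n` neurons the draw is refused
#' with an explicit flag rather than silently padded.
#'
#' @param tensor A `dg_trial_tensor`.
#' @param n Neurons per draw.
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return A list with `met` (logical), and when met, `draws`: a list of
#'   `dg_trial_tensor`s, plus `subsets` (the neuron indices used).
#' @export
subsample_neurons <- function(tensor, n = 42, n_draws = 10, seed = 1L) {
  nn <- dim(tensor$responses)[1]
  if (nn < n) {
    return(list(met = FALSE, n_available = nn, n_requested = n))
  }
  if (nn == n) n_draws <- 1L
  subsets <- with_stream(seed, "subsample", {
    lapply(seq_len(n_draws), function(d) sort(sample.int(nn, n)))
  })
  draws <- lapply(subsets, function(idx) {
    out <- tensor
    out$responses <- tensor$responses[idx, , , drop = FALSE]
    out
  })
  list(met = TRUE, draws = draws, subsets = subsets)
}

#' Decode position with a regularized multinomial linear decoder
#'
#' Multinomial logistic regression (ridge penalty, fixed strength) over the
#' position bins, trained on per-frame unfiltered dF/F: accuracy is the mean
#' held-out fraction correct over `n_splits` random stratified
#' `train_frac`/(1 - `train_frac`) splits of the frames. The decoder weights
#' retained for Fisher-information projections come from a final fit on all
#' frames.
#'
#' @param session A `dg_session`, or a numeric feature matrix
#'   (frames x neurons) if `labels` is given.
#' @param labels Optional integer bin label per frame (0-based); defaults to
#'   [bin_position()] of the session positions.
#' @param n_bins Number of position bins.
#' @param n_splits Number of random splits.
#' @param train_frac Training fraction.
#' @param lambda Ridge penalty.
#' @param seed Split seed.
#' @return A `dg_decoder`: `accuracy` (mean fraction correct), `per_split`,
#'   `weights` (neurons x bins), `intercepts`, `n_bins`, `seed`.
#' @export
decode_position <- function(session, labels = NULL, n_bins = 20,
                            n_splits = 10, train_frac = 0.75,
                            lambda = 0.01, seed = 1L) {
  if (inherits(session, "dg_session")) {
    X <- t(session$dff)
    if (is.null(labels))
      labels <- bin_position(session$position, n_bins, session$belt_length)
  } else {
    X <- as.matrix(session)
    if (is.null(labels)) stop("labels required when passing a feature matrix", call. = FALSE)
  }
  y <- factor(labels, levels = 0:(n_bins - 1))
  if (any(table(y) < 2))
    stop("invalid input: every bin needs at least 2 frames", call. = FALSE)

  splits <- with_stream(seed, "decoder_splits", {
    lapply(seq_len(n_splits), function(s) {
      tr <- logical(length(y))
      for (lev in levels(y)) {
        idx <- which(y == lev)
        tr[sample(idx, max(1L, round(train_frac * length(idx))))] <- TRUE
      }
      tr
    })
  })
  # glmnet needs warm starts along a decreasing path to converge at a small
  # ridge penalty; predict at the target lambda (last in the path)
  lam_seq <- exp(seq(log(1e3 * lambda), log(lambda), length.out = 12))
  ridge_fit <- function(Xm, ym) {
    glmnet::glmnet(Xm, ym, family = "multinomial", alpha = 0, lambda = lam_seq)
  }
  per_split <- vapply(splits, function(tr) {
    fit <- ridge_fit(X[tr, , drop = FALSE], y[tr])
    pred <- predict(fit, X[!tr, , drop = FALSE], type = "class", s = lambda)
    mean(pred == as.character(y[!tr]))
  }, numeric(1))

  full <- ridge_fit(X, y)
  co <- stats::coef(full, s = lambda)
  W <- do.call(cbind, lapply(co, function(m) as.numeric(m[-1, 1])))
  b0 <- vapply(co, function(m) m[1, 1], numeric(1))
  colnames(W) <- names(co)
  structure(list(
    accuracy = mean(per_split), per_split = per_split,
    weights = W, intercepts = b0, n_bins = n_bins, seed = seed
  ), class = "dg_decoder")
}

#' @export
print.dg_decoder <- function(x, ...) {
  cat(sprintf("<dg_decoder> %d bins, held-out accuracy %.1f%% (chance %.1f%%)\n",
              x$n_bins, 100 * x$accuracy, 100 / x$n_bins))
  invisible(x)
}

# Bias-corrected d'^2 between two response samples (projections or single
# neuron), N readout dimensions (= 1 here), T trials per location:
#   d2_bc = d2_naive * (2T - N - 3) / (2T - 2) - 2N / T
# which makes the estimator unbiased for Gaussian responses.
dprime2_bc <- function(z1, z2, correct = TRUE) {
  T1 <- length(z1); T2 <- length(z2)
  Tn <- min(T1, T2)
  if (Tn < 2) return(NA_real_)
  v <- 0.5 * (stats::var(z1) + stats::var(z2))
  if (!is.finite(v) || v <= 0) return(NA_real_)
  naive <- (mean(z1) - mean(z2))^2 / v
  if (!correct) return(naive)
  N <- 1
  naive * (2 * Tn - N - 3) / (2 * Tn - 2) - 2 * N / Tn
}

#' Population Fisher information from decoder projections
#'
#' For each pair of adjacent position bins (including the circular wrap),
#' lap responses are projected onto the pair-relevant decoder weight
#' direction (difference of the two class weight vectors), and d-prime
#' squared is computed on the 1D projections with small-sample bias
#' correction; pairs are then averaged. Equivalent linear Fisher information
#' per cm^2 is the average divided by the squared bin width.
#'
#' @param tensor A `dg_trial_tensor`.
#' @param weights Decoder weight matrix (neurons x bins), e.g. from
#'   [decode_position()].
#' @param correct Apply the small-sample bias correction.
#' @return A `dg_info`: `d2_pairs` (per adjacent pair), `d2` (average),
#'   `J_per_cm2`, `skipped` (zero-variance pairs), `T_used`.
#' @export
population_fisher_info <- function(tensor, weights, correct = TRUE) {
  resp <- tensor$responses
  B <- tensor$n_bins
  stopifnot(nrow(weights) == dim(resp)[1], ncol(weights) == B)
  d2 <- numeric(B)
  Tu <- integer(B)
  for (b in seq_len(B)) {
    b2 <- if (b == B) 1L else b + 1L
    w <- weights[, b] - weights[, b2]
    ok <- apply(!is.na(resp[, b, , drop = FALSE]), 3, all) &
      apply(!is.na(resp[, b2, , drop = FALSE]), 3, all)
    z1 <- as.numeric(t(w) %*% matrix(resp[, b, ok], nrow = length(w)))
    z2 <- as.numeric(t(w) %*% matrix(resp[, b2, ok], nrow = length(w)))
    d2[b] <- dprime2_bc(z1, z2, correct)
    Tu[b] <- sum(ok)
  }
  skipped <- !is.finite(d2)
  structure(list(
    d2_pairs = d2, d2 = mean(d2[!skipped]),
    J_per_cm2 = mean(d2[!skipped]) / tensor$delta_s^2,
    skipped = which(skipped), T_used = Tu
  ), class = "dg_info")
}

#' Single-cell Fisher information
#'
#' Bias-corrected signal-to-noise ratio per neuron: for each adjacent bin
#' pair, the signal is the squared difference of the mean activity at the
#' two locations and the noise the average variance at each, corrected for
#' small trial counts (see [population_fisher_info()]); pairs are averaged
#' per neuron.
#'
#' @param tensor A `dg_trial_tensor`.
#' @param neurons Neuron indices (default all).
#' @param correct Apply the small-sample bias correction.
#' @return A list: `d2` (per-neuron average d-prime squared), `J_per_cm2`,
#'   `d2_pairs` (neurons x pairs matrix).
#' @export
single_cell_fisher_info <- function(tensor, neurons = NULL, correct = TRUE) {
  resp <- tensor$responses
  B <- tensor$n_bins
  neurons <- neurons %||% seq_len(dim(resp)[1])
  pairs <- matrix(NA_real_, length(neurons), B)
  for (ii in seq_along(neurons)) {
    i <- neurons[ii]
    for (b in seq_len(B)) {
      b2 <- if (b == B) 1L else b + 1L
      z1 <- resp[i, b, ]
      z2 <- resp[i, b2, ]
      ok <- is.finite(z1) & is.finite(z2)
      pairs[ii, b] <- dprime2_bc(z1[ok], z2[ok], correct)
    }
  }
  d2 <- rowMeans(pairs, na.rm = TRUE)
  list(d2 = d2, J_per_cm2 = d2 / tensor$delta_s^2, d2_pairs = pairs)
}

#' Destroy noise correlations by per-neuron trial shuffling
#'
#' Within each position bin, lap order is permuted independently for each
#' neuron: every neuron's response is replaced by its response at the same
#' location on a different lap. Per-neuron per-bin marginals (hence tuning
#' curves) are preserved exactly; cross-neuron within-bin covariances are
#' destroyed in expectation.
#'
#' @param tensor A `dg_trial_tensor`.
#' @param seed Integer seed.
#' @return A shuffled `dg_trial_tensor`.
#' @export
shuffle_noise_correlations <- function(tensor, seed = 1L) {
  resp <- tensor$responses
  d <- dim(resp)
  with_stream(seed, "nc_shuffle", {
    for (i in seq_len(d[1])) {
      for (b in seq_len(d[2])) {
        idx <- which(is.finite(resp[i, b, ]))
        if (length(idx) > 1) resp[i, b, idx] <- resp[i, b, sample(idx)]
      }
    }
  })
  out <- tensor
  out$responses <- resp
  out
}

#' Mean pairwise noise correlation of a trial tensor
#'
#' Pearson correlation across laps of the within-bin responses for every
#' neuron pair, averaged over bins and pairs.
#'
#' @param tensor A `dg_trial_tensor`.
#' @return Mean pairwise correlation (scalar).
#' @export
noise_correlations <- function(tensor) {
  resp <- tensor$responses
  B <- tensor$n_bins
  vals <- c()
  for (b in seq_len(B)) {
    m <- t(resp[, b, ]) # laps x neurons
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3) next
    cc <- suppressWarnings(stats::cor(m))
    vals <- c(vals, cc[upper.tri(cc)])
  }
  mean(vals, na.rm = TRUE)
}

#' Discrimination threshold from Fisher information
#'
#' Under the local-linear Gaussian model, two positions `delta` cm apart are
#' separated by `d'(delta) = delta * sqrt(J)`; an equal-prior ideal observer
#' is correct with probability `PC = Phi(d'/2)` (`model = "single"`,
#' default) or `Phi(d'/sqrt(2))` (`model = "2afc"`). The threshold is the
#' smallest distance discriminated correctly at the criterion rate:
#' `delta* = 2 * qnorm(criterion) / sqrt(J)`.
#'
#' @param J_per_cm2 Fisher information per cm^2.
#' @param criterion Required proportion correct (default 0.70).
#' @param model Ideal-observer convention.
#' @return Threshold distance (cm); `Inf` with a warning when `J <= 0`.
#' @export
discrimination_threshold <- function(J_per_cm2, criterion = 0.70,
                                     model = c("single", "2afc")) {
  model <- match.arg(model)
  stopifnot(criterion > 0.5, criterion < 1)
  mult <- if (model == "single") 2 else sqrt(2)
  out <- ifelse(J_per_cm2 > 0, mult * stats::qnorm(criterion) / sqrt(pmax(J_per_cm2, 0)), Inf)
  if (any(!is.finite(out)))
    warning("non-positive Fisher information: threshold reported as Inf", call. = FALSE)
  out
}
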