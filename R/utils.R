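# Internal helpers shared across modules: derived RNG streams, rolling
# statistics, circular arithmetic.

#' Derive a child seed from a root seed and a stream name
#'
#' All stochastic stages of the pipeline draw from sub-streams derived
#' deterministically from one root seed, so a single integer reproduces an
#' entire experiment while independent stages (trajectory, tuning parameters,
#' spikes, noise, splits) stay decoupled.
#'
#' @param seed Integer root seed.
#' @param key Character stream name, e.g. `"spikes"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(key), length(key) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps derived seeds in int range
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% m
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m)
}

# Evaluate `code` under a derived seed without disturbing the caller's RNG.
with_stream <- function(seed, key, code) {
  withr::with_seed(derive_seed(seed, key), code)
}

# Centered rolling mean of x over a window of `w` samples, using only frames
# where `mask` is TRUE; windows with no unmasked frame fall back to the
# overall masked mean.
masked_rolling_mean <- function(x, mask, w) {
  n <- length(x)
  stopifnot(length(mask) == n, w >= 1)
  half <- floor(w / 2)
  xm <- ifelse(mask, x, 0)
  cs <- c(0, cumsum(xm))
  cn <- c(0, cumsum(as.numeric(mask)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cn[hi + 1L] - cn[lo]
  out <- s / k
  if (any(k == 0)) {
    fallback <- if (any(mask)) mean(x[mask]) else mean(x)
    out[k == 0] <- fallback
  }
  out
}

# Rolling lower-percentile baseline on a coarse grid (one knot per `stride`
# frames), linearly interpolated back to every frame.
rolling_quantile <- function(x, w, prob, stride = NULL) {
  n <- length(x)
  if (is.null(stride)) stride <- max(1L, round(w / 20))
  half <- floor(w / 2)
  centers <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(centers, function(i) {
    win <- x[max(1L, i - half):min(n, i + half)]
    stats::quantile(win, prob, names = FALSE, type = 7)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

# Wrap values onto [0, period).
wrap_position <- function(x, period) {
  y <- x %% period
  y[y == period] <- 0
  y
}

# Circular mean of angles weighted by w; returns angle in [0, 2*pi).
circular_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  z <- sum(w * exp(1i * theta))
  wrap_position(Arg(z), 2 * pi)
}

# Mean resultant length of angles weighted by nonnegative w.
resultant_length <- function(theta, w) {
  s <- sum(w)
  if (s <= 0) return(0)
  Mod(sum(w * exp(1i * theta)) / s)
}

# Per-frame locomotion speed (cm/s) from wrapped position.
frame_speed <- function(position, frame_times, belt_length) {
  d <- diff(position) %% belt_length
  # backwards micro-jitter shows up as a near-belt-length forward step; fold it
  d[d > belt_length / 2] <- d[d > belt_length / 2] - belt_length
  dt <- diff(frame_times)
  c(0, d / dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
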