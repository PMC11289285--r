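# Significant-transient detection and distance-normalized activity.

test_that("zero-phase filter has unit DC gain, strong stopband, and symmetry", {
  x <- rep(2.5, 600)
  expect_equal(lowpass_filter(x, 15), x, tolerance = 1e-9)
  # 6 Hz sinusoid vs 2 Hz cutoff: amplitude attenuated by > 99 %
  t <- seq_len(3000) / 15
  s <- sin(2 * pi * 6 * t)
  sf <- lowpass_filter(s, 15)
  mid <- 500:2500
  expect_lt(max(abs(sf[mid])), 0.01)
  # filtering then reversing equals reversing then filtering
  set.seed(2)
  y <- cumsum(rnorm(900))
  expect_equal(rev(lowpass_filter(y, 15)), lowpass_filter(rev(y), 15),
               tolerance = 1e-8)
  expect_error(lowpass_filter(y, 15, cutoff = 8), "Nyquist")
})

test_that("an isolated 5-sigma boxcar yields exactly one spanning transient", {
  x <- rep(0, 2000)
  x[1000:1030] <- 0.1
  ts <- detect_transients(x, 15)
  expect_equal(nrow(ts$intervals), 1L)
  expect_lte(abs(ts$intervals$start - 1000), 1)
  expect_lte(abs(ts$intervals$end - 1030), 1)
  # constant trace: degenerate, no transients
  tc <- detect_transients(rep(1, 2000), 15)
  expect_equal(nrow(tc$intervals), 0L)
  expect_true(all(tc$degenerate))
  expect_error(detect_transients(rep(0, 100), 15), "shorter than")
})

test_that("iterative baseline refinement never inflates the residual sd", {
  cfg <- synthetic_config(n_neurons = 30, n_laps = 10, seed = 9)
  s <- simulate_session(cfg)$session
  f <- lowpass_filter(s$dff, s$frame_rate)
  ts <- detect_transients(f, s$frame_rate)
  ok <- !ts$degenerate
  expect_true(all(ts$sigma[ok, 2] <= ts$sigma[ok, 1] + 1e-12))
  expect_true(all(ts$sigma[ok, 3] <= ts$sigma[ok, 2] + 1e-12))
})

test_that("intervals are disjoint and the masked trace conserves the integral", {
  cfg <- synthetic_config(n_neurons = 10, n_laps = 10, seed = 13)
  s <- simulate_session(cfg)$session
  f <- lowpass_filter(s$dff, s$frame_rate)
  ts <- detect_transients(f, s$frame_rate)
  for (i in unique(ts$intervals$neuron)) {
    iv <- ts$intervals[ts$intervals$neuron == i, ]
    expect_true(all(diff(iv$start) > 0))
    if (nrow(iv) > 1) expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
    expect_equal(sum(ts$masked[i, ]) / s$frame_rate, sum(iv$integral),
                 tolerance = 1e-10)
  }
})

test_that("detection is offset-invariant and time-translation equivariant", {
  set.seed(6)
  base <- rnorm(1500, 0, 0.02)
  mk <- function(at) { x <- base; x[at:(at + 20)] <- x[at:(at + 20)] + 0.15; x }
  ts1 <- detect_transients(mk(400), 15)
  ts_off <- detect_transients(mk(400) + 3.7, 15)
  expect_equal(ts1$intervals[, c("start", "end")],
               ts_off$intervals[, c("start", "end")])
  # same event later in the trace is found with the same duration
  ts2 <- detect_transients(mk(900), 15)
  d1 <- ts1$intervals[which.max(ts1$intervals$peak), ]
  d2 <- ts2$intervals[which.max(ts2$intervals$peak), ]
  expect_equal(d1$end - d1$start, d2$end - d2$start, tolerance = 1)
  expect_equal(d2$start - d1$start, 500, tolerance = 2)
})

test_that("transient recall of strong simulated events exceeds 90 %", {
  cfg <- synthetic_config(n_neurons = 30, n_laps = 15, seed = 31)
  sim <- simulate_session(cfg)
  s <- sim$session
  ts <- detect_transients(lowpass_filter(s$dff, s$frame_rate), s$frame_rate)
  strong <- sim$truth$dff_clean > 4 * cfg$noise_sd
  recall <- sum(ts$masked != 0 & strong) / sum(strong)
  expect_gt(recall, 0.9)
})

test_that("activity is the distance-normalized transient integral", {
  s <- fx_session()
  nf <- n_frames(s)
  # no transients: activity 0
  flat <- matrix(rnorm(nf, 0, 1e-4), 1)
  tset0 <- detect_transients(flat, s$frame_rate)
  tset0$masked[] <- 0
  expect_equal(compute_activity(tset0, s), 0)
  # one transient of integral I over distance D gives I / D
  x <- rep(0, nf); x[100:130] <- 0.2
  ts1 <- detect_transients(matrix(x, 1), s$frame_rate)
  D <- session_distance(s)
  expect_equal(compute_activity(ts1, s), sum(ts1$intervals$integral) / D,
               tolerance = 1e-12)
  # zero distance is an error
  s0 <- s; s0$position <- rep(1, nf)
  expect_error(compute_activity(ts1, s0), "zero distance")
})

test_that("doubling the gain raises median population activity", {
  cfg <- synthetic_config(n_neurons = 40, n_laps = 10, seed = 17)
  s1 <- simulate_session(cfg)$session
  s2 <- apply_gain(s1, 2)
  act <- function(s) {
    median(compute_activity(
      detect_transients(lowpass_filter(s$dff, s$frame_rate), s$frame_rate), s))
  }
  expect_gt(act(s2), act(s1))
})
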