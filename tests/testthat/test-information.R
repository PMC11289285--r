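# Trial tensors, decoding, bias-corrected Fisher information, shuffles,
# and discrimination thresholds.

gaussian_tensor <- function(mu, sigma, T, delta_s = 9) {
  # mu: bins x neurons matrix of mean responses
  B <- nrow(mu); nn <- ncol(mu)
  resp <- array(rnorm(nn * B * T, rep(t(mu), T), sigma), c(nn, B, T))
  structure(list(responses = resp, n_bins = B, delta_s = delta_s,
                 T_per_bin = rep(T, B), belt_length = delta_s * B),
            class = "dg_trial_tensor")
}

test_that("trial tensors hold lap-by-bin means with the right shape", {
  s <- fx_session()
  nlap <- max(s$lap_index) + 1L
  tens <- build_trial_tensor(s)
  expect_equal(dim(tens$responses), c(n_neurons(s), 20L, nlap))
  expect_equal(tens$delta_s, 9)
  # constant trace: every filled cell is the constant
  tc <- build_trial_tensor(s, trace = matrix(1.5, 1, n_frames(s)))
  expect_true(all(tc$responses[is.finite(tc$responses)] == 1.5))
  # brute-force check of a handful of cells
  bins <- bin_position(s$position, 20, s$belt_length)
  for (cell in list(c(3, 5, 2), c(1, 20, 4), c(7, 1, 1))) {
    sel <- bins == (cell[2] - 1) & s$lap_index == (cell[3] - 1)
    expect_equal(tens$responses[cell[1], cell[2], cell[3]],
                 mean(s$dff[cell[1], sel]), tolerance = 1e-12)
  }
})

test_that("neuron subsampling is deterministic and refuses short tensors", {
  tens <- build_trial_tensor(fx_session())
  sub_all <- subsample_neurons(tens, n = n_neurons(fx_session()), seed = 4)
  expect_true(sub_all$met)
  expect_length(sub_all$draws, 1L)
  expect_identical(sub_all$draws[[1]]$responses, tens$responses)
  s1 <- subsample_neurons(tens, n = 10, n_draws = 3, seed = 11)
  s2 <- subsample_neurons(tens, n = 10, n_draws = 3, seed = 11)
  expect_identical(s1$subsets, s2$subsets)
  short <- subsample_neurons(tens, n = 1000, seed = 1)
  expect_false(short$met)
  expect_equal(short$n_requested, 1000)
})

test_that("the decoder solves a separable population exactly", {
  set.seed(12)
  n_bins <- 20; per <- 30
  labels <- rep(0:(n_bins - 1), each = per)
  X <- matrix(0, length(labels), n_bins)
  X[cbind(seq_along(labels), labels + 1L)] <- 1
  X <- X + matrix(rnorm(length(X), 0, 0.01), nrow(X))
  dec <- decode_position(X, labels = labels, n_splits = 3, seed = 2)
  expect_equal(dec$accuracy, 1.0)
  expect_equal(dim(dec$weights), c(n_bins, n_bins))
})

test_that("bias-corrected d-prime squared is calibrated against Gaussian oracles", {
  set.seed(11)
  # null: corrected estimator centred on 0, naive positively biased
  nul <- replicate(800, dgspace:::dprime2_bc(rnorm(50), rnorm(50)))
  expect_lt(abs(mean(nul)), 2 * sd(nul) / sqrt(length(nul)))
  naive <- replicate(800, dgspace:::dprime2_bc(rnorm(20), rnorm(20), correct = FALSE))
  expect_gt(mean(naive), 0.05)
  # delta mu = 2, sigma = 1: asymptotic d'^2 = 4, estimator at T = 200 within 5 %
  est <- replicate(400, dgspace:::dprime2_bc(rnorm(200, 0), rnorm(200, 2)))
  expect_equal(mean(est), 4, tolerance = 0.05)
  # scale invariance is exact
  set.seed(13); z1 <- rnorm(40); z2 <- rnorm(40, 1)
  expect_equal(dgspace:::dprime2_bc(3 * z1, 3 * z2),
               dgspace:::dprime2_bc(z1, z2), tolerance = 1e-12)
})

test_that("single-cell estimates agree with the analytic homogeneous population", {
  set.seed(21)
  th <- (seq_len(20) - 0.5) * 2 * pi / 20
  mu <- outer(von_mises(th, 0, 2, 3, pi), rep(1, 6))
  tens <- gaussian_tensor(mu, sigma = 1, T = 200)
  sc <- single_cell_fisher_info(tens)
  # analytic adjacent-pair average for this tuning curve and noise
  mu1 <- mu[, 1]
  d2_true <- mean((mu1 - mu1[c(2:20, 1)])^2)
  expect_equal(mean(sc$d2), d2_true, tolerance = 0.1)
  # population read-out through the optimal direction carries more information
  pop <- population_fisher_info(tens, t(mu))
  expect_gt(pop$d2, max(sc$d2))
})

test_that("trial shuffling preserves marginals exactly and kills correlations", {
  cfg <- synthetic_config(n_neurons = 40, n_laps = 20, seed = 7)
  tens <- build_trial_tensor(simulate_session(cfg)$session)
  sh <- shuffle_noise_correlations(tens, seed = 5)
  for (i in c(1, 17, 40)) {
    for (b in c(1, 10, 20)) {
      expect_identical(sort(sh$responses[i, b, ]), sort(tens$responses[i, b, ]))
    }
  }
  sh2 <- shuffle_noise_correlations(tens, seed = 99)
  expect_identical(sort(sh2$responses[3, 7, ]), sort(sh$responses[3, 7, ]))
  Tmin <- min(tens$T_per_bin)
  expect_gt(noise_correlations(tens), 0)
  expect_lt(abs(noise_correlations(sh)), 2 / sqrt(Tmin))
})

test_that("discrimination thresholds follow the ideal-observer quantile", {
  expect_equal(discrimination_threshold(1, 0.70), 2 * qnorm(0.70),
               tolerance = 1e-12)
  expect_equal(discrimination_threshold(1, 0.70, model = "2afc"),
               sqrt(2) * qnorm(0.70), tolerance = 1e-12)
  J <- c(0.05, 0.2, 1, 5, 100)
  thr <- discrimination_threshold(J)
  expect_true(all(diff(thr) < 0)) # strictly decreasing in J
  expect_lt(discrimination_threshold(1e8), 1e-3) # J -> Inf limit
  expect_warning(out <- discrimination_threshold(0), "non-positive")
  expect_identical(out, Inf)
})
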