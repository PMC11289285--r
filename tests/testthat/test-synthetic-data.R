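# Synthetic-session generator: trajectory arithmetic, determinism, gain
# scaling, occupancy, noise correlations, parameter recovery.

test_that("trajectory reproduces the configured speed, lap count and encoder identity", {
  cfg <- fx_cfg()
  traj <- simulate_trajectory(cfg)
  # mean per-frame displacement at 421 cm/min, 15 Hz is 421/900 cm
  expect_equal(mean(diff(traj$true_unwrapped)), 421 / 900, tolerance = 0.02)
  expect_equal(max(floor(traj$true_unwrapped / cfg$belt_length)), cfg$n_laps - 1L)
  expect_lt(max(traj$true_unwrapped), cfg$n_laps * cfg$belt_length)
  # zero encoder noise: cumulative ticks equal true position everywhere
  expect_equal(cumsum(traj$ticks), traj$true_unwrapped, tolerance = 1e-12)
  # RFID events fire at texture boundaries
  expect_true(all(traj$rfid_events$position %in% c(0, 45, 90, 135)))
  expect_error(simulate_trajectory(cfg, encoder_noise_sd = -1), "invalid config")
  bad <- fx_cfg(); bad$mean_speed <- -5
  expect_error(validate_config(bad), "invalid config")
})

test_that("uncorrected encoder gain error grows with distance but RFID bounds it", {
  cfg <- fx_cfg()
  traj <- simulate_trajectory(cfg, encoder_gain = 1.01)
  # without RFID: terminal unwrapped error ~ 1% of total distance
  no_rfid <- traj; no_rfid$rfid_events <- traj$rfid_events[0, ]
  rec <- reconstruct_position(no_rfid, cfg$belt_length)
  u_est <- cumsum(traj$ticks)
  expect_equal(utils::tail(u_est - traj$true_unwrapped, 1),
               0.01 * utils::tail(traj$true_unwrapped, 1), tolerance = 1e-6)
  # with RFID every 45 cm, wrapped error stays below 1% of the tag spacing
  # plus one frame of travel
  rec2 <- reconstruct_position(traj, cfg$belt_length)
  err <- abs(rec2$position - traj$true_position)
  err <- pmin(err, cfg$belt_length - err)
  expect_lt(max(err), 0.01 * 45 + 0.5)
})

test_that("simulation is bit-deterministic and multiplicative in gain", {
  cfg <- fx_cfg()
  sim1 <- fx_sim()
  sim2 <- simulate_session(cfg)
  expect_identical(sim1$session$dff, sim2$session$dff)
  expect_identical(sim1$truth$spikes, sim2$truth$spikes)

  # g = 0: traces are pure noise around zero
  cfg0 <- cfg; cfg0$gain <- 0
  s0 <- simulate_session(cfg0)$session
  expect_lt(max(abs(rowMeans(s0$dff))), 3 * cfg$noise_sd)
  expect_equal(sum(simulate_session(cfg0)$truth$spikes), 0)

  # doubling g doubles expected spike counts
  cfg2 <- cfg; cfg2$gain <- 2
  r <- sum(simulate_session(cfg2)$truth$spikes) / sum(sim1$truth$spikes)
  expect_equal(r, 2, tolerance = 0.1)
})

test_that("untuned populations are flat across position bins", {
  cfg <- synthetic_config(n_neurons = 15, n_laps = 15, seed = 44,
                          fraction_tuned = 0, shared_gain_sd = 0)
  sim <- simulate_session(cfg)
  s <- sim$session
  # pooled event counts per bin should be multinomial with occupancy
  # proportions: chi-square goodness of fit on the latent events
  bins <- bin_position(s$position, 20, s$belt_length)
  counts <- vapply(0:19, function(b) sum(sim$truth$spikes[, bins == b]), numeric(1))
  occ <- tabulate(bins + 1L, 20)
  p <- suppressWarnings(stats::chisq.test(counts, p = occ / sum(occ)))$p.value
  expect_gt(p, 0.001)
})

test_that("apply_gain is the identity at g = 1 and rescales fitted amplitudes", {
  s <- fx_session()
  expect_identical(apply_gain(s, 1)$dff, s$dff)
  expect_error(apply_gain(s, -1), "invalid argument")

  sim <- fx_sim_tuned()
  st <- sim$session
  s2 <- apply_gain(st, 2)
  cfg <- st$metadata$config
  rat <- vapply(1:8, function(i) {
    f1 <- fit_von_mises(build_tuning_curve(
      deconvolve(st$dff[i, ], cfg$decay_tau, st$frame_rate), st, 20))
    f2 <- fit_von_mises(build_tuning_curve(
      deconvolve(s2$dff[i, ], cfg$decay_tau, s2$frame_rate), s2, 20))
    f2$A / f1$A
  }, numeric(1))
  expect_equal(mean(rat), 2, tolerance = 0.1)
})

test_that("occupancy is near-uniform for the default locomotion model", {
  cfg <- synthetic_config(n_neurons = 1, n_laps = 20, seed = 5)
  traj <- simulate_trajectory(cfg)
  occ <- tabulate(bin_position(traj$true_position, 100, cfg$belt_length) + 1L, 100)
  expect_lt(max(occ) / min(occ), 1.2)
})

test_that("shared gain induces positive noise correlations, none without it", {
  cfg <- synthetic_config(n_neurons = 50, n_laps = 20, seed = 7)
  tensor <- build_trial_tensor(simulate_session(cfg)$session)
  nc_shared <- noise_correlations(tensor)
  cfg0 <- cfg; cfg0$shared_gain_sd <- 0
  nc_zero <- noise_correlations(build_trial_tensor(simulate_session(cfg0)$session))
  expect_gt(nc_shared, 0.01)
  expect_lt(abs(nc_zero), 0.01)
  expect_gt(nc_shared, nc_zero)
})

test_that("tuning parameters are recovered from 50-lap high-SNR sessions", {
  sim <- fx_sim_tuned()
  s <- sim$session
  cfg <- s$metadata$config
  rates <- deconvolve(s$dff, cfg$decay_tau, s$frame_rate)
  p <- sim$truth$params
  errs <- vapply(seq_len(nrow(p)), function(i) {
    f <- fit_von_mises(build_tuning_curve(rates[i, ], s, 20))
    c(circ_err_deg(f$phi, p$phi[i]), abs(f$k - p$k[i]) / p$k[i])
  }, numeric(2))
  expect_lt(mean(errs[1, ]), 5)   # peak location, degrees
  expect_lt(mean(errs[2, ]), 0.2) # concentration, relative
})
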