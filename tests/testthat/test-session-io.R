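# Position reconstruction, dF/F, binning, and container round trips.

make_trace <- function(ticks, tags = data.frame(sample = integer(0), tag = integer(0),
                                                position = numeric(0)),
                       dt = 1 / 15) {
  t <- seq_along(ticks) * dt
  list(ticks = ticks, sample_times = t, frame_times = t,
       rfid_events = tags, tag_positions = c(0, 45, 90, 135))
}

test_that("reconstruction handles wrap-around, stationarity and drift correction", {
  # exactly one belt length of constant travel: back to start, lap 1
  r <- reconstruct_position(make_trace(rep(1, 180)), 180)
  expect_equal(utils::tail(r$position, 1), 0)
  expect_equal(utils::tail(r$lap_index, 1), 1L)
  expect_true(all(diff(r$lap_index) >= 0))

  # zero increments: constant position, lap 0 throughout
  r0 <- reconstruct_position(make_trace(rep(0, 100)), 180)
  expect_true(all(r0$position == 0))
  expect_true(all(r0$lap_index == 0L))

  # noise-free encoder is reproduced exactly
  cfg <- fx_cfg()
  traj <- simulate_trajectory(cfg)
  rec <- reconstruct_position(traj, cfg$belt_length)
  expect_lt(max(abs(rec$position - traj$true_position)), 1e-9)
  expect_identical(rec$lap_index,
                   as.integer(floor(traj$true_unwrapped / cfg$belt_length)))

  # 5% inflated increments, tags every 45 cm: error below 0.05 * 45
  traj5 <- simulate_trajectory(cfg, encoder_gain = 1.05)
  for (mode in c("reset", "distribute")) {
    rec5 <- reconstruct_position(traj5, cfg$belt_length, drift = mode)
    err <- abs(rec5$position - traj5$true_position)
    err <- pmin(err, cfg$belt_length - err)
    expect_lt(max(err), 0.05 * 45)
  }
})

test_that("reconstruction rejects unknown tags and non-monotone times", {
  tr <- make_trace(rep(1, 100),
                   tags = data.frame(sample = 50L, tag = 9L, position = 45))
  expect_error(reconstruct_position(tr, 180), "unknown tag")
  tr2 <- make_trace(rep(1, 100))
  tr2$sample_times[10] <- tr2$sample_times[8]
  expect_error(reconstruct_position(tr2, 180), "invalid input")
  tr3 <- make_trace(c(1, NA, 1))
  expect_error(reconstruct_position(tr3, 180), "invalid input")
})

test_that("position binning follows the half-open circular convention", {
  expect_identical(bin_position(0, 20, 180), 0L)
  expect_identical(bin_position(9.0, 20, 180), 1L)
  expect_identical(bin_position(179.999, 20, 180), 19L)
  expect_identical(bin_position(180, 20, 180), 0L) # exactly L wraps
  expect_error(bin_position(-0.1, 20, 180), "invalid input")
  expect_error(bin_position(180.5, 20, 180), "invalid input")
  expect_error(bin_position(10, 1, 180), "invalid input")
  # uniform grid: occupancy equal within one frame
  pos <- seq(0, 180 - 1e-9, length.out = 2000)
  occ <- tabulate(bin_position(pos, 20, 180) + 1L, 20)
  expect_lte(diff(range(occ)), 1)
  # idempotent under re-binning with the same n
  b <- bin_position(pos, 20, 180)
  centers <- (b + 0.5) * 9
  expect_identical(bin_position(centers, 20, 180), b)
})

test_that("dF/F recipe recovers constants, steps, and simulator ground truth", {
  # constant F = F0: dF/F identically 0 (10th-percentile baseline = F)
  expect_equal(compute_dff(rep(100, 1500), frame_rate = 15),
               rep(0, 1500), ignore_attr = TRUE)
  # step to 2 F0 within a long window reads ~1
  f <- rep(100, 1500); f[700:800] <- 200
  d <- compute_dff(f, frame_rate = 15)
  expect_equal(mean(d[720:780]), 1, tolerance = 1e-6)
  # round trip through the simulator's raw fluorescence
  cfg <- synthetic_config(n_neurons = 10, n_laps = 10, seed = 5, noise_sd = 0.01)
  s <- simulate_session(cfg)$session
  dffe <- compute_dff(s$raw_f, frame_rate = s$frame_rate)
  expect_lt(sqrt(mean((dffe - s$dff)^2)), 0.02)
  # all-zero trace: flagged, not an error
  expect_warning(z <- compute_dff(rbind(rep(0, 1500), f), frame_rate = 15),
                 "all-zero")
  expect_true(attr(z, "degenerate")[1])
  expect_false(attr(z, "degenerate")[2])
  expect_true(all(z[1, ] == 0))
})

test_that("session containers round-trip losslessly and fail loudly", {
  s <- fx_session()
  path <- withr::local_tempfile(fileext = ".dgs")
  write_session(s, path)
  s2 <- read_session(path)
  expect_identical(s2$dff, s$dff) # bit-exact
  expect_identical(s2$position, s$position)
  expect_identical(s2$lap_index, s$lap_index)
  expect_identical(s2$frame_times, s$frame_times)
  expect_equal(unclass(s2), unclass(s), ignore_attr = TRUE)

  # optional rates may be absent
  expect_null(s$rates)
  expect_null(s2$rates)

  # corrupt container: format error, not silent NaNs
  bad <- withr::local_tempfile(fileext = ".dgs")
  writeLines("not a container", bad)
  expect_error(read_session(bad), "format error")
  # schema-version mismatch
  old <- withr::local_tempfile(fileext = ".dgs")
  saveRDS(list(schema = "dg-session-v0", fields = list()), old)
  expect_error(read_session(old), "schema-version mismatch")
})

test_that("sessions can be assembled from extraction-tool trace matrices", {
  s <- fx_session()
  s3 <- session_from_traces(
    s$raw_f, s$frame_times, s$position, s$lap_index,
    s$belt_length, s$frame_rate,
    metadata = list(subject = "m1")
  )
  expect_s3_class(s3, "dg_session")
  expect_equal(dim(s3$dff), dim(s$dff))
  expect_equal(s3$metadata$subject, "m1")
})
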