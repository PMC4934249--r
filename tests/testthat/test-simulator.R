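test_that("zero strides gives a pure-stance recording", {
  sim <- simulate_walk(n_strides = 0, seed = 1)
  expect_equal(sim$truth$stride_count, 0)
  expect_equal(sim$truth$total_distance, 0)
  expect_true(all(sim$recording$pressure > 1))
  expect_equal(nrow(sim$truth$swing_intervals), 0L)
})

test_that("a fixed seed reproduces the recording bit-for-bit", {
  a <- simulate_walk(n_strides = 8, seed = 99)
  b <- simulate_walk(n_strides = 8, seed = 99)
  expect_identical(a$recording$ax, b$recording$ax)
  expect_identical(a$recording$pressure, b$recording$pressure)
  expect_identical(a$truth, b$truth)
  c <- simulate_walk(n_strides = 8, seed = 100)
  expect_false(identical(a$recording$ax, c$recording$ax))
})

test_that("pressure words are valid by phase", {
  sim <- simulate_walk(n_strides = 10, pressure_glitch_prob = 0.5, seed = 3)
  rec <- sim$recording
  truth <- sim$truth$swing_intervals
  in_swing <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(truth))) {
    in_swing <- in_swing |
      (rec$t >= truth$start_time[i] - 1e-9 & rec$t < truth$stop_time[i] - 1e-9)
  }
  # stance words always exceed the threshold
  expect_true(all(rec$pressure[!in_swing] > 1))
  # swing words are 0 except Sensor-8 glitches, which are exactly 1
  expect_true(all(rec$pressure[in_swing] %in% c(0L, 1L)))
  expect_gt(sum(rec$pressure[in_swing] == 1L), 0)
  # glitch-free swing is all-zero
  clean <- simulate_walk(n_strides = 10, pressure_glitch_prob = 0, seed = 3)
  expect_true(all(clean$recording$pressure %in%
                    c(0L, unique(rec$pressure[!in_swing]))))
})

test_that("default gait parameters produce realistic walking speeds", {
  for (seed in 1:5) {
    sim <- simulate_walk(n_strides = 20, seed = seed)
    duration <- nrow(sim$recording) / 50
    speed <- sim$truth$total_distance / duration
    expect_gte(speed, 1.0)
    expect_lte(speed, 1.6)
  }
})

test_that("pipeline quadrature on the clean trajectory recovers displacement", {
  # gravity- and noise-free signals are the exact second differences of the
  # foot trajectory, so the forward double sum telescopes to the stride
  # length and the vertical double sum to zero net displacement
  sim <- simulate_walk(n_strides = 5, accel_noise_sd = 0,
                       pressure_glitch_prob = 0, gravity = c(0, 0, 0),
                       stride_jitter = 0, seed = 7)
  rec <- sim$recording |> swing_mask()
  segs <- stride_segments(rec)
  for (i in seq_len(nrow(segs))) {
    ints <- integrate_stride(rec, segs[i, ])
    # forward displacement: feed ax through the oracle's single-axis channel
    m <- segs$n_samples[i]
    dx <- oracle_double_sums(rep(0, m), rep(0, m),
                             rec$ax[segs$start_idx[i]:segs$end_idx[i]],
                             1 / 50)$d_z
    expect_equal(dx, sim$truth$stride_lengths[i], tolerance = 1e-9)
    expect_equal(ints$d_z, 0, tolerance = 1e-9)
  }
})

test_that("ground-truth ratios equal the noiseless pipeline measurement", {
  sim <- simulate_walk(n_strides = 10, accel_noise_sd = 0,
                       pressure_glitch_prob = 0, seed = 12)
  est <- estimate_walk(sim$recording,
                       gait_params(K = 1, bandpass_enabled = FALSE))
  expect_equal(tidy(est)$ratio, sim$truth$per_stride_ratio, tolerance = 1e-9)
})

test_that("simulated databases are labelled and reproducible", {
  db <- simulate_database(4, 16, seed = 8)
  expect_equal(nrow(db), 4L)
  expect_true(all(db$reference_distance == 16))
  # nominal stride length is adjusted so the clean total hits the reference
  expect_equal(vapply(db$truth, function(tr) tr$stride_count, numeric(1)),
               rep(12, 4))
  db2 <- simulate_database(4, 16, seed = 8)
  expect_identical(db$recording[[1]]$ax, db2$recording[[1]]$ax)
  long <- simulate_database(2, 89, seed = 8)
  expect_true(all(long$reference_distance == 89))
  expect_equal(long$truth[[1]]$stride_count, 68)
})

test_that("invalid specs are rejected", {
  expect_error(simulate_walk(-1), "n_strides")
  expect_error(simulate_walk(5, swing_duration = 0), "durations")
  expect_error(simulate_walk(5, pressure_glitch_prob = 2), "\\[0, 1\\]")
})
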