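test_that("swing gating is element-wise multiplication by the mask", {
  df <- make_series(c(5, 2, 3, 7), swing = c(0L, 1L, 1L, 0L))
  gated <- mask_acceleration(df)
  expect_equal(gated$ax, c(0, 2, 3, 0))
  # identity and annihilator masks
  expect_equal(mask_acceleration(make_series(1:4, swing = 1L))$ax, 1:4)
  expect_equal(mask_acceleration(make_series(1:4, swing = 0L))$ax, rep(0, 4))
  # matches the loop oracle on random inputs
  set.seed(5)
  for (case in 1:20) {
    a <- rnorm(50)
    f <- sample(0:1, 50, replace = TRUE)
    expect_equal(mask_acceleration(make_series(a, swing = f))$ax,
                 oracle_mask(a, f))
  }
  expect_error(mask_acceleration(make_series(1:4)[, c("t", "ax")]),
               "swing_mask")
})

test_that("rectangular double integration reproduces hand-computed sums", {
  # constant magnitude 2 m/s^2 over 50 samples at 50 Hz:
  # vMAG[k] = 0.04 k, dMAG = sum(0.04 k * 0.02) = 1.02 m
  df <- make_series(rep(2, 50))
  out <- integrate_stride(df, one_segment(1, 50), fs = 50)
  expect_equal(out$d_mag, 1.02, tolerance = 1e-12)
  expect_true(out$flagged)  # az = 0 -> |dz| below epsilon

  # all-zero acceleration: everything zero, flagged
  zero <- integrate_stride(make_series(rep(0, 30)), one_segment(1, 30), fs = 50)
  expect_equal(zero$d_mag, 0)
  expect_equal(zero$d_z, 0)
  expect_true(zero$flagged)
})

test_that("double sums match the loop oracle to 1e-12 relative", {
  set.seed(21)
  for (case in 1:100) {
    n <- sample(5:100, 1)
    fs <- sample(c(25, 50, 100), 1)
    ax <- rnorm(n, 0, 3); ay <- rnorm(n, 0, 3); az <- rnorm(n, 0, 3)
    df <- tibble::tibble(t = (seq_len(n) - 1) / fs, ax = ax, ay = ay, az = az)
    out <- integrate_stride(df, one_segment(1, n), fs = fs,
                            dz_epsilon = 1e-300)
    ref <- oracle_double_sums(ax, ay, az, 1 / fs)
    expect_equal(out$d_mag, ref$d_mag, tolerance = 1e-12)
    expect_equal(out$d_z, ref$d_z, tolerance = 1e-12)
  }
})

test_that("half-sine lift-and-land vertical profile matches direct summation", {
  n <- 40; fs <- 50
  az <- 0.8 * sin(pi * (0:(n - 1)) / (n - 1)) - 0.3
  df <- make_series(rep(0, n), az = az)
  out <- integrate_stride(df, one_segment(1, n), fs = fs)
  ref <- oracle_double_sums(rep(0, n), rep(0, n), az, 1 / fs)
  expect_equal(out$d_z, ref$d_z, tolerance = 1e-12)
  expect_equal(out$ratio, out$d_mag / abs(out$d_z), tolerance = 1e-12)
})

test_that("per-stride update follows d[n] = d[n-1] + K ratio + L0", {
  # craft ratio = 2: a_mag = 2|az| via ax = sqrt(3) az
  n <- 25
  az <- rep(0.4, n)
  df <- make_series(sqrt(3) * az, az = az)
  seg <- one_segment(1, n)
  ints <- integrate_stride(df, seg, fs = 50)
  expect_equal(ints$ratio, 2, tolerance = 1e-12)
  est <- estimate_distance(df, segments = seg, K = 1, L0 = 0.26, fs = 50)
  expect_equal(est$total_distance, 1 * 2 + 0.26, tolerance = 1e-12)
  expect_equal(est$stride_count, 1L)
})

test_that("recursive cumulative distance equals the closed batch form", {
  sim <- simulate_walk(n_strides = 12, seed = 31)
  pre <- sim$recording |> separate_gravity() |> swing_mask() |>
    mask_acceleration()
  est <- estimate_distance(pre, K = 0.02, L0 = 0.26)
  td <- tidy(est)
  # independent recursion over the per-stride ratios
  d <- 0
  for (r in td$ratio) d <- d + 0.02 * r + 0.26
  expect_equal(est$total_distance, d, tolerance = 1e-12)
  expect_equal(est$total_distance,
               0.02 * sum(td$ratio) + nrow(td) * 0.26, tolerance = 1e-12)
  # cumulative distance is non-decreasing
  expect_true(all(diff(td$distance) > 0))
})

test_that("distance grows strictly with K and with L0", {
  sim <- simulate_walk(n_strides = 6, seed = 13)
  pre <- sim$recording |> separate_gravity() |> swing_mask() |>
    mask_acceleration()
  base <- estimate_distance(pre, K = 0.02, L0 = 0.26)$total_distance
  expect_gt(estimate_distance(pre, K = 0.03, L0 = 0.26)$total_distance, base)
  expect_gt(estimate_distance(pre, K = 0.02, L0 = 0.30)$total_distance, base)
})

test_that("the estimator is invariant to a common acceleration scale", {
  sim <- simulate_walk(n_strides = 6, accel_noise_sd = 0, seed = 17)
  pre <- sim$recording |> separate_gravity(init = "zero") |> swing_mask() |>
    mask_acceleration()
  scaled <- pre
  for (axis in c("ax", "ay", "az")) scaled[[axis]] <- 3.7 * scaled[[axis]]
  e1 <- estimate_distance(pre, K = 0.02)
  e2 <- estimate_distance(scaled, K = 0.02)
  expect_equal(tidy(e2)$d_mag, 3.7 * tidy(e1)$d_mag, tolerance = 1e-12)
  expect_equal(tidy(e2)$ratio, tidy(e1)$ratio, tolerance = 1e-12)
  expect_equal(e2$total_distance, e1$total_distance, tolerance = 1e-12)
})

test_that("stance samples contribute nothing to the integrals", {
  sim <- simulate_walk(n_strides = 5, seed = 23)
  pre <- sim$recording |> separate_gravity() |> swing_mask()
  gated <- mask_acceleration(pre)
  # corrupt the stance samples wildly; the gated estimate must not move
  corrupted <- pre
  stance <- corrupted$swing == 0L
  corrupted$ax[stance] <- 1e6
  corrupted$az[stance] <- -1e6
  gated2 <- mask_acceleration(corrupted)
  e1 <- estimate_distance(gated, K = 0.02)
  e2 <- estimate_distance(gated2, K = 0.02)
  expect_equal(e2$total_distance, e1$total_distance, tolerance = 1e-12)
})

test_that("flagged strides fall back to the median unflagged ratio", {
  n <- 25
  az <- rep(0.4, n)
  good <- make_series(sqrt(3) * az, az = az)       # ratio 2
  bad <- make_series(rep(1, n), az = rep(0, n))    # dz = 0 -> flagged
  df <- dplyr::bind_rows(good, bad, good)
  df$t <- (seq_len(nrow(df)) - 1) / 50
  segs <- tibble::tibble(start_idx = c(1L, n + 1L, 2L * n + 1L),
                         end_idx = c(n, 2L * n, 3L * n))
  est <- estimate_distance(df, segments = segs, K = 1, L0 = 0, fs = 50)
  td <- tidy(est)
  expect_identical(td$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(td$stride_distance[2], 2, tolerance = 1e-12)
  expect_equal(est$total_distance, 6, tolerance = 1e-12)
})

test_that("degenerate inputs raise the documented errors", {
  df <- make_series(rep(0, 20), swing = 0L)
  expect_error(estimate_distance(df, K = 1, fs = 50), "no strides detected")
  allflag <- make_series(rep(1, 20), az = rep(0, 20))
  expect_error(estimate_distance(allflag, segments = one_segment(1, 20),
                                 K = 1, fs = 50),
               "degenerate vertical displacement")
  expect_error(estimate_distance(allflag, segments = one_segment(1, 20),
                                 K = -1, fs = 50), "K")
  expect_error(integrate_stride(make_series(1:5), one_segment(3, 2)), "empty")
  expect_error(integrate_stride(make_series(1:5), one_segment(1, 99)),
               "bounds")
})
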