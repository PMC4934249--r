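# Independent plain-loop oracles and tiny fixture builders.

# gravity EWMA recurrence, one axis, literal loop
oracle_gravity <- function(raw, alpha, g0 = 0) {
  g <- numeric(length(raw))
  prev <- g0
  for (t in seq_along(raw)) {
    prev <- alpha * prev + (1 - alpha) * raw[t]
    g[t] <- prev
  }
  list(g = g, linear = raw - g)
}

# rectangular double sums with velocity reset at window start, literal loop
oracle_double_sums <- function(ax, ay, az, dt) {
  v_mag <- 0; d_mag <- 0; v_z <- 0; d_z <- 0
  for (k in seq_along(ax)) {
    v_mag <- v_mag + sqrt(ax[k]^2 + ay[k]^2 + az[k]^2) * dt
    d_mag <- d_mag + v_mag * dt
    v_z <- v_z + az[k] * dt
    d_z <- d_z + v_z * dt
  }
  list(d_mag = d_mag, d_z = d_z)
}

# element-wise swing gating, literal loop
oracle_mask <- function(a, f) {
  out <- numeric(length(a))
  for (k in seq_along(a)) out[k] <- if (f[k] == 1) a[k] else 0
  out
}

# recording with given pressure words (accel defaults to rest + gravity on z)
make_rec <- function(pressure, fs = 50, ax = 0, ay = 0, az = 9.81) {
  n <- length(pressure)
  insole_recording(
    tibble::tibble(t = (seq_len(n) - 1) / fs,
                   ax = rep_len(ax, n), ay = rep_len(ay, n),
                   az = rep_len(az, n), pressure = pressure),
    fs = fs
  )
}

# bare series + swing column for segment-level tests (skips recording checks)
make_series <- function(ax, ay = 0, az = 0, swing = 1, fs = 50) {
  n <- length(ax)
  tibble::tibble(t = (seq_len(n) - 1) / fs,
                 ax = ax, ay = rep_len(ay, n), az = rep_len(az, n),
                 swing = rep_len(swing, n))
}

one_segment <- function(start_idx, end_idx) {
  tibble::tibble(start_idx = start_idx, end_idx = end_idx)
}
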