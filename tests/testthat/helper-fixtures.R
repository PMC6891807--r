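# Shared fixtures: random rotations, circular comparison, tiny streams.

random_unit_quat <- function(n = 1L) {
  q <- matrix(stats::rnorm(4 * n), n, 4L)
  q / sqrt(rowSums(q^2))
}

# Absolute angular difference wrapped to [0, 180] degrees.
circ_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}

# Largest absolute difference between two 4x4 transforms.
transform_diff <- function(A, B) max(abs(A - B))

# A small constant-orientation stream for calibration tests.
constant_stream <- function(q, n = 10L, rate = 100) {
  qm <- matrix(rep(q, each = n), n, 4L)
  sensor_stream((0:(n - 1)) / rate, qm, qm, rate = rate)
}

# Simulated noiseless recording plus its matched angle recovery.
noiseless_sim <- function(...) {
  p <- gait_model_params(noise_std = 0, drift_rate = 0, ...)
  sim <- simulate_gait(p)
  ja <- joint_angles(sim$stream, n_init = p$n_calib, quiet = TRUE)
  list(p = p, sim = sim, ja = ja)
}
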