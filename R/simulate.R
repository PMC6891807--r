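# Synthetic two-sensor gait generator. Each joint angle follows a single
# cosine at the gait frequency (optionally with harmonics), the forward
# kinematic chain turns the six angles into the two sensor orientations, and
# an IMU noise model (white angle noise, random-walk drift, constant offset,
# mounting rotations) perturbs the emitted quaternions. Because every
# parameter is known, the whole analysis pipeline is testable by parameter
# recovery.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  ifelse(y == -180, 180, y)
}

#' Parameters of the synthetic gait model
#'
#' One cosine per joint angle, `theta_j(t) = mean_j + amp_j *
#' cos(2 pi f t - psi_j)`, preceded by a short hold at the aligned pose
#' (all angles zero) that plays the role of the calibration posture. The
#' defaults describe an adult walking normally: gait frequency 1/1.3 Hz,
#' hip flexion swinging 30 +/- 20 degrees, knee flexion 35 +/- 25 degrees,
#' small frontal/transverse excursions, and knee phase offsets shaped to
#' the normal coordination pattern. Noise defaults reflect a consumer IMU
#' after onboard fusion: 0.2 degrees white orientation noise per sample and
#' 5 degrees/hour drift.
#'
#' @param f Gait cycle frequency in Hz.
#' @param duration Trajectory duration in seconds (excluding the hold).
#' @param rate Sampling rate in Hz.
#' @param mean,amp,psi Length-6 vectors: per-joint mean, amplitude and phase
#'   offset, degrees. Order: theta1 (hip transverse), theta2 (hip sagittal),
#'   theta3 (hip frontal), theta4 (knee transverse), theta5 (knee sagittal),
#'   theta6 (knee frontal).
#' @param noise_std White orientation-noise standard deviation per sample,
#'   degrees.
#' @param drift_rate Expected random-walk drift magnitude, degrees per hour.
#' @param offset_A,offset_B Constant orientation bias per sensor, degrees
#'   (about a seeded fixed axis).
#' @param mount_A,mount_B Fixed mounting rotations, unit quaternions
#'   `(w, x, y, z)` or `NULL` for identity.
#' @param mount_side `"right"` (default) post-multiplies the mounting
#'   rotation (a sensor-frame offset, which the initial-pose calibration
#'   removes); `"left"` pre-multiplies (a world-frame offset, which it does
#'   not).
#' @param n_calib Number of leading aligned-pose hold samples (default 50,
#'   i.e. a 0.5 s hold at the default rate). Averaging the hold when
#'   calibrating (`n_init = n_calib`) suppresses the sensor noise that a
#'   single-sample reference would freeze into a constant misalignment.
#' @param harmonics Optional list of extra harmonic terms, each
#'   `list(joint =, k =, amp =, psi =)` adding
#'   `amp * cos(2 pi k f t - psi)` to that joint.
#' @param seed RNG seed for the noise model (`NULL`: use the current RNG
#'   state).
#' @return Validated list of class `gait_model_params`.
#' @export
gait_model_params <- function(f = 1 / 1.3, duration = 30, rate = 100,
                              mean = c(0, 30, 0, 0, 35, 0),
                              amp = c(5, 20, 8, 5, 25, 8),
                              psi = c(0, 0, 0, -155.63, 101.41, 91.70),
                              noise_std = 0.2, drift_rate = 5,
                              offset_A = 0, offset_B = 0,
                              mount_A = NULL, mount_B = NULL,
                              mount_side = c("right", "left"),
                              n_calib = 50L, harmonics = NULL, seed = NULL) {
  mount_side <- match.arg(mount_side)
  stopifnot(length(mean) == 6L, length(amp) == 6L, length(psi) == 6L)
  if (f <= 0 || duration <= 0 || rate <= 0) stop("f, duration, rate must be positive")
  if (rate < 10 * f) stop("sampling rate must be at least 10x the gait frequency")
  if (duration < 3 / f) stop("duration must cover at least 3 gait cycles")
  if (any(amp < 0)) stop("amplitudes must be nonnegative")
  for (j in c(2L, 5L)) {
    if (mean[j] < 20 || mean[j] > 160)
      stop(sprintf("mean of theta%d must lie in [20, 160] degrees to stay off the IK singularity", j))
    if (amp[j] >= min(mean[j] - 5, 175 - mean[j]))
      stop(sprintf("amplitude of theta%d too large: theta%d would approach the IK singularity", j, j))
  }
  if (noise_std < 0 || drift_rate < 0) stop("noise parameters must be nonnegative")
  if (!is.null(mount_A)) mount_A <- quat_normalize(mount_A)
  if (!is.null(mount_B)) mount_B <- quat_normalize(mount_B)
  structure(list(f = f, duration = duration, rate = rate, mean = mean,
                 amp = amp, psi = psi, noise_std = noise_std,
                 drift_rate = drift_rate, offset_A = offset_A,
                 offset_B = offset_B, mount_A = mount_A, mount_B = mount_B,
                 mount_side = mount_side, n_calib = as.integer(n_calib),
                 harmonics = harmonics, seed = seed),
            class = "gait_model_params")
}

#' Preset gait models
#'
#' Two prototype parameterizations: `"normal"` walking at a 1.3 s cycle
#' (0.77 Hz) with the knee trailing the hip sagittal oscillation by about
#' 100 degrees of cycle, and `"hemiplegic"` walking at a 1.8 s cycle
#' (0.56 Hz) with reduced knee amplitudes (stiff knee) and negative hip-knee
#' phase differences. The preset phase offsets are prototypes shaped to the
#' mean phase-difference angles of the two patterns; the amplitudes are
#' plausible but not claimed to be clinically representative. The normal
#' transverse offset is stored as its wrapped equivalent (-155.63 for a
#' 204.37-degree cycle fraction) since phase is defined modulo one cycle.
#'
#' @param name `"normal"` or `"hemiplegic"`.
#' @param ... Overrides passed to [gait_model_params()].
#' @return A `gait_model_params` object.
#' @export
gait_preset <- function(name = c("normal", "hemiplegic"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    normal = list(f = 1 / 1.3,
                  mean = c(0, 30, 0, 0, 35, 0),
                  amp = c(5, 20, 8, 5, 25, 8),
                  psi = c(0, 0, 0, -155.63, 101.41, 91.70)),
    hemiplegic = list(f = 1 / 1.8,
                      mean = c(0, 25, 0, 0, 30, 0),
                      amp = c(4, 12, 5, 3, 8, 5),
                      psi = c(0, 0, 0, -10.26, -62.61, -27.22))
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(gait_model_params, args)
}

#' Generate ground-truth joint-angle trajectories
#'
#' Samples the cosine gait model on a uniform time grid, prepending
#' `n_calib` aligned-pose hold samples (all angles zero) that stand for the
#' calibration posture. The injected hip-knee phase offsets per plane pair
#' (knee psi minus hip-sagittal psi, wrapped to `(-180, 180]`) are recorded
#' as the recovery targets for the phase module.
#'
#' @param p A [gait_model_params()] object.
#' @return Object of class `gait_truth`: list with `t`, `theta` (n x 6,
#'   degrees), `psi_pairs` (named: sagittal, frontal, transverse),
#'   `f`, `n_calib`, `params`.
#' @export
generate_trajectories <- function(p) {
  stopifnot(inherits(p, "gait_model_params"))
  n_traj <- round(p$duration * p$rate)
  n <- p$n_calib + n_traj
  t <- (seq_len(n) - 1L) / p$rate
  t0 <- p$n_calib / p$rate
  theta <- matrix(0, n, 6L, dimnames = list(NULL, paste0("theta", 1:6)))
  gait <- (p$n_calib + 1L):n
  tau <- t[gait] - t0
  for (j in 1:6)
    theta[gait, j] <- p$mean[j] + p$amp[j] * cos(2 * pi * p$f * tau - deg2rad(p$psi[j]))
  if (!is.null(p$harmonics)) {
    for (h in p$harmonics) {
      theta[gait, h$joint] <- theta[gait, h$joint] +
        h$amp * cos(2 * pi * h$k * p$f * tau - deg2rad(h$psi))
    }
  }
  psi_pairs <- c(sagittal = wrap180(p$psi[5] - p$psi[2]),
                 frontal = wrap180(p$psi[6] - p$psi[2]),
                 transverse = wrap180(p$psi[4] - p$psi[2]))
  structure(list(t = t, theta = theta, psi_pairs = psi_pairs, f = p$f,
                 n_calib = p$n_calib, params = p),
            class = "gait_truth")
}

#' Ground truth as a joint-angle series
#'
#' @param gt A `gait_truth` object.
#' @return The noiseless injected angles as a `joint_angle_series`.
#' @export
truth_series <- function(gt) {
  stopifnot(inherits(gt, "gait_truth"))
  out <- joint_angle_series(gt$t, gt$theta, rate = gt$params$rate)
  attr(out, "singular") <- seq_along(gt$t) <= gt$n_calib
  out
}

#' Forward-compose ground-truth angles into a sensor stream
#'
#' Runs the kinematic chain forward: the hip triad gives the thigh sensor
#' orientation, the hip and knee triads composed give the shin sensor
#' orientation, both converted to unit quaternions; mounting rotations are
#' applied on the configured side. The emitted stream is noiseless; apply
#' [add_imu_noise()] for the full sensor model.
#'
#' @param gt A `gait_truth` object.
#' @param p Parameters; defaults to `gt$params`.
#' @return A [sensor_stream()].
#' @export
forward_compose <- function(gt, p = gt$params) {
  stopifnot(inherits(gt, "gait_truth"))
  th <- gt$theta
  hip <- triad_entries(th[, 1], th[, 2], th[, 3])
  knee <- triad_entries(th[, 4], th[, 5], th[, 6])
  qA <- entries_to_quat(hip$E)
  qBA <- entries_to_quat(knee$E)
  qB <- quat_multiply(qA, qBA)
  apply_mount <- function(q, mount) {
    if (is.null(mount)) return(q)
    if (p$mount_side == "right") quat_multiply(q, mount)
    else quat_multiply(mount, q)
  }
  qA <- apply_mount(qA, p$mount_A)
  qB <- apply_mount(qB, p$mount_B)
  sensor_stream(gt$t, quat_normalize(qA), quat_normalize(qB), rate = p$rate)
}

# n random small-rotation quaternions: angles (deg) about uniform random axes.
random_rotation_quats <- function(angles_deg) {
  n <- length(angles_deg)
  ax <- matrix(stats::rnorm(3 * n), n, 3L)
  nrm <- sqrt(rowSums(ax^2))
  nrm[nrm == 0] <- 1
  ax <- ax / nrm
  half <- deg2rad(angles_deg) / 2
  cbind(cos(half), sin(half) * ax[, 1], sin(half) * ax[, 2], sin(half) * ax[, 3])
}

# Rotation-vector rows (degrees) -> unit quaternions.
rotvec_to_quat <- function(V) {
  ang <- sqrt(rowSums(V^2))
  ax <- V / ifelse(ang == 0, 1, ang)
  half <- deg2rad(ang) / 2
  cbind(cos(half), sin(half) * ax[, 1], sin(half) * ax[, 2], sin(half) * ax[, 3])
}

# E[chi_3] : expected norm of a standard trivariate normal.
CHI3_MEAN <- sqrt(2) * gamma(2) / gamma(1.5)

#' Perturb a sensor stream with an IMU noise model
#'
#' Right-multiplies each sensor's orientation by small perturbation
#' rotations, independently per sensor: white Gaussian angle noise of
#' standard deviation `noise_std` degrees about random axes; a random-walk
#' drift whose step size is calibrated so the expected accumulated drift
#' magnitude at the end of the stream equals `drift_rate` degrees/hour times
#' the stream duration; and a constant offset rotation of `offset_A` /
#' `offset_B` degrees about a seeded fixed axis. Deterministic under a fixed
#' seed.
#'
#' @param stream A [sensor_stream()].
#' @param p A [gait_model_params()] (fields `noise_std`, `drift_rate`,
#'   `offset_A`, `offset_B`, `seed` are used).
#' @return A perturbed `sensor_stream`.
#' @export
add_imu_noise <- function(stream, p) {
  stopifnot(inherits(stream, "sensor_stream"), inherits(p, "gait_model_params"))
  if (p$noise_std < 0 || p$drift_rate < 0) stop("noise parameters must be nonnegative")
  if (p$noise_std == 0 && p$drift_rate == 0 && p$offset_A == 0 && p$offset_B == 0)
    return(stream)
  n <- length(stream$t)
  span <- stream$t[n] - stream$t[1]
  with_seed(p$seed, {
    perturb <- function(q, offset_deg) {
      qn <- q
      if (offset_deg != 0) {
        ax <- stats::rnorm(3)
        qn <- quat_multiply(qn, quat_from_axis_angle(ax, offset_deg))
      }
      if (p$drift_rate > 0) {
        target <- p$drift_rate * span / 3600      # expected final drift, deg
        sigma_step <- target / (CHI3_MEAN * sqrt(n))
        steps <- matrix(stats::rnorm(3 * n, sd = sigma_step), n, 3L)
        V <- apply(steps, 2L, cumsum)
        qn <- quat_multiply(qn, rotvec_to_quat(V))
      }
      if (p$noise_std > 0)
        qn <- quat_multiply(qn, random_rotation_quats(stats::rnorm(n, sd = p$noise_std)))
      quat_normalize(qn)
    }
    qA <- perturb(stream$qA, p$offset_A)
    qB <- perturb(stream$qB, p$offset_B)
    sensor_stream(stream$t, qA, qB, rate = stream$rate)
  })
}

#' Simulate a complete two-sensor gait recording
#'
#' Convenience wrapper: [generate_trajectories()], [forward_compose()],
#' then [add_imu_noise()] when any noise parameter is nonzero.
#'
#' @param p A [gait_model_params()] object.
#' @return List with `stream` (a `sensor_stream`) and `truth`
#'   (a `gait_truth`).
#' @export
simulate_gait <- function(p) {
  stopifnot(inherits(p, "gait_model_params"))
  gt <- generate_trajectories(p)
  stream <- forward_compose(gt, p)
  if (p$noise_std > 0 || p$drift_rate > 0 || p$offset_A != 0 || p$offset_B != 0)
    stream <- add_imu_noise(stream, p)
  list(stream = stream, truth = gt)
}
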