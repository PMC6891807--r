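# Two-sensor stream container, calibration, and closed-form inverse
# kinematics. The pipeline is: quaternions -> calibrated orientations
# (initial aligned pose inverted out) -> hip angles from the thigh sensor
# transform, knee angles from the shin-in-thigh relative transform.

#' Construct a paired two-sensor orientation stream
#'
#' Holds time-aligned unit-quaternion samples from the thigh sensor (A) and
#' the shin sensor (B). Quaternions are scalar-first `(w, x, y, z)` and are
#' normalized on construction; inputs whose norm deviates from 1 by more than
#' `norm_tol` are rejected.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing,
#'   length >= 2.
#' @param qA,qB `length(t) x 4` matrices of quaternions for sensors A and B.
#' @param rate Nominal sampling rate in Hz; inferred from the median time
#'   step when `NULL`.
#' @param norm_tol Largest tolerated pre-normalization deviation of a
#'   quaternion norm from 1 (default `1e-3`).
#' @return An object of class `sensor_stream`: a list with elements `t`,
#'   `qA`, `qB`, `rate`.
#' @seealso [quat_slerp_series()] to resample a sensor with different
#'   timestamps onto a common time base before pairing.
#' @export
sensor_stream <- function(t, qA, qB, rate = NULL, norm_tol = 1e-3) {
  qA <- as_quat_matrix(qA); qB <- as_quat_matrix(qB)
  if (length(t) < 2L) stop("a stream needs at least 2 paired samples")
  if (nrow(qA) != length(t) || nrow(qB) != length(t))
    stop("t, qA and qB must have matching lengths")
  if (any(!is.finite(t)) || any(!is.finite(qA)) || any(!is.finite(qB)))
    stop("non-finite values in stream")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  qA <- quat_normalize(qA, tol = norm_tol)
  qB <- quat_normalize(qB, tol = norm_tol)
  dimnames(qA) <- dimnames(qB) <- NULL
  if (is.null(rate)) rate <- 1 / stats::median(diff(t))
  structure(list(t = as.numeric(t), qA = qA, qB = qB, rate = rate),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d paired samples, %.3f-%.3f s, rate %.6g Hz\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$rate))
  invisible(x)
}

#' @export
length.sensor_stream <- function(x) length(x$t)

#' Calibrate a sensor stream against its initial aligned pose
#'
#' For each sensor the reference orientation is the (sign-aligned,
#' normalized) component mean of the first `n_init` samples, recorded while
#' the leg is held in the aligned initial pose. Each sample is then
#' right-multiplied by the inverse of the reference, so the calibrated
#' transform at the reference pose is identity. Right-multiplication removes
#' the initial pose itself; `side = "left"` removes a world-frame offset
#' instead and is provided as an alternative convention.
#'
#' @param stream A [sensor_stream()].
#' @param n_init Number of leading samples that define the reference pose
#'   (default 1).
#' @param side `"right"` (default) applies `T(t) %*% solve(T_ref)`;
#'   `"left"` applies `solve(T_ref) %*% T(t)`.
#' @return A calibrated `sensor_stream` with attributes `ref_A`, `ref_B`
#'   (the reference quaternions that were inverted out).
#' @export
calibrate_stream <- function(stream, n_init = 1L, side = c("right", "left")) {
  stopifnot(inherits(stream, "sensor_stream"))
  side <- match.arg(side)
  n <- length(stream$t)
  if (n_init < 1L || n_init > n)
    stop(sprintf("n_init must be in [1, %d], got %s", n, format(n_init)))
  ref_A <- quat_mean(stream$qA, n_init)
  ref_B <- quat_mean(stream$qB, n_init)
  if (side == "right") {
    qA <- quat_multiply(stream$qA, quat_conjugate(ref_A))
    qB <- quat_multiply(stream$qB, quat_conjugate(ref_B))
  } else {
    qA <- quat_multiply(quat_conjugate(ref_A), stream$qA)
    qB <- quat_multiply(quat_conjugate(ref_B), stream$qB)
  }
  out <- stream
  out$qA <- quat_normalize(qA)
  out$qB <- quat_normalize(qB)
  dimnames(out$qA) <- dimnames(out$qB) <- NULL
  attr(out, "ref_A") <- ref_A
  attr(out, "ref_B") <- ref_B
  attr(out, "n_init") <- as.integer(n_init)
  attr(out, "side") <- side
  out
}

# Vectorised inverse kinematics of the three-angle triad from rotation
# entries (n x 9, columns r11..r33). Returns n x 3 angles in degrees plus a
# logical singular-sample flag. policy "zero": at |sin t2| < eps report
# t2 = 0 or 180, t3 = 0 and t1 = atan2(r21, r11) (the combined z rotation);
# "hold" additionally carries the previous non-singular t1, t3 forward.
ik_triad <- function(E, mode = c("atan2", "acos"), eps = 1e-6,
                     singular_policy = c("zero", "hold")) {
  mode <- match.arg(mode)
  singular_policy <- match.arg(singular_policy)
  r11 <- E[, "r11"]; r13 <- E[, "r13"]; r21 <- E[, "r21"]; r23 <- E[, "r23"]
  r31 <- E[, "r31"]; r32 <- E[, "r32"]; r33 <- E[, "r33"]
  clamp <- function(x) pmin(1, pmax(-1, x))
  s2 <- sqrt(pmax(0, r31^2 + r32^2))          # |sin(theta2)|
  singular <- s2 < eps
  if (mode == "atan2") {
    t2 <- atan2(s2, r33)
    t3 <- atan2(r32, -r31)
    t1 <- atan2(r23, r13)
  } else {
    t2 <- acos(clamp(r33))
    sin2 <- sin(t2)
    sin2[singular] <- 1                        # placeholder; overwritten below
    t3 <- acos(clamp(-r31 / sin2))
    t1 <- acos(clamp(r13 / sin2))
  }
  if (any(singular)) {
    t2[singular] <- ifelse(r33[singular] >= 0, 0, pi)
    t1[singular] <- atan2(r21[singular], r11[singular])
    t3[singular] <- 0
    if (singular_policy == "hold") {
      idx <- seq_along(singular)
      last_ok <- cummax(ifelse(singular, 0L, idx))
      carry <- which(singular & last_ok > 0L)
      t1[carry] <- t1[last_ok[carry]]
      t3[carry] <- t3[last_ok[carry]]
    }
  }
  list(theta = cbind(rad2deg(t1), rad2deg(t2), rad2deg(t3)),
       singular = singular)
}

transform_to_entries <- function(M) {
  M <- as.matrix(M)
  if (all(dim(M) == c(4L, 4L))) M <- M[1:3, 1:3]
  if (!all(dim(M) == c(3L, 3L))) stop("expected a 3x3 or 4x4 matrix")
  matrix(as.numeric(t(M)), 1L, 9L,
         dimnames = list(NULL, c("r11", "r12", "r13", "r21", "r22", "r23",
                                 "r31", "r32", "r33")))
}

#' Hip joint angles from a thigh-sensor transform
#'
#' Closed-form inverse kinematics of the hip triad. In `acos` mode the
#' angles are `theta2 = acos(r33)`, `theta3 = acos(-r31 / sin theta2)`,
#' `theta1 = acos(r13 / sin theta2)`, all restricted to `[0, 180]` degrees.
#' The default `atan2` mode returns the same angles where both are defined
#' but additionally recovers signs:
#' `theta2 = atan2(sqrt(r31^2 + r32^2), r33)`, `theta3 = atan2(r32, -r31)`,
#' `theta1 = atan2(r23, r13)`.
#'
#' Near the chain singularity `sin(theta2) = 0` the decomposition is
#' degenerate; `theta2` is reported as 0 or 180 degrees, `theta3` as 0, and
#' `theta1` as the combined z rotation `atan2(r21, r11)` (never a
#' division-by-zero failure).
#'
#' @param T_A0 4 x 4 homogeneous transform (or 3 x 3 rotation) of the thigh
#'   sensor in the base frame.
#' @param mode `"atan2"` (sign-recovering, default) or `"acos"`
#'   (principal-range closed form).
#' @param eps Singularity threshold on `|sin(theta2)|` (default `1e-6`).
#' @return Named numeric vector `c(theta1, theta2, theta3)` in degrees, with
#'   attribute `singular` (logical).
#' @export
ik_hip <- function(T_A0, mode = c("atan2", "acos"), eps = 1e-6) {
  res <- ik_triad(transform_to_entries(T_A0), mode = match.arg(mode), eps = eps)
  out <- stats::setNames(res$theta[1L, ], c("theta1", "theta2", "theta3"))
  attr(out, "singular") <- res$singular[1L]
  out
}

#' Knee joint angles from the shin-in-thigh relative transform
#'
#' Identical closed form to [ik_hip()] applied to the relative transform
#' `T_BA` of [relative_transform()]; returns the knee triad
#' `theta4, theta5, theta6`.
#'
#' @param T_BA 4 x 4 homogeneous transform (or 3 x 3 rotation) of the shin
#'   sensor in the thigh sensor frame.
#' @inheritParams ik_hip
#' @return Named numeric vector `c(theta4, theta5, theta6)` in degrees, with
#'   attribute `singular`.
#' @export
ik_knee <- function(T_BA, mode = c("atan2", "acos"), eps = 1e-6) {
  res <- ik_triad(transform_to_entries(T_BA), mode = match.arg(mode), eps = eps)
  out <- stats::setNames(res$theta[1L, ], c("theta4", "theta5", "theta6"))
  attr(out, "singular") <- res$singular[1L]
  out
}

#' Default anatomical plane labels of the six joint angles
#'
#' Maps each joint angle to the anatomical plane of the motion it captures.
#' The polar angles of the two triads (`theta2`, `theta5`) carry the large
#' flexion/extension oscillation and are labelled sagittal; `theta3`/`theta6`
#' frontal (abduction/adduction); `theta1`/`theta4` transverse
#' (internal/external rotation). The mapping is conventional, not intrinsic
#' to the chain, and every consumer accepts an alternative.
#'
#' @return Named character vector mapping channel labels
#'   (`hip_sagittal`, ..., `knee_transverse`) to angle columns
#'   (`theta1`...`theta6`).
#' @export
default_plane_map <- function() {
  c(hip_transverse = "theta1", hip_sagittal = "theta2", hip_frontal = "theta3",
    knee_transverse = "theta4", knee_sagittal = "theta5", knee_frontal = "theta6")
}

#' Hip and knee joint-angle time series from a two-sensor stream
#'
#' Runs the full kinematic pipeline: normalize quaternions, calibrate both
#' sensors against the initial aligned pose, take hip angles from the
#' calibrated thigh transform and knee angles from the calibrated
#' shin-in-thigh relative transform, via closed-form inverse kinematics.
#' Singular samples (the calibrated initial pose is always one) are handled
#' by the singular-pose policy and counted in a message, never an error.
#'
#' @param stream A [sensor_stream()].
#' @param n_init Leading samples defining the calibration pose (default 1).
#' @param mode IK mode, `"atan2"` (default) or `"acos"`; see [ik_hip()].
#' @param singular_policy `"zero"` (default: report `theta1` as the combined
#'   rotation, `theta3 = 0`) or `"hold"` (carry the previous non-singular
#'   `theta1`, `theta3` forward).
#' @param eps Singularity threshold on `|sin(theta2)|`.
#' @param calib_side Calibration side, see [calibrate_stream()].
#' @param plane_map Named character vector mapping channel labels to angle
#'   columns; default [default_plane_map()].
#' @param quiet Suppress the singular-sample message.
#' @return A data frame of class `joint_angle_series` with columns `t`,
#'   `theta1`...`theta6` (degrees) and attributes `plane_map`, `rate`,
#'   `singular` (logical per sample).
#' @export
joint_angles <- function(stream, n_init = 1L, mode = c("atan2", "acos"),
                         singular_policy = c("zero", "hold"), eps = 1e-6,
                         calib_side = c("right", "left"),
                         plane_map = default_plane_map(), quiet = FALSE) {
  mode <- match.arg(mode)
  singular_policy <- match.arg(singular_policy)
  cal <- calibrate_stream(stream, n_init = n_init, side = match.arg(calib_side))
  E_hip <- quat_entries(cal$qA)
  q_rel <- quat_multiply(quat_conjugate(cal$qA), cal$qB)
  E_knee <- quat_entries(quat_normalize(q_rel))
  hip <- ik_triad(E_hip, mode = mode, eps = eps, singular_policy = singular_policy)
  knee <- ik_triad(E_knee, mode = mode, eps = eps, singular_policy = singular_policy)
  out <- data.frame(t = stream$t,
                    theta1 = hip$theta[, 1], theta2 = hip$theta[, 2],
                    theta3 = hip$theta[, 3],
                    theta4 = knee$theta[, 1], theta5 = knee$theta[, 2],
                    theta6 = knee$theta[, 3])
  singular <- hip$singular | knee$singular
  n_sing <- sum(singular)
  if (!quiet && n_sing > 0L)
    message(sprintf("joint_angles: %d of %d samples at/near the sin(theta2)=0 singularity; '%s' policy applied",
                    n_sing, nrow(out), singular_policy))
  structure(out,
            plane_map = plane_map,
            rate = stream$rate,
            singular = singular,
            n_init = as.integer(n_init),
            class = c("joint_angle_series", "data.frame"))
}

#' Construct a joint-angle series from raw columns
#'
#' Wraps already-computed joint angles (e.g. read back from CSV or produced
#' by the simulator) in the container the phase module consumes.
#'
#' @param t Timestamps, seconds, strictly increasing.
#' @param theta `length(t) x 6` matrix or data frame of angles in degrees
#'   (columns `theta1`...`theta6`).
#' @param plane_map See [default_plane_map()].
#' @param rate Sampling rate in Hz; inferred when `NULL`.
#' @return A `joint_angle_series` data frame.
#' @export
joint_angle_series <- function(t, theta, plane_map = default_plane_map(),
                               rate = NULL) {
  theta <- as.matrix(theta)
  if (ncol(theta) != 6L) stop("theta must have 6 columns")
  if (nrow(theta) != length(t)) stop("t and theta lengths differ")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(rate)) rate <- 1 / stats::median(diff(t))
  out <- data.frame(t = as.numeric(t))
  out[paste0("theta", 1:6)] <- as.data.frame(theta)
  structure(out, plane_map = plane_map, rate = rate,
            singular = rep(FALSE, length(t)),
            class = c("joint_angle_series", "data.frame"))
}

# Angle channel (numeric vector, degrees) of a series by channel label
# ("hip_sagittal", ...) or by explicit column name ("theta2").
series_channel <- function(series, channel) {
  pm <- attr(series, "plane_map")
  col <- if (channel %in% names(pm)) pm[[channel]] else channel
  if (!col %in% names(series))
    stop(sprintf("unknown channel '%s'", channel))
  series[[col]]
}
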