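# Quaternion algebra (scalar-first convention: w, x, y, z).
#
# Quaternions arrive from the sensors' onboard fusion; everything downstream
# needs only conversion to/from rotation matrices, Hamilton products and
# spherical interpolation. All helpers accept either a length-4 vector or an
# n x 4 matrix and are vectorised over rows.

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) {
    if (length(q) != 4L) stop("a quaternion needs 4 components (w, x, y, z)")
    q <- matrix(q, nrow = 1L)
  }
  if (ncol(q) != 4L) stop("quaternion matrix must have 4 columns (w, x, y, z)")
  storage.mode(q) <- "double"
  q
}

#' Normalize quaternions to unit norm
#'
#' @param q Length-4 numeric vector `(w, x, y, z)` or an `n x 4` matrix,
#'   one quaternion per row.
#' @param tol Largest tolerated deviation of the input norm from 1 before the
#'   input is rejected as not an orientation; set to `Inf` to normalize
#'   anything with nonzero norm.
#' @return Same shape as `q`, rows scaled to unit norm.
#' @export
quat_normalize <- function(q, tol = Inf) {
  qm <- as_quat_matrix(q)
  n <- sqrt(rowSums(qm^2))
  if (any(n == 0)) stop("zero-norm quaternion is not an orientation")
  if (any(abs(n - 1) > tol)) {
    stop(sprintf("quaternion norm deviates from 1 by more than %g (worst: %g)",
                 tol, max(abs(n - 1))))
  }
  out <- qm / n
  if (is.null(dim(q))) out[1L, ] else out
}

#' Quaternion conjugate
#'
#' For unit quaternions the conjugate is the inverse rotation.
#'
#' @inheritParams quat_normalize
#' @return Same shape as `q`.
#' @export
quat_conjugate <- function(q) {
  qm <- as_quat_matrix(q)
  qm[, 2:4] <- -qm[, 2:4]
  if (is.null(dim(q))) qm[1L, ] else qm
}

#' Hamilton product of quaternions
#'
#' Row-wise product `p * q`; either argument may be a single quaternion,
#' which is recycled against the other.
#'
#' @param p,q Length-4 vectors or `n x 4` matrices (scalar-first).
#' @return `n x 4` matrix (or length-4 vector when both inputs are vectors).
#' @export
quat_multiply <- function(p, q) {
  vec_in <- is.null(dim(p)) && is.null(dim(q))
  pm <- as_quat_matrix(p)
  qm <- as_quat_matrix(q)
  n <- max(nrow(pm), nrow(qm))
  if (nrow(pm) == 1L) pm <- pm[rep(1L, n), , drop = FALSE]
  if (nrow(qm) == 1L) qm <- qm[rep(1L, n), , drop = FALSE]
  if (nrow(pm) != nrow(qm)) stop("incompatible numbers of quaternions")
  w1 <- pm[, 1]; x1 <- pm[, 2]; y1 <- pm[, 3]; z1 <- pm[, 4]
  w2 <- qm[, 1]; x2 <- qm[, 2]; y2 <- qm[, 3]; z2 <- qm[, 4]
  out <- cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
  colnames(out) <- c("w", "x", "y", "z")
  if (vec_in) out[1L, ] else out
}

#' Quaternion from axis and angle
#'
#' @param axis Length-3 axis (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return Length-4 unit quaternion `(w, x, y, z)`.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  if (length(axis) != 3L) stop("axis must have 3 components")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) {
    if (abs(angle_deg) > 0) stop("zero axis with nonzero angle")
    return(c(w = 1, x = 0, y = 0, z = 0))
  }
  half <- angle_deg * pi / 360
  c(w = cos(half), x = sin(half) * axis[1] / nrm,
    y = sin(half) * axis[2] / nrm, z = sin(half) * axis[3] / nrm)
}

# Rotation-matrix entries for rows of a unit-quaternion matrix.
# Returns an n x 9 matrix with columns r11..r33 (row-major names).
quat_entries <- function(qm) {
  w <- qm[, 1]; x <- qm[, 2]; y <- qm[, 3]; z <- qm[, 4]
  out <- cbind(
    r11 = 1 - 2 * (y^2 + z^2), r12 = 2 * (x * y - w * z), r13 = 2 * (x * z + w * y),
    r21 = 2 * (x * y + w * z), r22 = 1 - 2 * (x^2 + z^2), r23 = 2 * (y * z - w * x),
    r31 = 2 * (x * z - w * y), r32 = 2 * (y * z + w * x), r33 = 1 - 2 * (x^2 + y^2)
  )
  out
}

#' Convert a unit quaternion to a homogeneous transform
#'
#' Standard scalar-first quaternion to rotation-matrix conversion; the
#' translation block is zero. The input is normalized first, so any nonzero
#' quaternion is accepted.
#'
#' @param q Length-4 quaternion `(w, x, y, z)`.
#' @return A 4 x 4 homogeneous transformation matrix.
#' @examples
#' quat_to_rotmat(c(1, 0, 0, 0))            # identity
#' quat_to_rotmat(c(sqrt(.5), sqrt(.5), 0, 0))  # 90 degrees about x
#' @export
quat_to_rotmat <- function(q) {
  qn <- quat_normalize(q)
  e <- quat_entries(matrix(qn, nrow = 1L))[1L, ]
  M <- diag(4)
  M[1:3, 1:3] <- matrix(e, 3L, 3L, byrow = TRUE)
  M
}

# Vectorised rotation entries -> unit quaternions (Shepperd's branch method).
# E: n x 9 matrix with columns r11..r33. Returns n x 4 (w, x, y, z), with
# w >= 0 (sign-fixed representative of the double cover).
entries_to_quat <- function(E) {
  r11 <- E[, "r11"]; r12 <- E[, "r12"]; r13 <- E[, "r13"]
  r21 <- E[, "r21"]; r22 <- E[, "r22"]; r23 <- E[, "r23"]
  r31 <- E[, "r31"]; r32 <- E[, "r32"]; r33 <- E[, "r33"]
  n <- nrow(E)
  q <- matrix(0, n, 4L, dimnames = list(NULL, c("w", "x", "y", "z")))
  tr <- r11 + r22 + r33
  # branch on the largest of (trace, r11, r22, r33) for numerical stability
  branch <- max.col(cbind(tr, r11, r22, r33), ties.method = "first")
  i <- branch == 1L
  if (any(i)) {
    s <- 2 * sqrt(1 + tr[i])
    q[i, ] <- cbind(s / 4, (r32[i] - r23[i]) / s, (r13[i] - r31[i]) / s,
                    (r21[i] - r12[i]) / s)
  }
  i <- branch == 2L
  if (any(i)) {
    s <- 2 * sqrt(1 + r11[i] - r22[i] - r33[i])
    q[i, ] <- cbind((r32[i] - r23[i]) / s, s / 4, (r12[i] + r21[i]) / s,
                    (r13[i] + r31[i]) / s)
  }
  i <- branch == 3L
  if (any(i)) {
    s <- 2 * sqrt(1 - r11[i] + r22[i] - r33[i])
    q[i, ] <- cbind((r13[i] - r31[i]) / s, (r12[i] + r21[i]) / s, s / 4,
                    (r23[i] + r32[i]) / s)
  }
  i <- branch == 4L
  if (any(i)) {
    s <- 2 * sqrt(1 - r11[i] - r22[i] + r33[i])
    q[i, ] <- cbind((r21[i] - r12[i]) / s, (r13[i] + r31[i]) / s,
                    (r23[i] + r32[i]) / s, s / 4)
  }
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  q / sqrt(rowSums(q^2))
}

#' Convert a rotation matrix to a unit quaternion
#'
#' @param R A 3 x 3 rotation matrix or a 4 x 4 homogeneous transform (the
#'   rotation block is used).
#' @return Length-4 unit quaternion `(w, x, y, z)` with nonnegative scalar
#'   part.
#' @export
rotmat_to_quat <- function(R) {
  R <- as.matrix(R)
  if (all(dim(R) == c(4L, 4L))) R <- R[1:3, 1:3]
  if (!all(dim(R) == c(3L, 3L))) stop("R must be 3x3 or 4x4")
  E <- matrix(as.numeric(t(R)), 1L, 9L,
              dimnames = list(NULL, c("r11", "r12", "r13", "r21", "r22",
                                      "r23", "r31", "r32", "r33")))
  entries_to_quat(E)[1L, ]
}

#' Spherical linear interpolation of a quaternion series
#'
#' Resamples an orientation series onto new timestamps by slerp between the
#' bracketing samples, taking the short arc of the double cover. Used to put
#' two sensors with unequal timestamps onto a common time base.
#'
#' @param t Numeric vector of source timestamps, strictly increasing.
#' @param q `length(t) x 4` matrix of unit quaternions.
#' @param t_out Target timestamps; must lie within `range(t)`.
#' @return `length(t_out) x 4` matrix of unit quaternions.
#' @export
quat_slerp_series <- function(t, q, t_out) {
  qm <- quat_normalize(as_quat_matrix(q))
  if (length(t) != nrow(qm)) stop("t and q lengths differ")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(t_out < t[1] | t_out > t[length(t)]))
    stop("t_out outside the source time range")
  idx <- findInterval(t_out, t, rightmost.closed = TRUE)
  idx[idx >= length(t)] <- length(t) - 1L
  q0 <- qm[idx, , drop = FALSE]
  q1 <- qm[idx + 1L, , drop = FALSE]
  u <- (t_out - t[idx]) / (t[idx + 1L] - t[idx])
  dot <- rowSums(q0 * q1)
  q1[dot < 0, ] <- -q1[dot < 0, , drop = FALSE]
  dot <- abs(dot)
  dot[dot > 1] <- 1
  omega <- acos(dot)
  s0 <- ifelse(omega < 1e-9, 1 - u, sin((1 - u) * omega) / sin(pmax(omega, 1e-12)))
  s1 <- ifelse(omega < 1e-9, u, sin(u * omega) / sin(pmax(omega, 1e-12)))
  quat_normalize(q0 * s0 + q1 * s1)
}

# Sign-aligned normalized component mean of the first n rows; the reference
# orientation for calibration. Rows are flipped onto the hemisphere of the
# first sample before averaging so the double cover cannot cancel.
quat_mean <- function(qm, n = nrow(qm)) {
  qm <- qm[seq_len(n), , drop = FALSE]
  sgn <- sign(qm %*% qm[1L, ])
  sgn[sgn == 0] <- 1
  m <- colSums(qm * as.numeric(sgn)) / n
  quat_normalize(m)
}
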