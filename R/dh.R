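# Denavit-Hartenberg model of one leg instrumented with two orientation
# sensors: thigh and shin are serial links, and the hip and knee are each
# modelled as three coincident revolute joints. The fixed parameter table
# (link twists -90, +90, 0 degrees, repeated for the two triads) makes the
# chain's composed transforms take the closed forms implemented in
# compose_hip_transform()/compose_knee_transform().

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Homogeneous transform of a single D-H link
#'
#' Computes `Rotz(theta) %*% Transz(d) %*% Transx(a) %*% Rotx(alpha)`, the
#' standard Denavit-Hartenberg product of the four elementary link
#' transformations.
#'
#' @param theta Joint angle, degrees.
#' @param d Link offset along z, length units.
#' @param a Link length along x, length units.
#' @param alpha Link twist about x, degrees.
#' @return A 4 x 4 homogeneous transformation matrix.
#' @examples
#' dh_transform(0, 0, 0, 0)          # identity
#' dh_transform(30, 0, 0, -90)       # first hip link at 30 degrees
#' @export
dh_transform <- function(theta, d = 0, a = 0, alpha = 0) {
  th <- deg2rad(theta); al <- deg2rad(alpha)
  ct <- cos(th); st <- sin(th); ca <- cos(al); sa <- sin(al)
  matrix(c(ct, -st * ca,  st * sa, a * ct,
           st,  ct * ca, -ct * sa, a * st,
           0,        sa,       ca,      d,
           0,         0,        0,      1),
         nrow = 4L, byrow = TRUE)
}

#' The fixed six-link D-H parameter table of the leg chain
#'
#' Links 1-3 are the hip joint triad ending in the thigh sensor frame, links
#' 4-6 the knee triad ending in the shin sensor frame. Only the two link
#' offsets (thigh and shin lengths `dA`, `dB`) are free; they do not affect
#' joint angles, which are orientation-only.
#'
#' @param dA Thigh link offset (length units), default 1.
#' @param dB Shin link offset (length units), default 1.
#' @return A data frame with columns `link`, `theta` (NA: the joint
#'   variables), `d`, `a`, `alpha`.
#' @export
dh_table <- function(dA = 1, dB = 1) {
  data.frame(
    link  = 1:6,
    theta = NA_real_,
    d     = c(0, 0, dA, 0, 0, dB),
    a     = 0,
    alpha = c(-90, 90, 0, -90, 90, 0)
  )
}

# Closed-form rotation entries of the three-link triad
#   Rotz(t1)Rotx(-90) . Rotz(t2)Rotx(+90) . Rotz(t3)Transz(d):
# shared by hip (t1,t2,t3) and knee (t4,t5,t6). Vectorised over angles
# (degrees). Returns list(E = n x 9 entries r11..r33, p = n x 3 translation
# direction (c1 s2, s1 s2, c2), scaled by d by the callers).
triad_entries <- function(t1, t2, t3) {
  c1 <- cos(deg2rad(t1)); s1 <- sin(deg2rad(t1))
  c2 <- cos(deg2rad(t2)); s2 <- sin(deg2rad(t2))
  c3 <- cos(deg2rad(t3)); s3 <- sin(deg2rad(t3))
  E <- cbind(
    r11 = c1 * c2 * c3 - s1 * s3, r12 = -c1 * c2 * s3 - s1 * c3, r13 = c1 * s2,
    r21 = s1 * c2 * c3 + c1 * s3, r22 = -s1 * c2 * s3 + c1 * c3, r23 = s1 * s2,
    r31 = -s2 * c3,               r32 = s2 * s3,                 r33 = c2
  )
  list(E = E, p = cbind(c1 * s2, s1 * s2, c2))
}

entries_to_transform <- function(e_row, p_row = c(0, 0, 0)) {
  M <- diag(4)
  M[1:3, 1:3] <- matrix(e_row, 3L, 3L, byrow = TRUE)
  M[1:3, 4] <- p_row
  M
}

#' Closed-form hip transform of the leg chain
#'
#' The composed transform of the hip joint triad (links 1-3), mapping the
#' thigh sensor frame into the base frame. Implemented from its closed form;
#' equal to `dh_transform` products of links 1-3 entrywise (a tested
#' invariant).
#'
#' @param theta1,theta2,theta3 Hip joint angles, degrees.
#' @param dA Thigh link offset, default 1 (does not affect orientation).
#' @return A 4 x 4 homogeneous transform; translation `dA * (c1 s2, s1 s2, c2)`.
#' @export
compose_hip_transform <- function(theta1, theta2, theta3, dA = 1) {
  tri <- triad_entries(theta1, theta2, theta3)
  entries_to_transform(tri$E[1L, ], dA * tri$p[1L, ])
}

#' Closed-form knee transform of the leg chain
#'
#' The composed transform of the knee joint triad (links 4-6), mapping the
#' shin sensor frame into the thigh sensor frame.
#'
#' @param theta4,theta5,theta6 Knee joint angles, degrees.
#' @param dB Shin link offset, default 1.
#' @return A 4 x 4 homogeneous transform.
#' @export
compose_knee_transform <- function(theta4, theta5, theta6, dB = 1) {
  tri <- triad_entries(theta4, theta5, theta6)
  entries_to_transform(tri$E[1L, ], dB * tri$p[1L, ])
}

# Inverse of a rigid transform without a linear solve.
rigid_inverse <- function(M) {
  R <- M[1:3, 1:3]
  out <- diag(4)
  out[1:3, 1:3] <- t(R)
  out[1:3, 4] <- -t(R) %*% M[1:3, 4]
  out
}

#' Relative transform between the two sensor frames
#'
#' Orientation of the shin sensor expressed in the thigh sensor frame,
#' `solve(T_A0) %*% T_B0`, with the global frame taken as identity. This is
#' the transform whose inverse kinematics yield the knee angles.
#'
#' @param T_A0 Thigh sensor transform in the base frame (4 x 4).
#' @param T_B0 Shin sensor transform in the base frame (4 x 4).
#' @return A 4 x 4 homogeneous transform `T_BA`.
#' @export
relative_transform <- function(T_A0, T_B0) {
  rigid_inverse(T_A0) %*% T_B0
}
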