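test_that("calibration maps the reference pose to identity", {
  set.seed(31)
  # constant stream at any fixed orientation calibrates to identity throughout
  q <- random_unit_quat()[1, ]
  cal <- calibrate_stream(constant_stream(q), n_init = 3L)
  for (i in 1:nrow(cal$qA)) {
    expect_equal(quat_to_rotmat(cal$qA[i, ]), diag(4), tolerance = 1e-9)
    expect_equal(quat_to_rotmat(cal$qB[i, ]), diag(4), tolerance = 1e-9)
  }
  # n_init = 1 with an identity first sample leaves the series unchanged
  qm <- rbind(c(1, 0, 0, 0), random_unit_quat(4))
  st <- sensor_stream((0:4) / 10, qm, qm)
  cal1 <- calibrate_stream(st, n_init = 1L)
  expect_equal(abs(cal1$qA), abs(st$qA), tolerance = 1e-12)
  expect_error(calibrate_stream(st, n_init = 0L), "n_init")
  expect_error(calibrate_stream(st, n_init = 99L), "n_init")
})

test_that("right-multiplying calibration removes the initial pose, not a left mount", {
  # raw series R(t) = M S(t) with S(0) = I: calibrated series is the
  # conjugation M S(t) M^-1, not S(t) -- explicit matrix-algebra oracle
  set.seed(32)
  qM <- random_unit_quat()[1, ]
  n <- 8L
  qS <- rbind(c(1, 0, 0, 0), random_unit_quat(n - 1L))
  qraw <- quat_multiply(matrix(qM, n, 4L, byrow = TRUE), qS)
  st <- sensor_stream((0:(n - 1)) / 10, qraw, qraw)
  cal <- calibrate_stream(st, n_init = 1L)
  M <- quat_to_rotmat(qM)
  for (i in 2:n) {
    expected <- M %*% quat_to_rotmat(qS[i, ]) %*% gaitphase:::rigid_inverse(M)
    expect_lt(transform_diff(quat_to_rotmat(cal$qA[i, ]), expected), 1e-9)
  }
})

test_that("inverse kinematics recovers angles from composed transforms", {
  # hand-derived entries for (0, 90, 0): r33 = 0, r31 = -1, r13 = 1
  expect_equal(unclass(ik_hip(compose_hip_transform(0, 90, 0)))[1:3],
               c(theta1 = 0, theta2 = 90, theta3 = 0), tolerance = 1e-9)
  expect_equal(unclass(ik_knee(compose_knee_transform(0, 90, 0)))[1:3],
               c(theta4 = 0, theta5 = 90, theta6 = 0), tolerance = 1e-9)
  # FK -> IK round trips with signed angles (atan2 mode)
  expect_equal(unclass(ik_hip(compose_hip_transform(30, 45, 60)))[1:3],
               c(theta1 = 30, theta2 = 45, theta3 = 60), tolerance = 1e-9)
  expect_equal(unclass(ik_knee(compose_knee_transform(15, 70, -40)))[1:3],
               c(theta4 = 15, theta5 = 70, theta6 = -40), tolerance = 1e-9)
})

test_that("FK -> IK round trip holds over the non-singular domain", {
  set.seed(33)
  n <- 1000L
  t1 <- runif(n, -180, 180); t2 <- runif(n, 5, 175); t3 <- runif(n, -180, 180)
  worst <- 0
  for (i in seq_len(n)) {
    rec <- ik_hip(compose_hip_transform(t1[i], t2[i], t3[i]))
    worst <- max(worst, circ_diff(rec, c(t1[i], t2[i], t3[i])))
  }
  expect_lt(worst, 1e-9)
})

test_that("acos and atan2 modes agree on the principal range", {
  set.seed(34)
  for (i in 1:200) {
    th <- c(runif(1, 0, 180), runif(1, 1, 179), runif(1, 0, 180))
    M <- compose_hip_transform(th[1], th[2], th[3])
    a1 <- ik_hip(M, mode = "atan2")
    a2 <- ik_hip(M, mode = "acos")
    expect_lt(max(abs(unclass(a1)[1:3] - unclass(a2)[1:3])), 1e-9)
  }
})

test_that("singular poses follow the zero policy instead of failing", {
  res <- ik_hip(diag(4))
  expect_true(attr(res, "singular"))
  expect_equal(unclass(res)[1:3], c(theta1 = 0, theta2 = 0, theta3 = 0))
  # pure z rotation at theta2 = 0: theta1 absorbs the combined rotation
  Mz <- dh_transform(25, 0, 0, 0)
  res_z <- ik_hip(Mz)
  expect_true(attr(res_z, "singular"))
  expect_equal(unname(res_z["theta1"]), 25, tolerance = 1e-9)
  expect_equal(unname(res_z["theta3"]), 0)
  # theta2 = 180 side of the singularity
  M180 <- compose_hip_transform(0, 180, 0)
  expect_equal(unname(ik_hip(M180)["theta2"]), 180, tolerance = 1e-9)
})

test_that("hold policy carries the last resolved theta1/theta3 through a singular gap", {
  th <- cbind(c(10, 20, 0, 30), c(40, 50, 0, 60), c(-15, -25, 0, -35))
  E <- gaitphase:::triad_entries(th[, 1], th[, 2], th[, 3])$E
  res <- gaitphase:::ik_triad(E, singular_policy = "hold")
  expect_equal(res$theta[3, c(1, 3)], res$theta[2, c(1, 3)], tolerance = 1e-9)
  expect_equal(res$theta[3, 2], 0)
  res0 <- gaitphase:::ik_triad(E, singular_policy = "zero")
  expect_equal(res0$theta[3, 3], 0)
})

test_that("joint_angles recovers simulated trajectories end to end", {
  ns <- noiseless_sim(seed = 35)
  rec <- as.matrix(ns$ja[paste0("theta", 1:6)])
  gait <- (ns$p$n_calib + 1L):nrow(rec)
  expect_lt(max(circ_diff(rec[gait, ], ns$sim$truth$theta[gait, ])), 1e-6)
  # constant-pose stream decomposes to the singular-policy zero angles
  q <- quat_from_axis_angle(c(0, 0, 1), 15)
  ja_const <- joint_angles(constant_stream(q, n = 20L), quiet = TRUE)
  expect_equal(max(abs(as.matrix(ja_const[paste0("theta", 1:6)]))), 0,
               tolerance = 1e-9)
})

test_that("mounting offsets on the calibrated side do not disturb recovery", {
  qmA <- quat_from_axis_angle(c(1, 0.3, -0.2), 25)
  qmB <- quat_from_axis_angle(c(-0.5, 1, 0.1), -40)
  ns <- noiseless_sim(mount_A = qmA, mount_B = qmB, mount_side = "right")
  rec <- as.matrix(ns$ja[paste0("theta", 1:6)])
  gait <- (ns$p$n_calib + 1L):nrow(rec)
  expect_lt(max(circ_diff(rec[gait, ], ns$sim$truth$theta[gait, ])), 1e-6)
  # the same mounts on the left (world-frame) side are NOT removed by the
  # right-multiplying calibration: recovery must break
  ns_l <- noiseless_sim(mount_A = qmA, mount_B = qmB, mount_side = "left")
  rec_l <- as.matrix(ns_l$ja[paste0("theta", 1:6)])
  expect_gt(max(circ_diff(rec_l[gait, ], ns_l$sim$truth$theta[gait, ])), 1)
})

test_that("stream validation rejects malformed input", {
  q <- matrix(rep(c(1, 0, 0, 0), 3), 3, 4, byrow = TRUE)
  expect_error(sensor_stream(c(0, 0.1, 0.05), q, q), "increasing")
  expect_error(sensor_stream(c(0, 0.1), q[1:2, ] * 2, q[1:2, ]), "norm")
  expect_error(sensor_stream(0, q[1, , drop = FALSE], q[1, , drop = FALSE]),
               "at least 2")
})
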