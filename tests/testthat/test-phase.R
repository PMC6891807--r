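test_that("gait frequency estimation resolves off-grid periods", {
  t <- seq(0, 30, by = 0.01)
  f1 <- estimate_gait_frequency(20 * cos(2 * pi * t / 1.3), t = t)
  expect_equal(round(f1, 2), 0.77)
  f2 <- estimate_gait_frequency(20 * cos(2 * pi * t / 1.8), t = t)
  expect_equal(round(f2, 2), 0.56)
  # a pure on-grid sinusoid is recovered essentially exactly
  f3 <- estimate_gait_frequency(sin(2 * pi * 1 * seq(0, 20, by = 0.01)),
                                t = seq(0, 20, by = 0.01))
  expect_equal(f3, 1, tolerance = 1e-4)
})

test_that("frequency estimation rejects signals without a gait rhythm", {
  t <- seq(0, 30, by = 0.01)
  set.seed(41)
  expect_error(estimate_gait_frequency(rnorm(length(t)), t = t),
               "no spectral peak")
  expect_error(estimate_gait_frequency(rep(3, length(t)), t = t), "constant")
  expect_error(estimate_gait_frequency(sin(t), t = t[1:50]), "matching")
})

test_that("normalized instantaneous signal strips offsets and drift", {
  t <- seq(0, 10, by = 0.01)
  expect_error(normalize_signal(t, rep(5, length(t))), "degenerate")
  # derivative of A sin + c is a cosine regardless of A and c
  for (A in c(1, 17)) {
    ns <- normalize_signal(t, A * sin(2 * pi * 0.8 * t) + 3)
    expect_equal(max(abs(ns$values)), 1, tolerance = 1e-12)
    expect_equal(mean(ns$values), 0, tolerance = 1e-9)
    expect_lt(max(abs(ns$values - cos(2 * pi * 0.8 * t)))[1], 0.01)
  }
  # linear drift changes nothing beyond discretization error
  base <- normalize_signal(t, 10 * sin(2 * pi * 0.8 * t))
  drift <- normalize_signal(t, 10 * sin(2 * pi * 0.8 * t) + 0.5 * t)
  expect_lt(max(abs(base$values - drift$values)), 1e-6)
})

test_that("phase diagrams trace diagonal, circle and anti-diagonal", {
  t <- seq(0, 10, by = 0.01)
  h <- normalize_signal(t, sin(2 * pi * t))
  expect_equal(phase_diagram(h, h)$hip_value, phase_diagram(h, h)$knee_value)
  k90 <- normalize_signal(t, sin(2 * pi * t + pi / 2))
  pd <- phase_diagram(h, k90)
  inner <- 50:(length(t) - 50)         # away from derivative endpoints
  expect_lt(max(abs(pd$hip_value[inner]^2 + pd$knee_value[inner]^2 - 1)), 0.01)
  k180 <- normalize_signal(t, -sin(2 * pi * t))
  pd2 <- phase_diagram(h, k180)
  expect_equal(pd2$knee_value, -pd2$hip_value, tolerance = 1e-9)
  expect_error(phase_diagram(h, normalize_signal(t[1:500], sin(t[1:500]))),
               "length")
})

test_that("time-lag estimators recover injected delays with the documented sign", {
  t <- seq(0, 20, by = 0.01)
  h <- normalize_signal(t, sin(2 * pi * t))
  expect_equal(estimate_time_lag(h, h, f = 1), 0, tolerance = 1e-9)
  # knee delayed 0.10 s -> positive lag
  k <- normalize_signal(t, sin(2 * pi * (t - 0.10)))
  expect_lt(abs(estimate_time_lag(h, k, f = 1) - 0.10), 0.01)
  expect_lt(abs(estimate_time_lag(h, k, f = 1, method = "xcorr") - 0.10), 0.01)
  # knee advanced a quarter cycle -> negative lag
  k2 <- normalize_signal(t, sin(2 * pi * (t + 0.25)))
  expect_lt(abs(estimate_time_lag(h, k2, f = 1) + 0.25), 0.01)
  expect_error(estimate_time_lag(h, k, f = 0.05), "fewer than 2 cycles")
})

test_that("analytic and xcorr lag estimators agree on monochromatic signals", {
  set.seed(42)
  t <- seq(0, 10, by = 0.01)             # 10 cycles at 1 Hz
  for (i in 1:20) {
    lag <- runif(1, -0.45, 0.45)
    h <- normalize_signal(t, sin(2 * pi * t + runif(1, 0, 2 * pi)))
    k <- normalize_signal(t, sin(2 * pi * (t - lag) + runif(1, 0, 2 * pi)))
    a <- estimate_time_lag(h, k, f = 1, method = "analytic")
    x <- estimate_time_lag(h, k, f = 1, method = "xcorr")
    d <- (a - x) %% 1
    expect_lt(min(d, 1 - d), 0.01 + 1e-9)   # within one sample interval
  }
})

test_that("phase_difference_angle is the literal 360 f dt product", {
  expect_equal(phase_difference_angle(0.9, 0), 0)
  expect_equal(phase_difference_angle(0.77, 0.36), 99.792, tolerance = 1e-12)
  expect_equal(phase_difference_angle(0.5, -0.5), -90)
  expect_error(phase_difference_angle(0, 0.1), "positive")
})

test_that("phase profiles recover injected per-plane offsets", {
  psi_knee <- c(-35, 100, 60)            # theta4, theta5, theta6
  ns <- noiseless_sim(psi = c(0, 0, 0, psi_knee))
  pp <- phase_profile(ns$ja)
  expect_equal(pp$pair, c("sagittal", "frontal", "transverse"))
  truth <- ns$sim$truth$psi_pairs[as.character(pp$pair)]
  expect_lt(max(circ_diff(pp$phi_deg, truth)), 1)
  # stored rows satisfy phi = 360 f dt exactly
  expect_identical(pp$phi_deg, 360 * pp$f_hz * pp$dt_s)
  # determinism
  expect_identical(pp, phase_profile(ns$ja))
})

test_that("identical channels give zero phase difference on all pairs", {
  t <- seq(0, 20, by = 0.01)
  x <- 30 + 10 * cos(2 * pi * 0.7 * t)
  ja <- joint_angle_series(t, matrix(x, length(t), 6))
  pp <- phase_profile(ja)
  expect_lt(max(abs(pp$phi_deg)), 1e-6)
})

test_that("phi is invariant to channel amplitude, offset and slow drift", {
  ns <- noiseless_sim(seed = 43)
  pp0 <- phase_profile(ns$ja)
  ja2 <- ns$ja
  ja2$theta5 <- 3 * ja2$theta5 + 12 + (5 / 3600) * ja2$t   # gain, offset, 5 deg/h
  ja2$theta4 <- 0.25 * ja2$theta4 - 4
  pp1 <- phase_profile(ja2)
  expect_lt(max(abs(pp1$phi_deg - pp0$phi_deg)), 0.5)
  # pure positive scaling alone is exactly neutral
  ja3 <- ns$ja
  ja3$theta5 <- 7 * ja3$theta5
  expect_equal(phase_profile(ja3)$phi_deg, pp0$phi_deg, tolerance = 1e-9)
})

test_that("classification applies the documented threshold rule", {
  expect_equal(classify_gait(101.41)$label, "normal")
  expect_equal(classify_gait(-62.61)$label, "hemiplegic")
  cl <- classify_gait(20)
  expect_equal(cl$label, "indeterminate")
  expect_equal(cl$score, 20)
  expect_match(classify_gait(101.41)$rule, "[Hh]euristic")
  # profile path needs the sagittal pair
  ns <- noiseless_sim(seed = 44)
  pp <- phase_profile(ns$ja, plane_pairs = c("frontal"))
  expect_error(classify_gait(pp), "sagittal")
  expect_error(classify_gait(50, threshold_normal = 10, threshold_hemi = 20),
               "below")
})

test_that("trial summaries compute linear mean/sd per pair", {
  mk <- function(phi) {
    structure(data.frame(pair = "sagittal", hip_channel = "hip_sagittal",
                         knee_channel = "knee_sagittal", f_hz = 0.77,
                         dt_s = phi / (360 * 0.77), phi_deg = phi),
              class = c("phase_profile", "data.frame"))
  }
  s1 <- summarize_trials(list(mk(95)))
  expect_equal(s1$mean_phi, 95)
  expect_equal(s1$std_phi, 0)
  s3 <- summarize_trials(list(mk(90), mk(100), mk(110)))
  expect_equal(s3$mean_phi, 100)
  expect_equal(s3$std_phi, 10)
  expect_equal(s3$n_trials, 3)
  expect_error(summarize_trials(list()), "at least one")
})

test_that("noisy repeated trials stay centred on the injected offset", {
  trials <- lapply(1:20, function(s) {
    p <- gait_model_params(psi = c(0, 0, 0, -155.63, 100, 91.7), seed = s)
    sim <- simulate_gait(p)
    phase_profile(joint_angles(sim$stream, n_init = p$n_calib, quiet = TRUE),
                  plane_pairs = "sagittal")
  })
  sm <- summarize_trials(trials)
  expect_lt(abs(sm$mean_phi - 100), 3)
  expect_equal(sm$n_trials, 20)
  expect_equal(round(sm$f_mean, 2), 0.77)
})
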