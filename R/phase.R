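# Gait phase analysis: normalized instantaneous signals, gait-frequency
# estimation, hip-knee time lags and the phase-difference angle
# phi = 360 * f * dt per anatomical plane pair.
#
# The oscillation of each joint-angle channel is represented by its
# "instantaneous signal": the temporal derivative, mean-removed and
# amplitude-normalized. Differentiation annihilates constant mounting/offset
# errors exactly and turns slow drift into a near-constant that mean removal
# strips, which is what makes the phase estimates robust to the dominant IMU
# error modes.

#' Normalized instantaneous signal of a joint-angle channel
#'
#' Central-difference temporal derivative of the channel, mean-removed and
#' scaled to unit peak amplitude (`max(abs(values)) == 1`). Constant offsets
#' in the input are annihilated exactly; linear drift becomes a constant in
#' the derivative and is removed by the mean subtraction.
#'
#' @param t Timestamps in seconds (>= 3 samples, strictly increasing).
#' @param theta Joint-angle values in degrees, same length as `t`.
#' @return An object of class `normalized_signal`: list with `t`, `values`
#'   (dimensionless, zero mean, unit peak), `rate`.
#' @export
normalize_signal <- function(t, theta) {
  if (length(t) < 3L) stop("need at least 3 samples to differentiate")
  if (length(theta) != length(t)) stop("t and theta lengths differ")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  n <- length(t)
  v <- numeric(n)
  v[1] <- (theta[2] - theta[1]) / (t[2] - t[1])
  v[n] <- (theta[n] - theta[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L)
    v[2:(n - 1)] <- (theta[3:n] - theta[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v <- v - mean(v)
  peak <- max(abs(v))
  if (peak == 0)
    stop("degenerate signal: channel has zero oscillation (constant or purely linear input)")
  structure(list(t = as.numeric(t), values = v / peak,
                 rate = 1 / stats::median(diff(t))),
            class = "normalized_signal")
}

as_normalized_signal <- function(x, t = NULL) {
  if (inherits(x, "normalized_signal")) return(x)
  if (is.null(t)) stop("timestamps required for a raw numeric channel")
  normalize_signal(t, x)
}

#' Estimate the gait cycle frequency of a joint-angle channel
#'
#' Locates the dominant spectral peak of the mean-removed channel inside a
#' frequency band, then refines the peak location by maximizing the
#' continuous DFT magnitude around the coarse periodogram bin, so the
#' estimate is not quantized to the periodogram grid. The hip sagittal
#' channel (the strongest gait oscillation) is the default.
#'
#' @param x A `joint_angle_series`, a `normalized_signal`, or a numeric
#'   vector (then `t` is required).
#' @param t Timestamps when `x` is a plain numeric vector.
#' @param channel Channel label or column used when `x` is a series
#'   (default `"hip_sagittal"`).
#' @param band Two-element search band in Hz, default `c(0.3, 3)`.
#' @param min_peak_ratio Reject the estimate when the in-band peak power is
#'   below this multiple of the median in-band power (no clear gait
#'   rhythm).
#' @return Gait cycle frequency in Hz (unrounded; round to 2 decimals for
#'   display).
#' @export
estimate_gait_frequency <- function(x, t = NULL, channel = "hip_sagittal",
                                    band = c(0.3, 3), min_peak_ratio = 20) {
  if (inherits(x, "joint_angle_series")) {
    t <- x$t
    x <- series_channel(x, channel)
  } else if (inherits(x, "normalized_signal")) {
    t <- x$t
    x <- x$values
  }
  if (is.null(t) || length(t) != length(x)) stop("need matching t and signal")
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be an increasing positive interval in Hz")
  n <- length(x)
  dt <- mean(diff(t))
  span <- t[n] - t[1]
  if (span * band[1] < 2)
    stop("series shorter than 2 cycles of the lower band edge")
  y <- x - mean(x)
  if (all(y == 0)) stop("constant channel: no spectral peak")
  spec <- Mod(stats::fft(y))^2
  freqs <- (seq_len(n) - 1L) / (n * dt)
  in_band <- which(freqs >= band[1] & freqs <= min(band[2], 1 / (2 * dt)))
  if (length(in_band) < 3L) stop("band too narrow for the series length")
  pw <- spec[in_band]
  peak <- which.max(pw)
  if (pw[peak] < min_peak_ratio * stats::median(pw))
    stop("no spectral peak above the noise floor in the search band")
  f0 <- freqs[in_band[peak]]
  # refine on the continuous DFT magnitude of the analytic signal within
  # +/- one coarse bin (the analytic signal has no negative-frequency image,
  # whose leakage would otherwise bias the peak location)
  df <- 1 / (n * dt)
  z <- analytic_signal(y)
  amp <- function(f) Mod(sum(z * exp(-2i * pi * f * t)))
  opt <- stats::optimize(amp, lower = max(band[1], f0 - df),
                         upper = min(band[2], f0 + df), maximum = TRUE,
                         tol = 1e-10)
  f_hat <- opt$maximum
  if (span * f_hat < 3)
    stop("series covers fewer than 3 cycles of the estimated gait frequency")
  f_hat
}

#' Normalized gait phase diagram of a hip-knee channel pair
#'
#' The Lissajous-style point sequence (hip normalized instantaneous signal
#' against the knee's) whose shape encodes the hip-knee coordination over
#' the gait cycle: a diagonal for in-phase motion, a circle for quadrature,
#' the anti-diagonal for anti-phase.
#'
#' @param hip,knee `normalized_signal` objects on common timestamps.
#' @return Data frame of class `gait_phase_diagram` with columns `t`,
#'   `hip_value`, `knee_value`.
#' @export
phase_diagram <- function(hip, knee) {
  if (!inherits(hip, "normalized_signal") || !inherits(knee, "normalized_signal"))
    stop("phase_diagram expects two normalized_signal objects")
  if (length(hip$values) != length(knee$values))
    stop("hip and knee signals differ in length")
  if (max(abs(hip$t - knee$t)) > 1e-9)
    stop("hip and knee signals are not on common timestamps")
  structure(data.frame(t = hip$t, hip_value = hip$values,
                       knee_value = knee$values),
            class = c("gait_phase_diagram", "data.frame"))
}

#' @export
plot.gait_phase_diagram <- function(x, ...) {
  graphics::plot(x$hip_value, x$knee_value, type = "l", asp = 1,
                 xlab = "hip (normalized)", ylab = "knee (normalized)", ...)
  invisible(x)
}

# Analytic signal via the FFT: zero the negative-frequency half, double the
# positive half. Standard discrete Hilbert-transform construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Estimate the hip-knee time lag
#'
#' Signed time difference between the hip and knee oscillations at gait
#' frequency `f`. Positive lag means the knee waveform trails the hip
#' waveform.
#'
#' Two estimators are provided. `"analytic"` (default) takes the circular
#' mean of the instantaneous phase difference between the two analytic
#' (discrete Hilbert) signals and divides by `2 pi f`; it resolves lags in
#' `(-1/(2f), 1/(2f)]`. `"xcorr"` locates the cross-correlation maximum over
#' lags in the same window, widened to `(-1/f, 1/f)` when `extend = TRUE`,
#' with parabolic sub-sample refinement of the peak.
#'
#' @param hip,knee `normalized_signal` objects on common timestamps (or raw
#'   numeric channels, then `t` is required).
#' @param f Gait cycle frequency in Hz.
#' @param method `"analytic"` or `"xcorr"`.
#' @param extend Widen the `xcorr` lag window to a full cycle (ignored by
#'   the analytic estimator, whose phase is principal-valued).
#' @param edge_trim Fraction of samples discarded at each end before the
#'   circular mean, to suppress Hilbert edge effects (analytic method only).
#' @param t Timestamps for raw numeric inputs.
#' @return Time lag in seconds.
#' @export
estimate_time_lag <- function(hip, knee, f, method = c("analytic", "xcorr"),
                              extend = FALSE, edge_trim = 0.1, t = NULL) {
  method <- match.arg(method)
  hip <- as_normalized_signal(hip, t)
  knee <- as_normalized_signal(knee, t)
  if (length(hip$values) != length(knee$values))
    stop("hip and knee signals differ in length")
  if (f <= 0) stop("gait frequency must be positive")
  n <- length(hip$values)
  span <- hip$t[n] - hip$t[1]
  if (span * f < 2) stop("signals span fewer than 2 cycles of f")
  if (method == "analytic") {
    zh <- analytic_signal(hip$values)
    zk <- analytic_signal(knee$values)
    keep <- seq_len(n)
    drop_n <- floor(edge_trim * n)
    if (drop_n > 0 && n - 2 * drop_n >= 8)
      keep <- (drop_n + 1):(n - drop_n)
    cross <- zk[keep] * Conj(zh[keep])
    m <- mean(cross / pmax(Mod(cross), .Machine$double.eps))
    -Arg(m) / (2 * pi * f)
  } else {
    rate <- hip$rate
    max_lag <- if (extend) floor(rate / f) - 1L else floor(rate / (2 * f))
    max_lag <- max(1L, min(max_lag, n - 2L))
    lags <- seq.int(-max_lag, max_lag)
    score <- vapply(lags, function(L) {
      if (L >= 0) {
        i <- (L + 1L):n
        sum(hip$values[i - L] * knee$values[i])
      } else {
        i <- 1L:(n + L)
        sum(hip$values[i - L] * knee$values[i])
      }
    }, numeric(1))
    k <- which.max(score)
    L <- lags[k]
    # parabolic sub-sample refinement when the peak is interior
    if (k > 1L && k < length(lags)) {
      y1 <- score[k - 1L]; y2 <- score[k]; y3 <- score[k + 1L]
      denom <- y1 - 2 * y2 + y3
      if (denom < 0) L <- L + 0.5 * (y1 - y3) / denom
    }
    L / rate
  }
}

#' Phase-difference angle from frequency and time lag
#'
#' Converts a hip-knee time lag into degrees of gait cycle:
#' `phi = 360 * f * dt`. No modular reduction is applied, so with lags
#' resolved within one cycle the result lies in `(-360, 360)` degrees.
#'
#' @param f Gait cycle frequency in Hz (positive).
#' @param dt Time lag in seconds (positive: knee trails hip).
#' @return Phase-difference angle in degrees.
#' @export
phase_difference_angle <- function(f, dt) {
  if (any(f <= 0)) stop("gait frequency must be positive")
  360 * f * dt
}

#' Phase-difference profile of a joint-angle series
#'
#' For each requested plane pair (hip sagittal against a knee plane), builds
#' the normalized instantaneous signals, estimates the hip-knee time lag,
#' and reports the phase-difference angle `phi = 360 * f * dt`. The gait
#' frequency is estimated once from the hip sagittal channel unless supplied.
#'
#' @param series A `joint_angle_series`.
#' @param plane_pairs Character vector of knee planes to pair with the hip
#'   sagittal channel; default `c("sagittal", "frontal", "transverse")`.
#' @param f Gait frequency in Hz, or `NULL` (default) to estimate it from
#'   `freq_channel`.
#' @param method Lag estimator, `"analytic"` (default) or `"xcorr"`.
#' @param freq_channel Channel used for frequency estimation.
#' @param band Frequency search band in Hz.
#' @param extend Widen the xcorr lag window to a full cycle.
#' @param skip_calibration_hold Drop the calibration window (the series'
#'   `n_init` leading samples) plus any further leading singular samples
#'   before analysis (default TRUE). The hold is not gait, and under
#'   measurement noise its near-singular samples decompose to
#'   ill-determined transverse/frontal angles whose derivative spikes would
#'   corrupt the analytic-signal phase.
#' @return Data frame of class `phase_profile` with columns `pair`,
#'   `hip_channel`, `knee_channel`, `f_hz`, `dt_s`, `phi_deg`; attributes
#'   `method`, `f_source`. Each row satisfies
#'   `phi_deg == 360 * f_hz * dt_s` exactly as stored.
#' @export
phase_profile <- function(series,
                          plane_pairs = c("sagittal", "frontal", "transverse"),
                          f = NULL, method = c("analytic", "xcorr"),
                          freq_channel = "hip_sagittal", band = c(0.3, 3),
                          extend = FALSE, skip_calibration_hold = TRUE) {
  stopifnot(inherits(series, "joint_angle_series"))
  method <- match.arg(method)
  if (skip_calibration_hold) {
    n_init <- attr(series, "n_init")
    drop <- if (is.null(n_init)) 0L else as.integer(n_init)
    sing <- attr(series, "singular")
    if (!is.null(sing) && any(sing)) {
      run <- rle(sing)
      if (run$values[1]) drop <- max(drop, run$lengths[1])
    }
    if (drop > 0L && nrow(series) - drop >= 3L) {
      keep <- (drop + 1L):nrow(series)
      pm <- attr(series, "plane_map"); rt <- attr(series, "rate")
      series <- joint_angle_series(series$t[keep],
                                   as.matrix(series[keep, paste0("theta", 1:6)]),
                                   plane_map = pm, rate = rt)
    }
  }
  t <- series$t
  f_source <- if (is.null(f)) sprintf("estimated from %s", freq_channel) else "supplied"
  if (is.null(f))
    f <- estimate_gait_frequency(series, channel = freq_channel, band = band)
  hip_sig <- normalize_signal(t, series_channel(series, "hip_sagittal"))
  rows <- lapply(plane_pairs, function(pl) {
    knee_channel <- paste0("knee_", pl)
    res <- tryCatch({
      knee_sig <- normalize_signal(t, series_channel(series, knee_channel))
      dt <- estimate_time_lag(hip_sig, knee_sig, f = f, method = method,
                              extend = extend)
      data.frame(pair = pl, hip_channel = "hip_sagittal",
                 knee_channel = knee_channel, f_hz = f, dt_s = dt,
                 phi_deg = phase_difference_angle(f, dt))
    }, error = function(e) {
      stop(sprintf("plane pair 'hip_sagittal vs %s' failed: %s",
                   knee_channel, conditionMessage(e)), call. = FALSE)
    })
    res
  })
  structure(do.call(rbind, rows), method = method, f_source = f_source,
            class = c("phase_profile", "data.frame"))
}

classifier_disclaimer <- function() {
  paste("Heuristic threshold rule calibrated to prototype phase-difference",
        "means; not a validated clinical classifier.")
}

#' Classify a gait pattern from its phase-difference profile
#'
#' Threshold rule on the sagittal-sagittal phase-difference angle: large
#' positive phase difference (knee trailing the hip by a sizeable fraction
#' of the cycle) is the normal pattern; zero or negative phase difference is
#' the hemiplegic pattern; the band between the thresholds is reported as
#' indeterminate. The rule is a heuristic calibrated to prototype means of
#' the two patterns, not a validated clinical classifier, and every report
#' carries that disclaimer.
#'
#' @param profile A `phase_profile` (must contain the sagittal pair), or a
#'   single numeric sagittal phi in degrees.
#' @param threshold_normal Lower phi bound for the normal label, degrees
#'   (default 45).
#' @param threshold_hemi Upper phi bound for the hemiplegic label, degrees
#'   (default 0).
#' @return Object of class `gait_classification`: list with `label`
#'   (`"normal"`, `"hemiplegic"` or `"indeterminate"`), `score` (degrees to
#'   the decision boundary), `phi_sagittal`, `thresholds`, `rule`.
#' @export
classify_gait <- function(profile, threshold_normal = 45, threshold_hemi = 0) {
  if (threshold_hemi >= threshold_normal)
    stop("threshold_hemi must be below threshold_normal")
  if (is.numeric(profile) && length(profile) == 1L) {
    phi <- as.numeric(profile)
  } else {
    if (!inherits(profile, "phase_profile"))
      stop("profile must be a phase_profile or a single sagittal phi")
    row <- which(profile$pair == "sagittal")
    if (length(row) != 1L)
      stop("sagittal-sagittal pair missing from the profile")
    phi <- profile$phi_deg[row]
  }
  if (phi >= threshold_normal) {
    label <- "normal"; score <- phi - threshold_normal
  } else if (phi <= threshold_hemi) {
    label <- "hemiplegic"; score <- threshold_hemi - phi
  } else {
    label <- "indeterminate"
    score <- min(threshold_normal - phi, phi - threshold_hemi)
  }
  structure(list(label = label, score = score, phi_sagittal = phi,
                 thresholds = c(normal = threshold_normal,
                                hemi = threshold_hemi),
                 rule = classifier_disclaimer()),
            class = "gait_classification")
}

#' @export
print.gait_classification <- function(x, ...) {
  cat(sprintf("gait pattern: %s (sagittal phi = %.2f deg, %.2f deg from boundary)\n",
              x$label, x$phi_sagittal, x$score))
  cat("rule:", x$rule, "\n")
  invisible(x)
}

#' Summarize phase-difference profiles over repeated trials
#'
#' Arithmetic mean and sample standard deviation of the phase-difference
#' angle per plane pair across trials, plus the mean gait frequency. A
#' circular alternative (circular mean direction and circular SD) is behind
#' the `circular` flag.
#'
#' @param trials List of `phase_profile` objects with identical pair sets.
#' @param circular Use circular statistics instead of linear ones.
#' @return Data frame of class `trial_summary` with columns `pair`,
#'   `mean_phi`, `std_phi`, `n_trials`, `f_mean`.
#' @export
summarize_trials <- function(trials, circular = FALSE) {
  if (length(trials) < 1L) stop("need at least one trial")
  if (!all(vapply(trials, inherits, logical(1), "phase_profile")))
    stop("trials must be phase_profile objects")
  pairs <- trials[[1]]$pair
  for (tr in trials)
    if (!identical(as.character(tr$pair), as.character(pairs)))
      stop("trials have inconsistent plane-pair sets")
  n <- length(trials)
  rows <- lapply(seq_along(pairs), function(i) {
    phis <- vapply(trials, function(tr) tr$phi_deg[i], numeric(1))
    fs <- vapply(trials, function(tr) tr$f_hz[i], numeric(1))
    if (circular) {
      z <- mean(exp(1i * deg2rad(phis)))
      mean_phi <- rad2deg(Arg(z))
      std_phi <- rad2deg(sqrt(-2 * log(pmax(Mod(z), .Machine$double.eps))))
    } else {
      mean_phi <- mean(phis)
      std_phi <- if (n > 1L) stats::sd(phis) else 0
    }
    data.frame(pair = pairs[i], mean_phi = mean_phi, std_phi = std_phi,
               n_trials = n, f_mean = mean(fs))
  })
  structure(do.call(rbind, rows), class = c("trial_summary", "data.frame"))
}
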