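# Readers and writers for the package's file dialects: the paired
# two-sensor quaternion CSV, the joint-angle CSV, and the JSON phase report.
# Comma-separated, dot decimal, mandatory header, UTF-8 throughout.

SENSOR_CSV_HEADER <- c("t", "qw_A", "qx_A", "qy_A", "qz_A",
                       "qw_B", "qx_B", "qy_B", "qz_B")
ANGLES_CSV_HEADER <- c("t", paste0("theta", 1:6))

#' Read a paired two-sensor quaternion CSV
#'
#' Expects the header `t,qw_A,qx_A,qy_A,qz_A,qw_B,qx_B,qy_B,qz_B`, one row
#' per paired sample. Rows with non-finite values, non-increasing
#' timestamps, or quaternion norms deviating from 1 by more than `norm_tol`
#' are rejected with the offending row number in the error message.
#'
#' @param path CSV file path.
#' @param norm_tol Largest tolerated quaternion-norm deviation (default
#'   `1e-3`).
#' @return A [sensor_stream()].
#' @export
read_sensor_csv <- function(path, norm_tol = 1e-3) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), SENSOR_CSV_HEADER))
    stop(sprintf("bad sensor CSV header: expected '%s', got '%s'",
                 paste(SENSOR_CSV_HEADER, collapse = ","),
                 paste(names(df), collapse = ",")))
  m <- as.matrix(df)
  if (!is.numeric(m) || any(!is.finite(m))) {
    bad <- which(apply(m, 1L, function(r) !is.numeric(r) || any(!is.finite(r))))[1]
    stop(sprintf("non-finite or non-numeric value at data row %d", bad))
  }
  bad_t <- which(diff(m[, "t"]) <= 0)
  if (length(bad_t) > 0)
    stop(sprintf("timestamps not strictly increasing at data row %d", bad_t[1] + 1L))
  for (s in c("A", "B")) {
    q <- m[, paste0(c("qw_", "qx_", "qy_", "qz_"), s), drop = FALSE]
    dev <- abs(sqrt(rowSums(q^2)) - 1)
    if (any(dev > norm_tol))
      stop(sprintf("sensor %s quaternion norm deviates by %.3g at data row %d",
                   s, max(dev), which.max(dev)))
  }
  sensor_stream(m[, "t"],
                m[, paste0(c("qw_", "qx_", "qy_", "qz_"), "A")],
                m[, paste0(c("qw_", "qx_", "qy_", "qz_"), "B")],
                norm_tol = norm_tol)
}

#' Write a sensor stream to the paired quaternion CSV dialect
#'
#' @param stream A [sensor_stream()].
#' @param path Output path.
#' @param digits Significant digits written (default 10).
#' @export
write_sensor_csv <- function(stream, path, digits = 10) {
  stopifnot(inherits(stream, "sensor_stream"))
  m <- cbind(stream$t, stream$qA, stream$qB)
  df <- as.data.frame(signif(m, digits))
  names(df) <- SENSOR_CSV_HEADER
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a joint-angle series to CSV
#'
#' Header `t,theta1,...,theta6`, angles in degrees.
#'
#' @param series A `joint_angle_series`.
#' @param path Output path.
#' @param digits Significant digits written (default 10).
#' @export
write_angles_csv <- function(series, path, digits = 10) {
  stopifnot(inherits(series, "joint_angle_series"))
  df <- as.data.frame(signif(as.matrix(series[ANGLES_CSV_HEADER]), digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a joint-angle CSV
#'
#' @param path CSV path with header `t,theta1,...,theta6`.
#' @param plane_map Channel-to-column mapping, default [default_plane_map()].
#' @return A `joint_angle_series`.
#' @export
read_angles_csv <- function(path, plane_map = default_plane_map()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), ANGLES_CSV_HEADER))
    stop(sprintf("bad angles CSV header: expected '%s'",
                 paste(ANGLES_CSV_HEADER, collapse = ",")))
  m <- as.matrix(df)
  if (any(!is.finite(m))) stop("non-finite values in angles CSV")
  joint_angle_series(m[, "t"], m[, -1L, drop = FALSE], plane_map = plane_map)
}

#' Write a JSON phase report
#'
#' Serializes a phase-difference profile (and optionally its
#' classification) to the documented JSON schema:
#' `{version, seed, config, pairs: [{plane_pair, f_hz, dt_s, phi_deg}],
#' classification: {label, score, phi_sagittal, thresholds, rule}}`.
#' The classifier's heuristic-rule disclaimer travels with every report.
#'
#' @param profile A `phase_profile`.
#' @param path Output path.
#' @param classification Optional `gait_classification`.
#' @param config Optional named list echoed into the report.
#' @param seed Optional RNG seed echoed into the report.
#' @export
write_phase_report <- function(profile, path, classification = NULL,
                               config = list(), seed = NULL) {
  stopifnot(inherits(profile, "phase_profile"))
  pairs <- lapply(seq_len(nrow(profile)), function(i) {
    list(plane_pair = sprintf("%s vs %s", profile$hip_channel[i],
                              profile$knee_channel[i]),
         pair = as.character(profile$pair[i]),
         f_hz = profile$f_hz[i], dt_s = profile$dt_s[i],
         phi_deg = profile$phi_deg[i])
  })
  report <- list(
    tool = "gaitphase",
    version = as.character(utils::packageVersion("gaitphase")),
    seed = seed,
    config = config,
    method = attr(profile, "method"),
    f_source = attr(profile, "f_source"),
    pairs = pairs
  )
  if (!is.null(classification)) {
    stopifnot(inherits(classification, "gait_classification"))
    report$classification <- list(
      label = classification$label,
      score = classification$score,
      phi_sagittal = classification$phi_sagittal,
      threshold_normal = unname(classification$thresholds["normal"]),
      threshold_hemi = unname(classification$thresholds["hemi"]),
      rule = classification$rule
    )
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON phase report
#'
#' @param path Report path written by [write_phase_report()].
#' @return List with `profile` (a `phase_profile` data frame),
#'   `classification` (list or `NULL`) and the report metadata.
#' @export
read_phase_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- rep$pairs
  profile <- structure(
    data.frame(pair = pr$pair, hip_channel = "hip_sagittal",
               knee_channel = paste0("knee_", pr$pair),
               f_hz = pr$f_hz, dt_s = pr$dt_s, phi_deg = pr$phi_deg),
    method = rep$method, f_source = rep$f_source,
    class = c("phase_profile", "data.frame"))
  list(profile = profile, classification = rep$classification,
       version = rep$version, seed = rep$seed, config = rep$config)
}

#' Write a ground-truth JSON for a simulated recording
#'
#' @param truth A `gait_truth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "gait_truth"))
  p <- truth$params
  jsonlite::write_json(list(
    f_hz = truth$f,
    psi_deg = as.list(truth$psi_pairs),
    n_calib = truth$n_calib,
    params = list(f = p$f, duration = p$duration, rate = p$rate,
                  mean = p$mean, amp = p$amp, psi = p$psi,
                  noise_std = p$noise_std, drift_rate = p$drift_rate,
                  offset_A = p$offset_A, offset_B = p$offset_B,
                  mount_side = p$mount_side, seed = p$seed)
  ), path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
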