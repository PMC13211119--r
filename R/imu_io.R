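# Data model for foot-mounted IMU streams and stride windows, CSV I/O, and
# quaternion utilities.
#
# Conventions (documented once, used everywhere):
#   * Quaternions are scalar-first (w, x, y, z), Hamilton product, and encode
#     the body -> global rotation, so quat_to_rotmat(q) %*% v_body = v_global.
#     This matches the default of common wearable sensor SDKs.
#   * The global frame is right-handed with the z-axis up; gravity is
#     [0, 0, g] with g = 9.81 m/s^2 by default.
#   * Integration uses a fixed step dt = 1/rate_hz; timestamps are used for
#     validation only.

#' IMU stream container
#'
#' Bundles a time-stamped stream of body-frame specific-force acceleration
#' (gravity-inclusive, m/s^2), body-frame angular velocity (rad/s) and
#' body-to-global orientation quaternions sampled at a fixed nominal rate.
#'
#' @param t Numeric vector of timestamps (s), strictly increasing.
#' @param a Numeric n x 3 matrix of body-frame acceleration (m/s^2).
#' @param w Numeric n x 3 matrix of body-frame angular velocity (rad/s).
#' @param q Numeric n x 4 matrix of unit quaternions (w, x, y, z),
#'   body -> global; renormalized on ingest.
#' @param rate_hz Nominal sampling rate (Hz).
#' @param label Optional integer vector of per-sample activity codes
#'   (0 = level, 1 = ramp ascend, 2 = ramp descend, 3 = stair ascend,
#'   4 = stair descend).
#' @param meta Free-form provenance list.
#' @param check_rate If `TRUE` (default), warn when the observed sampling
#'   interval deviates from 1/`rate_hz` by more than 10%.
#'
#' @return An object of class `imu_stream`.
#' @export
imu_stream <- function(t, a, w, q, rate_hz, label = NULL, meta = list(),
                       check_rate = TRUE) {
  a <- as_matrix3(a, "a")
  w <- as_matrix3(w, "w")
  q <- as.matrix(q)
  n <- length(t)
  if (n == 0L) stop("imu_stream must be non-empty")
  if (nrow(a) != n || nrow(w) != n || nrow(q) != n) {
    stop("t, a, w and q must have matching lengths")
  }
  if (ncol(q) != 4L) stop("q must be an n x 4 matrix (w, x, y, z)")
  if (any(!is.finite(t)) || any(!is.finite(a)) || any(!is.finite(w)) ||
      any(!is.finite(q))) {
    stop("imu_stream fields must be finite")
  }
  if (n > 1L) {
    dts <- diff(t)
    if (any(dts <= 0)) {
      stop(sprintf("timestamps must be strictly increasing (first violation at sample %d)",
                   which(dts <= 0)[1L] + 1L))
    }
    if (isTRUE(check_rate)) {
      nominal <- 1 / rate_hz
      if (any(abs(dts - nominal) > 0.1 * nominal)) {
        warning(sprintf("sampling interval deviates >10%% from nominal 1/%g s", rate_hz))
      }
    }
  }
  nq <- sqrt(rowSums(q^2))
  if (any(nq < 1e-8)) stop("near-zero quaternion norm in stream")
  q <- q / nq
  if (!is.null(label)) {
    label <- as.integer(label)
    if (length(label) != n) stop("label must have one entry per sample")
  }
  structure(
    list(t = as.numeric(t), a = unname(a), w = unname(w), q = unname(q),
         rate_hz = rate_hz, label = label, meta = meta),
    class = "imu_stream"
  )
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %d samples @ %g Hz (%.2f s)%s\n",
              n_samples(x), x$rate_hz, diff(range(x$t)),
              if (!is.null(x$label)) ", labelled" else ""))
  invisible(x)
}

#' Number of samples in a stream
#' @param stream An `imu_stream`.
#' @return Integer sample count.
#' @export
n_samples <- function(stream) length(stream$t)

as_matrix3 <- function(x, name) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must be an n x 3 matrix", name))
  storage.mode(x) <- "double"
  x
}

imu_csv_columns <- c("t", "ax", "ay", "az", "wx", "wy", "wz",
                     "qw", "qx", "qy", "qz")

#' Read an IMU stream from CSV
#'
#' The file must carry a header with columns `t, ax, ay, az, wx, wy, wz,
#' qw, qx, qy, qz` and may carry an optional integer `label` column.
#' Quaternions are renormalized; rows containing non-finite values are
#' dropped with a warning naming the offending row numbers.
#'
#' @param path Path to a CSV file (comma-separated, `.` decimal, UTF-8).
#' @param rate_hz Nominal sampling rate (Hz).
#' @return An [imu_stream].
#' @export
read_imu_csv <- function(path, rate_hz) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, header = TRUE)
  missing <- setdiff(imu_csv_columns, names(df))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  num <- as.matrix(df[imu_csv_columns])
  bad <- which(!is.finite(rowSums(num)))
  if (length(bad)) {
    warning(sprintf("dropping %d row(s) with non-finite values: %s",
                    length(bad), paste(utils::head(bad, 10L), collapse = ", ")))
    df <- df[-bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid rows in file")
  dts <- diff(df$t)
  if (any(dts <= 0)) {
    stop(sprintf("timestamps not strictly increasing at row %d",
                 which(dts <= 0)[1L] + 1L))
  }
  imu_stream(
    t = df$t,
    a = as.matrix(df[c("ax", "ay", "az")]),
    w = as.matrix(df[c("wx", "wy", "wz")]),
    q = as.matrix(df[c("qw", "qx", "qy", "qz")]),
    rate_hz = rate_hz,
    label = if ("label" %in% names(df)) df$label else NULL,
    meta = list(source = path)
  )
}

#' Write an IMU stream to CSV
#'
#' Inverse of [read_imu_csv()]; fields round-trip to at least 12
#' significant digits.
#'
#' @param stream An [imu_stream].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  df <- data.frame(
    t = stream$t,
    ax = stream$a[, 1], ay = stream$a[, 2], az = stream$a[, 3],
    wx = stream$w[, 1], wy = stream$w[, 2], wz = stream$w[, 3],
    qw = stream$q[, 1], qx = stream$q[, 2], qy = stream$q[, 3],
    qz = stream$q[, 4]
  )
  if (!is.null(stream$label)) df$label <- stream$label
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "label"
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Scalar-first Hamilton convention; the returned matrix maps body-frame
#' vectors to the global frame. The input is renormalized internally and
#' must be within 1e-3 of unit norm.
#'
#' @param q Length-4 numeric vector (w, x, y, z).
#' @return A proper 3 x 3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  if (length(q) != 4L) stop("q must have 4 components (w, x, y, z)")
  nq <- sqrt(sum(q^2))
  if (nq < 1e-8) stop("invalid orientation: near-zero quaternion norm")
  if (abs(nq - 1) > 1e-3) {
    stop(sprintf("quaternion norm %.6f deviates from 1 by more than 1e-3", nq))
  }
  q <- q / nq
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Rotation matrices for every sample of a stream (list of 3x3).
stream_rotations <- function(stream, idx = seq_len(n_samples(stream))) {
  lapply(idx, function(i) quat_to_rotmat(stream$q[i, ]))
}

#' Stride window
#'
#' A stride spans from one zero-velocity point (ZVP) to the next, inclusive.
#' `khs` is the heel-strike sample index, 1-based within the window.
#'
#' @param k0 Start index in the stream (opening ZVP, inclusive, 1-based).
#' @param k1 End index in the stream (closing ZVP, inclusive).
#' @param khs Heel-strike index relative to the window start (1-based);
#'   may be `NA` before detection.
#' @param min_len Minimum admissible sample count.
#' @return An object of class `stride_window` with fields `k0`, `k1`, `N`,
#'   `khs`.
#' @export
stride_window <- function(k0, k1, khs = NA_integer_, min_len = 2L) {
  k0 <- as.integer(k0); k1 <- as.integer(k1)
  if (k0 >= k1) stop("stride window requires k0 < k1")
  N <- k1 - k0 + 1L
  if (N < min_len) {
    stop(sprintf("degenerate stride: %d samples < minimum %d", N, min_len))
  }
  if (!is.na(khs)) {
    khs <- as.integer(khs)
    if (khs < 1L || khs > N) stop("khs must lie within the stride window")
  }
  structure(list(k0 = k0, k1 = k1, N = N, khs = khs), class = "stride_window")
}

#' @export
print.stride_window <- function(x, ...) {
  cat(sprintf("<stride_window> [%d, %d] N=%d khs=%s\n",
              x$k0, x$k1, x$N, ifelse(is.na(x$khs), "?", x$khs)))
  invisible(x)
}
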