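# Real-time gait event detection: zero-velocity points (stride boundaries)
# by thresholded stance windows, and heel strike by the intra-stride foot
# pitch maximum.

#' ZVP detector configuration
#'
#' Thresholds and window parameters for the causal zero-velocity-point
#' detector. The numeric defaults are engineering choices tuned for typical
#' adult gait at 60 Hz; the selection of the window's angular-velocity
#' minimum is insensitive to moderate variation of the candidate thresholds.
#'
#' @param ta Acceleration magnitude threshold (m/s^2): a sample qualifies
#'   when `| ||a|| - g | < ta`.
#' @param tw Angular velocity magnitude threshold (rad/s).
#' @param wcap Target window capacity (samples); the window closes and
#'   emits once it holds this many candidates.
#' @param tmax Maximum window duration (s) before a non-empty window is
#'   force-closed.
#' @param g Gravity magnitude (m/s^2).
#' @param min_stride_samples Minimum samples between consecutive emitted
#'   ZVPs; later candidates within this distance are suppressed.
#' @param hybrid If `TRUE`, the ZVP within a window is taken from the
#'   acceleration-deviation minimum whenever it is smaller than the
#'   angular-velocity minimum; the default uses the angular-velocity
#'   minimum alone.
#' @return A list of class `zvp_config`.
#' @export
zvp_config <- function(ta = 0.8, tw = 0.6, wcap = 8L, tmax = 0.4, g = 9.81,
                       min_stride_samples = 30L, hybrid = FALSE) {
  stopifnot(ta > 0, tw > 0, wcap >= 2L, tmax > 0, g > 0,
            min_stride_samples >= 1L)
  structure(list(ta = ta, tw = tw, wcap = as.integer(wcap), tmax = tmax,
                 g = g, min_stride_samples = as.integer(min_stride_samples),
                 hybrid = isTRUE(hybrid)),
            class = "zvp_config")
}

#' Detect zero-velocity points in an IMU stream
#'
#' Causal sliding-window detector. A sample enters the candidate window when
#' both the gravity-removed acceleration magnitude and the angular velocity
#' magnitude fall below their thresholds. A window that reaches `wcap`
#' candidates is a valid stance: it closes and emits the candidate with the
#' minimum angular velocity magnitude (earliest sample on ties). A non-empty
#' window that has been open longer than `tmax` without filling is discarded
#' and detection restarts -- isolated low-motion samples during swing (for
#' example at pitch-rate zero crossings) therefore never emit. Each emission
#' uses only samples up to the closing sample, and emissions closer than
#' `min_stride_samples` to the previously kept ZVP are suppressed.
#'
#' @param stream An [imu_stream].
#' @param cfg A [zvp_config].
#' @return Integer vector of ZVP sample indices (possibly empty).
#' @export
detect_zvp <- function(stream, cfg = zvp_config()) {
  amag_dev <- abs(sqrt(rowSums(stream$a^2)) - cfg$g)
  wmag <- sqrt(rowSums(stream$w^2))
  qualifies <- amag_dev < cfg$ta & wmag < cfg$tw

  zvps <- integer(0)
  win <- integer(0)
  t_first <- NA_real_
  last_kept <- -Inf
  for (k in seq_len(n_samples(stream))) {
    if (qualifies[k]) {
      if (length(win) == 0L) t_first <- stream$t[k]
      win <- c(win, k)
    }
    if (length(win) >= cfg$wcap) {
      crit <- wmag[win]
      if (cfg$hybrid && min(amag_dev[win]) < min(crit)) crit <- amag_dev[win]
      kz <- win[which.min(crit)]
      if (kz - last_kept >= cfg$min_stride_samples) {
        zvps <- c(zvps, kz)
        last_kept <- kz
      }
      win <- integer(0)
      t_first <- NA_real_
    } else if (length(win) > 0L && (stream$t[k] - t_first) > cfg$tmax) {
      # underfilled window timed out: not a stance, restart detection
      win <- integer(0)
      t_first <- NA_real_
    }
  }
  zvps
}

#' Foot pitch angle from orientation quaternions
#'
#' The foot's longitudinal axis is body +y (heel to toe). Pitch is the
#' sagittal-plane inclination of that axis: the arcsine of the vertical
#' component of its global image. Positive pitch is dorsiflexion (toe up).
#' Configurations within 1e-3 rad of +/- pi/2 are flagged as near-gimbal in
#' the `"near_gimbal"` attribute; the value is still returned.
#'
#' @param q A length-4 quaternion or an n x 4 matrix of quaternions
#'   (w, x, y, z, body -> global).
#' @return Numeric vector of pitch angles (rad) with attribute
#'   `"near_gimbal"` (logical).
#' @export
pitch_from_quaternion <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  # z-component of R %*% c(0,1,0) expanded from the quaternion product
  nq <- sqrt(rowSums(q^2))
  if (any(nq < 1e-8)) stop("invalid orientation: near-zero quaternion norm")
  q <- q / nq
  zy <- 2 * (q[, 3] * q[, 4] + q[, 1] * q[, 2])
  zy <- pmin(1, pmax(-1, zy))
  pitch <- asin(zy)
  attr(pitch, "near_gimbal") <- abs(abs(pitch) - pi / 2) < 1e-3
  pitch
}

#' Detect the heel strike within a stride window
#'
#' The heel strike is the sample with the maximum foot pitch angle in the
#' second half of the stride window, `[floor(N/2), N]`; restricting the
#' search avoids spurious maxima in early swing. First index wins on exact
#' ties.
#'
#' @param pitch Numeric vector of per-sample pitch angles (rad) over the
#'   stride window.
#' @return Integer heel-strike index `khs` (1-based within the window),
#'   guaranteed to lie in `[floor(N/2), N]`.
#' @export
detect_heel_strike <- function(pitch) {
  N <- length(pitch)
  if (N < 2L) stop("stride window must contain at least 2 samples")
  lo <- max(1L, N %/% 2L)
  lo + which.max(pitch[lo:N]) - 1L
}
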