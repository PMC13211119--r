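# Per-stride kinematic features of the reconstructed foot trajectory, and
# the rigid-body toe transform used for toe clearance estimation.

#' Stride kinematic metrics
#'
#' From a reconstructed stride trajectory computes:
#' stride height `dh = p_z(N) - p_z(1)` (net vertical displacement, zero on
#' level ground, positive ascending); maximum stride height
#' `h_max = max_k p_z(k) - min_k p_z(k)` (vertical excursion, the foot
#' clearance measure); stride length `L` (planar start-to-end distance);
#' and maximum stride length `L_max` (maximum planar distance from the
#' start at any sample, which can exceed `L` when the planar path
#' overshoots the end point, as in stair descent).
#'
#' All four metrics are invariant to rotations of the trajectory about the
#' global vertical axis, so heading drift does not affect them.
#'
#' @param traj A `trajectory` (list with an N x 3 position matrix `p`), or
#'   an N x 3 position matrix.
#' @param activity Optional activity label carried through to the result.
#' @return A list of class `stride_metrics` with `stride_height`,
#'   `max_stride_height`, `stride_length`, `max_stride_length`, `activity`.
#' @export
stride_metrics <- function(traj, activity = NA_character_) {
  p <- if (is.list(traj)) traj$p else traj
  p <- as_matrix3(p, "p")
  if (nrow(p) == 0L) stop("trajectory must be non-empty")
  N <- nrow(p)
  dxy <- sweep(p[, 1:2, drop = FALSE], 2, p[1, 1:2])
  planar <- sqrt(rowSums(dxy^2))
  structure(list(
    stride_height = p[N, 3] - p[1, 3],
    max_stride_height = max(p[, 3]) - min(p[, 3]),
    stride_length = planar[N],
    max_stride_length = max(planar),
    activity = activity
  ), class = "stride_metrics")
}

#' @export
print.stride_metrics <- function(x, ...) {
  cat(sprintf("<stride_metrics%s> dh=%.3f m  h_max=%.3f m  L=%.3f m  L_max=%.3f m\n",
              if (is.na(x$activity)) "" else paste0(" ", x$activity),
              x$stride_height, x$max_stride_height,
              x$stride_length, x$max_stride_length))
  invisible(x)
}

#' Toe position by rigid-body transform
#'
#' The IMU sits on the dorsum of the foot; the toe lies a fixed distance
#' `d` along the foot's longitudinal axis (body +y). Its global position is
#' `p_toe = p_imu + R [0, d, 0]'`. The offset is an isometry:
#' `||p_toe - p_imu|| = d` for any orientation. With the dorsiflexion-
#' positive pitch convention, plantar flexion (negative pitch) lowers the
#' toe below the IMU.
#'
#' @param p_imu Length-3 global IMU position (m), or an N x 3 matrix.
#' @param R A 3 x 3 rotation matrix (body -> global), or a list of N such
#'   matrices when `p_imu` is a matrix.
#' @param d IMU-to-toe distance along the foot axis (m, positive).
#' @return Global toe position(s), same shape as `p_imu`.
#' @export
toe_position <- function(p_imu, R, d) {
  if (d <= 0) stop("toe offset d must be positive")
  offset_b <- c(0, d, 0)
  if (is.null(dim(p_imu))) {
    return(drop(p_imu + R %*% offset_b))
  }
  p_imu <- as_matrix3(p_imu, "p_imu")
  stopifnot(is.list(R), length(R) == nrow(p_imu))
  p_imu + t(vapply(R, function(Rk) drop(Rk %*% offset_b), numeric(3)))
}

#' Check obstacle clearance for a stride
#'
#' A stride clears an obstacle when its maximum stride height strictly
#' exceeds the obstacle height; the margin is the difference.
#'
#' @param metrics A `stride_metrics` object, or a numeric maximum stride
#'   height (m).
#' @param obstacle_height Obstacle height (m, non-negative).
#' @return A list with `pass` (logical) and `margin` (m).
#' @export
obstacle_clearance_check <- function(metrics, obstacle_height) {
  if (obstacle_height < 0) stop("obstacle height must be non-negative")
  h_max <- if (is.list(metrics)) metrics$max_stride_height else metrics
  list(pass = h_max > obstacle_height, margin = h_max - obstacle_height)
}
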