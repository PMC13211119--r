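# Strapdown kinematics for a single foot-mounted IMU: gravity removal,
# per-stride integration, drift bookkeeping, and the zero-velocity /
# zero-height-change constraint solves that estimate a per-stride
# accelerometer bias and heel-strike velocity error.
#
# Discrete model within one stride window of N samples (indices k0..k1 in
# the stream). Sample 1 of the window is the opening ZVP, where velocity is
# zero by assumption. Integration runs over the M = N - 1 remaining samples:
#
#   a_g(k) = R(k) a_b(k) - g_g                          (gravity removal)
#   v(k)   = v(k-1) + a_g(k) dt                          (velocity update)
#   p(k)   = p(k-1) + v(k-1) dt + 1/2 a_g(k) dt^2        (position update)
#
# A constant body-frame accelerometer bias b and an impulsive heel-strike
# velocity error propagate through these exact updates as
#
#   dv(M)   = La(M) b dt  - [0, 0, v_hs]
#   dpz(M)  = Lv3(M) b dt^2 - (M - khs + 1/2) dt v_hs
#
# where La(k) = sum_j R(j) and Lv(k) = sum_j (La(j) - R(j)/2) are cumulative
# rotation sums and v_hs is the (upward-positive) heel-strike velocity
# correction. The impulse is realized as a single-sample vertical
# acceleration of magnitude v_hs/dt at the heel-strike sample: its in-sample
# position contribution under the stated position update is exactly
# 1/2 v_hs dt, hence the half-step in the height coefficient (a pure
# velocity-discontinuity rendering would use M - khs; the difference is
# v_hs * dt/2, about 8 mm per m/s at 60 Hz, and omitting it breaks the
# exactness of inject-and-recover). On level ground both terminal velocity
# and terminal height of the corrected trajectory are zero, which makes the
# 4x4 system exactly determined.

gravity_vec <- function(g) c(0, 0, g)

#' Remove gravity from one body-frame acceleration sample
#'
#' Rotates a body-frame specific-force measurement to the global frame and
#' subtracts gravity, returning the kinematic acceleration.
#'
#' @param a_b Length-3 body-frame acceleration (m/s^2, gravity-inclusive).
#' @param q Length-4 unit quaternion (body -> global).
#' @param g Gravity magnitude (m/s^2).
#' @return Length-3 global kinematic acceleration.
#' @export
remove_gravity <- function(a_b, q, g = 9.81) {
  drop(quat_to_rotmat(q) %*% a_b) - gravity_vec(g)
}

#' Integrate a stride trajectory from global accelerations
#'
#' Applies the discrete velocity and position updates
#' `v(k) = v(k-1) + a(k) dt` and
#' `p(k) = p(k-1) + v(k-1) dt + a(k) dt^2 / 2` exactly as written (no
#' trapezoidal or higher-order scheme), so that the linear drift algebra of
#' the constraint solves holds to machine precision.
#'
#' @param accel_g M x 3 matrix of global kinematic accelerations, one row
#'   per update step.
#' @param dt Time step (s).
#' @param v0,p0 Initial velocity and position (length 3).
#' @return A list with `v` and `p`, (M+1) x 3 matrices whose first row is
#'   the initial state.
#' @export
integrate_stride <- function(accel_g, dt, v0 = c(0, 0, 0), p0 = c(0, 0, 0)) {
  accel_g <- as_matrix3(accel_g, "accel_g")
  M <- nrow(accel_g)
  if (M == 0L) stop("accel_g must be non-empty")
  if (dt <= 0) stop("dt must be positive")
  v <- matrix(0, M + 1L, 3L)
  p <- matrix(0, M + 1L, 3L)
  v[1L, ] <- v0
  p[1L, ] <- p0
  for (k in seq_len(M)) {
    a <- accel_g[k, ]
    p[k + 1L, ] <- p[k, ] + v[k, ] * dt + 0.5 * a * dt^2
    v[k + 1L, ] <- v[k, ] + a * dt
  }
  list(v = v, p = p)
}

#' Cumulative rotation sums for the drift model
#'
#' Recursively accumulates `La(k) = La(k-1) + R(k)` and
#' `Lv(k) = Lv(k-1) + La(k) - R(k)/2` from `La(0) = Lv(0) = 0`. `La`
#' propagates a constant body-frame bias into terminal velocity drift and
#' `Lv` into terminal position drift.
#'
#' @param rotations List of 3 x 3 rotation matrices, one per update step.
#' @return A list with `La` and `Lv`, each a list of per-step 3 x 3
#'   matrices (the k-th entry holds the sums after k steps).
#' @export
accumulate_sums <- function(rotations) {
  La <- vector("list", length(rotations))
  Lv <- vector("list", length(rotations))
  la <- matrix(0, 3, 3)
  lv <- matrix(0, 3, 3)
  for (k in seq_along(rotations)) {
    R <- rotations[[k]]
    la <- la + R
    lv <- lv + la - 0.5 * R
    La[[k]] <- la
    Lv[[k]] <- lv
  }
  list(La = La, Lv = Lv)
}

# Everything the constraint solves need for one stride: terminal drift,
# rotation sums at the stride end, step count M and heel-strike step index.
stride_drift_state <- function(stride, stream, g = 9.81) {
  if (stride$N < 3L) stop("degenerate stride: too few samples to integrate")
  idx <- (stride$k0 + 1L):stride$k1          # update steps (M = N - 1)
  Rs <- stream_rotations(stream, idx)
  ag <- t(vapply(seq_along(idx),
                 function(j) drop(Rs[[j]] %*% stream$a[idx[j], ]),
                 numeric(3))) -
    matrix(gravity_vec(g), length(idx), 3, byrow = TRUE)
  dt <- 1 / stream$rate_hz
  M <- length(idx)
  sums <- accumulate_sums(Rs)
  traj <- integrate_stride(ag, dt)
  list(
    dv = traj$v[M + 1L, ],
    dpz = traj$p[M + 1L, 3L],
    La = sums$La[[M]],
    Lv3 = sums$Lv[[M]][3L, ],
    M = M,
    khs_step = if (is.na(stride$khs)) NA_integer_ else stride$khs - 1L,
    dt = dt,
    accel_g = ag,
    rotations = Rs
  )
}

#' Terminal drift of an uncorrected stride
#'
#' Integrates the raw (uncorrected) kinematics over a stride from zero
#' initial velocity at the opening ZVP and reports the terminal velocity
#' and terminal height displacement. Under the zero-velocity assumption
#' the terminal velocity is entirely drift; on level ground the terminal
#' height displacement is entirely drift as well.
#'
#' @param stride A [stride_window].
#' @param stream An [imu_stream].
#' @param g Gravity magnitude (m/s^2).
#' @return A list with `dv` (length-3 terminal velocity, m/s) and `dpz`
#'   (terminal height displacement, m).
#' @export
terminal_drift <- function(stride, stream, g = 9.81) {
  st <- stride_drift_state(stride, stream, g)
  list(dv = st$dv, dpz = st$dpz)
}

bias_solution <- function(a_bias, v_error_hs, cond, mode,
                          flags = character()) {
  structure(list(a_bias = a_bias, v_error_hs = v_error_hs, cond = cond,
                 mode = mode, flags = flags),
            class = "bias_solution")
}

#' @export
print.bias_solution <- function(x, ...) {
  cat(sprintf("<bias_solution %s> a_bias=(%.4g, %.4g, %.4g) m/s^2  v_error_hs=%.4g m/s  cond=%.3g\n",
              x$mode, x$a_bias[1], x$a_bias[2], x$a_bias[3], x$v_error_hs, x$cond))
  invisible(x)
}

# 4x4 constraint matrix. The heel-strike column carries a minus sign because
# v_error_hs is the correction added back at k_hs: the signal error it
# cancels is -v_error_hs. The velocity rows of this column act on global z
# only, and the height row carries the half-step in-sample term of the
# acceleration-realized impulse (see the module header).
full_constraint_matrix <- function(La, Lv3, M, khs_step, dt) {
  rbind(cbind(La * dt, -c(0, 0, 1)),
        c(Lv3 * dt^2, -(M - khs_step + 0.5) * dt))
}

#' Solve the full four-unknown stride constraint system
#'
#' Imposes zero terminal velocity (three equations) and zero terminal height
#' change (one equation) on a completed stride, solving jointly for the
#' constant body-frame accelerometer bias and the scalar heel-strike
#' velocity correction. The system is exactly determined; its condition
#' number is returned and checked against `cond_cap`.
#'
#' The heel-strike velocity correction is upward-positive: on ascending
#' terrain the level-ground height constraint attributes the true height
#' gain to a positive correction, which is what makes the parameter usable
#' as an activity classification feature.
#'
#' @param drift List with `dv` and `dpz` as returned by [terminal_drift()].
#' @param La 3 x 3 cumulative rotation sum at the stride end.
#' @param Lv3 Length-3 third row of the cumulative double sum at the stride
#'   end.
#' @param M Number of integration steps in the stride.
#' @param khs_step Heel-strike step index (1-based, must satisfy
#'   `1 < khs_step < M`).
#' @param dt Time step (s).
#' @param cond_cap Condition-number cap; above it the solve aborts with an
#'   error carrying the value.
#' @return A `bias_solution` with `mode = "full"`.
#' @export
solve_full_constraints <- function(drift, La, Lv3, M, khs_step, dt,
                                   cond_cap = 1e8) {
  if (is.na(khs_step) || khs_step <= 1L || khs_step >= M) {
    stop(sprintf("degenerate heel-strike timing: khs_step=%s not in (1, %d)",
                 as.character(khs_step), M))
  }
  A <- full_constraint_matrix(La, Lv3, M, khs_step, dt)
  cond <- kappa(A, exact = TRUE)
  if (!is.finite(cond) || cond > cond_cap) {
    stop(sprintf("ill-conditioned constraint system: condition number %.3g exceeds cap %.3g",
                 cond, cond_cap))
  }
  x <- solve(A, c(drift$dv, drift$dpz))
  bias_solution(a_bias = x[1:3], v_error_hs = x[4], cond = cond, mode = "full")
}

#' Solve the velocity-only stride constraint system
#'
#' Imposes only the zero terminal velocity constraint, solving for the
#' accelerometer bias while leaving natural height changes untouched. Used
#' for ramp and stair strides, where the zero-height-change assumption does
#' not hold. The heel-strike velocity error is identically zero in this
#' mode.
#'
#' @inheritParams solve_full_constraints
#' @return A `bias_solution` with `mode = "velocity_only"`.
#' @export
solve_velocity_only <- function(drift, La, dt, cond_cap = 1e8) {
  A <- La * dt
  cond <- kappa(A, exact = TRUE)
  if (!is.finite(cond) || cond > cond_cap) {
    stop(sprintf("ill-conditioned velocity constraint: condition number %.3g exceeds cap %.3g",
                 cond, cond_cap))
  }
  b <- drop(solve(A, drift$dv))
  bias_solution(a_bias = b, v_error_hs = 0, cond = cond, mode = "velocity_only")
}

#' Reconstruct the corrected trajectory of a stride
#'
#' Applies the estimated accelerometer bias (and, for level-ground strides,
#' the heel-strike velocity correction) and re-integrates the stride:
#' `a_corr(k) = R(k) (a_b(k) - a_bias) - g_g`, with the heel-strike
#' correction applied as a single-sample vertical acceleration of magnitude
#' `v_error_hs/dt` at the heel-strike sample (its integral is the
#' `[0, 0, v_error_hs]` velocity increment of the discrete model). By
#' construction the corrected terminal velocity is zero, and for level
#' strides the terminal height equals the initial height.
#'
#' @param stride A [stride_window] with a detected `khs`.
#' @param stream An [imu_stream].
#' @param sol A `bias_solution`; its mode must match the activity
#'   (`"full"` for `"LEVEL"`, `"velocity_only"` otherwise).
#' @param activity Activity label string (see [activity_labels()]).
#' @param g Gravity magnitude (m/s^2).
#' @param p0 Initial position (global, length 3).
#' @return A list of class `trajectory` with `v` and `p` (N x 3 matrices,
#'   one row per window sample, the first being the opening ZVP) and
#'   `corrected = TRUE`.
#' @export
reconstruct_corrected <- function(stride, stream, sol, activity, g = 9.81,
                                  p0 = c(0, 0, 0)) {
  is_level <- identical(activity, "LEVEL")
  if (is_level && sol$mode != "full") {
    stop("level-ground reconstruction requires a full-constraint solution")
  }
  if (!is_level && sol$mode != "velocity_only") {
    stop("non-level reconstruction requires a velocity-only solution")
  }
  st <- stride_drift_state(stride, stream, g)
  ag <- st$accel_g -
    t(vapply(st$rotations, function(R) drop(R %*% sol$a_bias), numeric(3)))
  if (is_level) {
    ag[st$khs_step, 3] <- ag[st$khs_step, 3] + sol$v_error_hs / st$dt
  }
  traj <- integrate_stride(ag, st$dt, p0 = p0)
  structure(list(v = traj$v, p = traj$p, corrected = TRUE),
            class = "trajectory")
}

#' Reconstruct the raw (uncorrected) trajectory of a stride
#'
#' Plain strapdown integration from zero velocity at the opening ZVP, with
#' no bias or heel-strike correction. Useful as the baseline against which
#' the corrected reconstruction is compared.
#'
#' @inheritParams reconstruct_corrected
#' @return A `trajectory` with `corrected = FALSE`.
#' @export
reconstruct_uncorrected <- function(stride, stream, g = 9.81,
                                    p0 = c(0, 0, 0)) {
  st <- stride_drift_state(stride, stream, g)
  traj <- integrate_stride(st$accel_g, st$dt, p0 = p0)
  structure(list(v = traj$v, p = traj$p, corrected = FALSE),
            class = "trajectory")
}
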