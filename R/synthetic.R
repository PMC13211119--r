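# Synthetic single-IMU gait simulator: ground-truth foot trajectories for
# level walking, ramps and stairs, plus the corrupted body-frame IMU
# measurements a strapdown pipeline would see. The generator is built so
# that a noise-free measured stream is *exactly* consistent with the truth
# under the package's discrete integration scheme, which keeps downstream
# test tolerances meaningful:
#
#   * Per-sample truth velocities are designed first; truth positions are
#     their discrete trapezoid (the position update implies
#     p(k) - p(k-1) = dt (v(k-1) + v(k)) / 2).
#   * Measured acceleration is the exact inverse of gravity removal,
#     a_b(k) = R(k)' ((v(k) - v(k-1))/dt + g_g), plus injected corruption.
#
# Corruption model: a constant body-frame accelerometer bias per stride, a
# single-sample heel-strike acceleration spike whose integral equals the
# modeled velocity discontinuity, and additive Gaussian noise on the
# accelerometer and gyroscope channels. The heel-strike parameter is stated
# in the correction sense (upward-positive, the value the constraint solve
# recovers); the injected signal error is its negative.

activity_geometry_defaults <- list(
  LEVEL         = list(stride_length = 1.30, dh = 0,      apex = 0.09, swing_s = 0.8),
  RAMP_ASCEND   = list(stride_length = 1.20, dh = NA,     apex = 0.16, swing_s = 0.8),
  RAMP_DESCEND  = list(stride_length = 1.20, dh = NA,     apex = 0.07, swing_s = 0.8),
  STAIR_ASCEND  = list(stride_length = 0.68, dh = NA,     apex = 0.40, swing_s = 0.9),
  STAIR_DESCEND = list(stride_length = 0.68, dh = NA,     apex = 0.03, swing_s = 0.9)
)

#' Describe one simulated activity segment
#'
#' Geometry defaults emulate common built environments: 0.17 m stair rise
#' with two steps traversed per steady-state stride (0.34 m tread), a 4
#' degree ramp, and a 1.3 m level stride. Swing apex defaults give maximum
#' stride heights of roughly 0.09 m (level), 0.16 m (ramps) and
#' 0.37-0.40 m (stairs).
#'
#' @param activity One of [activity_labels()].
#' @param n_strides Number of strides in the segment.
#' @param stride_length Horizontal progression per stride (m).
#' @param step_rise Stair step rise (m); ignored off stairs.
#' @param n_steps Steps traversed per stair stride (default 2,
#'   steady-state).
#' @param ramp_slope_deg Ramp inclination (degrees); ignored off ramps.
#' @param swing_apex Peak foot elevation above the stride start (m); must
#'   be at least the net stride rise.
#' @param swing_s Swing duration (s).
#' @param khs_frac Heel-strike timing as a fraction of the swing (0-1);
#'   the scripted foot pitch maximum falls there.
#' @param pitch_push Push-off plantar-flexion pitch extreme (rad,
#'   negative).
#' @param pitch_hs Heel-strike dorsiflexion pitch peak (rad, positive).
#' @return A list of class `sim_segment`.
#' @export
sim_segment <- function(activity, n_strides,
                        stride_length = NULL, step_rise = 0.17, n_steps = 2,
                        ramp_slope_deg = 4, swing_apex = NULL, swing_s = NULL,
                        khs_frac = 0.85,
                        pitch_push = -55 * pi / 180, pitch_hs = 20 * pi / 180) {
  activity <- match.arg(activity, activity_labels())
  def <- activity_geometry_defaults[[activity]]
  if (is.null(stride_length)) stride_length <- def$stride_length
  if (is.null(swing_apex)) swing_apex <- def$apex
  if (is.null(swing_s)) swing_s <- def$swing_s
  dh <- switch(activity,
    LEVEL = 0,
    RAMP_ASCEND = stride_length * tan(ramp_slope_deg * pi / 180),
    RAMP_DESCEND = -stride_length * tan(ramp_slope_deg * pi / 180),
    STAIR_ASCEND = n_steps * step_rise,
    STAIR_DESCEND = -n_steps * step_rise
  )
  if (stride_length <= 0 || swing_s <= 0 || n_strides < 1) {
    stop("segment geometry must be positive")
  }
  if (swing_apex < max(0, dh)) {
    stop(sprintf("inconsistent geometry: swing apex %.3f m below net stride rise %.3f m",
                 swing_apex, dh))
  }
  if (khs_frac <= 0.5 || khs_frac >= 1) {
    stop("khs_frac must lie in (0.5, 1) so the pitch peak falls in late swing")
  }
  structure(list(activity = activity, n_strides = as.integer(n_strides),
                 stride_length = stride_length, dh = dh,
                 swing_apex = swing_apex, swing_s = swing_s,
                 khs_frac = khs_frac, pitch_push = pitch_push,
                 pitch_hs = pitch_hs),
            class = "sim_segment")
}

#' Simulation configuration
#'
#' @param segments A `sim_segment` or list of them, walked in order with
#'   stance-bridged transitions.
#' @param rate_hz Sampling rate (Hz).
#' @param stance_s Foot-flat stance duration between swings (s).
#' @param a_bias Constant body-frame accelerometer bias (length 3, m/s^2),
#'   or an n_strides x 3 matrix of per-stride biases (a per-stride bias
#'   switches at the stance preceding the stride's swing).
#' @param v_error_hs Per-stride heel-strike velocity error (m/s,
#'   correction sense, upward-positive): a single value recycled, a vector
#'   of length n_strides, or `NULL` for the default draw (level strides
#'   from N(0.001, 0.013^2), emulating the near-zero impact error of
#'   level walking; zero on ramps and stairs, where the terrain itself
#'   induces the classifying signature through the constraint solve).
#' @param accel_noise_sd Accelerometer noise sd (m/s^2).
#' @param gyro_noise_sd Gyroscope noise sd (rad/s).
#' @param seed Optional RNG seed recorded in the output metadata.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(segments, rate_hz = 60, stance_s = 0.3,
                       a_bias = c(0, 0, 0), v_error_hs = NULL,
                       accel_noise_sd = 0.03, gyro_noise_sd = 0.01,
                       seed = NULL) {
  if (inherits(segments, "sim_segment")) segments <- list(segments)
  stopifnot(length(segments) >= 1L,
            all(vapply(segments, inherits, logical(1), "sim_segment")),
            rate_hz > 0, stance_s > 0,
            accel_noise_sd >= 0, gyro_noise_sd >= 0)
  structure(list(segments = segments, rate_hz = rate_hz, stance_s = stance_s,
                 a_bias = a_bias, v_error_hs = v_error_hs,
                 accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd, seed = seed),
            class = "sim_config")
}

# Smooth velocity bump with zero value and slope at both ends.
sim_bump <- function(u) sin(pi * u)^2

# Skewed pitch profile over swing, peaking at u_hs with value 1 and a
# push-off trough scaled separately by the caller.
sim_pitch_profile <- function(u, u_hs, pitch_push, pitch_hs) {
  th <- numeric(length(u))
  u_tr <- 0.25  # push-off trough timing (fraction of swing)
  early <- u < u_tr
  th[early] <- pitch_push * sim_bump(u[early] / (2 * u_tr))
  mid <- !early & u < u_hs
  wm <- (u[mid] - u_tr) / (u_hs - u_tr)
  th[mid] <- pitch_push + (pitch_hs - pitch_push) * (0.5 - 0.5 * cos(pi * wm))
  late <- u >= u_hs
  wl <- (u[late] - u_hs) / (1 - u_hs)
  th[late] <- pitch_hs * (0.5 + 0.5 * cos(pi * wl))
  th
}

#' Simulate a gait trial
#'
#' Generates ground-truth foot kinematics and the corresponding corrupted
#' IMU measurement stream for the configured activity segments. The trial
#' is a sequence of foot-flat stance blocks bridged by swing phases; truth
#' velocity is exactly zero throughout every stance, level strides return
#' exactly to their starting height, and each swing carries exactly one
#' scripted pitch maximum (the heel strike).
#'
#' @param cfg A [sim_config].
#' @return A list of class `sim_output` with `measured` (an [imu_stream]
#'   with per-sample activity labels), `truth` (per-sample `t`, `p`, `v`,
#'   `theta`; per-stride data frame `strides`; `stance_intervals` matrix)
#'   and `config`.
#' @export
simulate_trial <- function(cfg) {
  if (!is.null(cfg$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(cfg$seed)
  }
  dt <- 1 / cfg$rate_hz
  n_st <- max(2L, round(cfg$stance_s * cfg$rate_hz))

  strides <- do.call(rbind, lapply(cfg$segments, function(seg) {
    data.frame(activity = rep(seg$activity, seg$n_strides),
               stride_length = seg$stride_length, dh = seg$dh,
               apex = seg$swing_apex, swing_s = seg$swing_s,
               khs_frac = seg$khs_frac, pitch_push = seg$pitch_push,
               pitch_hs = seg$pitch_hs, stringsAsFactors = FALSE)
  }))
  n_strides <- nrow(strides)

  bias <- cfg$a_bias
  if (is.null(dim(bias))) {
    bias <- matrix(rep(as.numeric(bias), each = n_strides), n_strides, 3)
  }
  stopifnot(nrow(bias) == n_strides, ncol(bias) == 3)
  v_hs <- cfg$v_error_hs
  if (is.null(v_hs)) {
    v_hs <- ifelse(strides$activity == "LEVEL",
                   stats::rnorm(n_strides, 0.001, 0.013), 0)
  }
  v_hs <- rep_len(as.numeric(v_hs), n_strides)

  # ---- truth assembly, stride by stride -------------------------------
  vel <- list()          # per-block velocity rows
  theta <- list()
  seg_of <- list()       # stride index owning each block (0 = leading stance)
  vel[[1]] <- matrix(0, n_st, 3)
  theta[[1]] <- numeric(n_st)
  seg_of[[1]] <- rep(1L, n_st)
  stance_start <- integer(n_strides + 1L)
  stance_start[1L] <- 1L
  swing_start <- integer(n_strides)
  khs_global <- integer(n_strides)
  n_acc <- n_st

  for (i in seq_len(n_strides)) {
    s <- strides[i, ]
    n_sw <- max(8L, round(s$swing_s * cfg$rate_hz))
    u <- seq_len(n_sw) / (n_sw + 1)
    b1 <- ifelse(u < 0.5, sim_bump(u / 0.5), 0)
    b2 <- ifelse(u >= 0.5, sim_bump((u - 0.5) / 0.5), 0)
    bx <- sim_bump(u)
    # net displacement from stance i to stance i+1 is exactly dt * sum(v)
    A <- if (sum(b1) > 0) s$apex / (dt * sum(b1)) else 0
    B <- (A * dt * sum(b1) - s$dh) / (dt * sum(b2))
    v_sw <- cbind(bx * s$stride_length / (dt * sum(bx)), 0, A * b1 - B * b2)
    th_sw <- sim_pitch_profile(u, s$khs_frac, s$pitch_push, s$pitch_hs)

    swing_start[i] <- n_acc + 1L
    khs_global[i] <- n_acc + which.max(th_sw)
    vel[[2L * i]] <- v_sw
    theta[[2L * i]] <- th_sw
    seg_of[[2L * i]] <- rep(i, n_sw)
    n_acc <- n_acc + n_sw
    vel[[2L * i + 1L]] <- matrix(0, n_st, 3)
    theta[[2L * i + 1L]] <- numeric(n_st)
    seg_of[[2L * i + 1L]] <- rep(min(i + 1L, n_strides), n_st)
    stance_start[i + 1L] <- n_acc + 1L
    n_acc <- n_acc + n_st
  }

  v <- do.call(rbind, vel)
  th <- unlist(theta)
  stride_of <- unlist(seg_of)
  n <- nrow(v)
  t <- (seq_len(n) - 1L) * dt
  # position = discrete trapezoid of velocity (exact under the position
  # update); acceleration = forward difference (exact under the velocity
  # update)
  vprev <- rbind(0, v[-n, , drop = FALSE])
  p <- apply(dt * (vprev + v) / 2, 2, cumsum)
  a_g <- (v - vprev) / dt
  omega_x <- c(0, diff(th)) / dt
  q <- cbind(cos(th / 2), sin(th / 2), 0, 0)

  # ---- measurement synthesis ------------------------------------------
  g_g <- gravity_vec(9.81)
  a_b <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    R <- quat_to_rotmat(q[k, ])
    a_b[k, ] <- drop(crossprod(R, a_g[k, ] + g_g))
  }
  a_b <- a_b + bias[stride_of, , drop = FALSE]
  for (i in seq_len(n_strides)) {
    if (v_hs[i] != 0) {
      k <- khs_global[i]
      R <- quat_to_rotmat(q[k, ])
      a_b[k, ] <- a_b[k, ] + drop(crossprod(R, c(0, 0, -v_hs[i] / dt)))
    }
  }
  w_b <- cbind(omega_x, 0, 0)
  if (cfg$accel_noise_sd > 0) {
    a_b <- a_b + matrix(stats::rnorm(3 * n, 0, cfg$accel_noise_sd), n, 3)
  }
  if (cfg$gyro_noise_sd > 0) {
    w_b <- w_b + matrix(stats::rnorm(3 * n, 0, cfg$gyro_noise_sd), n, 3)
  }

  measured <- imu_stream(
    t = t, a = a_b, w = w_b, q = q, rate_hz = cfg$rate_hz,
    label = activity_to_code(strides$activity)[stride_of],
    meta = list(generator = "simulate_trial", seed = cfg$seed)
  )
  stride_df <- data.frame(
    stride = seq_len(n_strides),
    activity = strides$activity,
    stance_start = stance_start[seq_len(n_strides)],
    swing_start = swing_start,
    next_stance_start = stance_start[-1L],
    khs = khs_global,
    dh = strides$dh,
    apex = strides$apex,
    stride_length = strides$stride_length,
    bias_x = bias[, 1], bias_y = bias[, 2], bias_z = bias[, 3],
    v_error_hs = v_hs,
    stringsAsFactors = FALSE
  )
  stance_intervals <- cbind(
    start = stance_start,
    end = c(swing_start - 1L, n)
  )
  structure(list(
    measured = measured,
    truth = list(t = t, p = p, v = v, theta = th,
                 strides = stride_df, stance_intervals = stance_intervals),
    config = cfg
  ), class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %d strides, %d samples @ %g Hz, activities: %s\n",
              nrow(x$truth$strides), n_samples(x$measured),
              x$measured$rate_hz,
              paste(unique(x$truth$strides$activity), collapse = ", ")))
  invisible(x)
}

#' Simulate a closed walking loop
#'
#' Convenience wrapper over [simulate_trial()] for multi-segment courses
#' (e.g. level - stairs up - level - stairs down - level). By default the
#' configured segments must return the net height to zero.
#'
#' @param segments List of [sim_segment()]s walked in order.
#' @param ... Passed to [sim_config()].
#' @param allow_open If `FALSE` (default), error when the segments do not
#'   close the height loop.
#' @return A `sim_output`.
#' @export
simulate_loop <- function(segments, ..., allow_open = FALSE) {
  net <- sum(vapply(segments, function(s) s$dh * s$n_strides, numeric(1)))
  if (!allow_open && abs(net) > 1e-9) {
    stop(sprintf("segments do not close the height loop (net %.3f m); set allow_open = TRUE to keep",
                 net))
  }
  simulate_trial(sim_config(segments, ...))
}

#' Write simulation ground truth to JSON
#'
#' @param sim A `sim_output`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(sim, path) {
  jsonlite::write_json(
    list(strides = sim$truth$strides,
         stance_intervals = as.data.frame(sim$truth$stance_intervals),
         rate_hz = sim$measured$rate_hz,
         seed = sim$config$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}
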