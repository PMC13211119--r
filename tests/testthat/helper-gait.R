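# Shared fixtures: random orientations and a one-stop stride processor used
# across the module tests.

random_unit_quat <- function(n = 1) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# Independent quaternion -> direction-cosine oracle: the explicit 9-term
# expansion, written out separately from the package's implementation.
quat_to_rotmat_oracle <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * x * y - 2 * w * z, 2 * x * z + 2 * w * y),
    c(2 * x * y + 2 * w * z, w^2 - x^2 + y^2 - z^2, 2 * y * z - 2 * w * x),
    c(2 * x * z - 2 * w * y, 2 * y * z + 2 * w * x, w^2 - x^2 - y^2 + z^2)
  )
}

# Simulate one clean-orientation trial and run segmentation + heel-strike
# detection on the first stride, returning everything the solver needs.
sim_one_stride <- function(activity = "LEVEL", a_bias = c(0, 0, 0),
                           v_error_hs = 0, accel_noise_sd = 0,
                           gyro_noise_sd = 0, seed = NULL, ...) {
  sim <- simulate_trial(sim_config(
    sim_segment(activity, n_strides = 1, ...),
    a_bias = a_bias, v_error_hs = v_error_hs,
    accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
    seed = seed))
  zv <- detect_zvp(sim$measured)
  stopifnot(length(zv) >= 2)
  win <- stride_window(zv[1], zv[2])
  pitch <- pitch_from_quaternion(sim$measured$q[win$k0:win$k1, , drop = FALSE])
  win$khs <- detect_heel_strike(as.numeric(pitch))
  st <- zhcgait:::stride_drift_state(win, sim$measured)
  list(sim = sim, stream = sim$measured, win = win, st = st,
       drift = list(dv = st$dv, dpz = st$dpz))
}

solve_full_of <- function(x, ...) {
  solve_full_constraints(x$drift, x$st$La, x$st$Lv3, x$st$M, x$st$khs_step,
                         x$st$dt, ...)
}

solve_vonly_of <- function(x, ...) {
  solve_velocity_only(x$drift, x$st$La, x$st$dt, ...)
}
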