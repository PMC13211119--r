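test_that("gravity removal maps stationary and rotated poses correctly", {
  qi <- c(1, 0, 0, 0)
  expect_equal(remove_gravity(c(0, 0, 9.81), qi), c(0, 0, 0))
  expect_equal(remove_gravity(c(1, 0, 9.81), qi), c(1, 0, 0))
  # 90 degrees about x: body y points up, so gravity reads on body y
  qx90 <- c(cos(pi / 4), sin(pi / 4), 0, 0)
  expect_equal(remove_gravity(c(0, 9.81, 0), qx90), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("stride integration follows the discrete update equations exactly", {
  z <- integrate_stride(matrix(0, 10, 3), dt = 1 / 60, p0 = c(1, 2, 3))
  expect_true(all(z$v == 0))
  expect_true(all(abs(sweep(z$p, 2, c(1, 2, 3))) == 0))

  one <- integrate_stride(matrix(c(0, 0, 1), 1, 3), dt = 1)
  expect_equal(one$v[2, ], c(0, 0, 1))
  expect_equal(one$p[2, ], c(0, 0, 0.5))

  # independent per-step loop oracle
  set.seed(3)
  a <- matrix(rnorm(150), 50, 3)
  dt <- 1 / 60
  got <- integrate_stride(a, dt, v0 = c(0.1, 0, -0.2), p0 = c(1, 1, 1))
  v <- c(0.1, 0, -0.2); p <- c(1, 1, 1)
  for (k in 1:50) {
    p <- p + v * dt + 0.5 * a[k, ] * dt^2
    v <- v + a[k, ] * dt
  }
  expect_equal(got$v[51, ], v, tolerance = 1e-12)
  expect_equal(got$p[51, ], p, tolerance = 1e-12)
})

test_that("recursive rotation sums match their definitional form", {
  one <- accumulate_sums(list(diag(3)))
  expect_equal(one$La[[1]], diag(3))
  expect_equal(one$Lv[[1]], 0.5 * diag(3))

  three <- accumulate_sums(rep(list(diag(3)), 3))
  expect_equal(three$La[[3]], 3 * diag(3))
  expect_equal(three$Lv[[3]], 4.5 * diag(3))  # k^2/2 closed form

  set.seed(5)
  Rs <- lapply(1:30, function(i) quat_to_rotmat(drop(random_unit_quat())))
  got <- accumulate_sums(Rs)
  for (k in c(1, 7, 30)) {
    La_def <- Reduce(`+`, Rs[1:k])
    Lv_def <- Reduce(`+`, lapply(1:k, function(j) {
      Reduce(`+`, Rs[1:j]) - 0.5 * Rs[[j]]
    }))
    expect_equal(got$La[[k]], La_def, tolerance = 1e-12)
    expect_equal(got$Lv[[k]], Lv_def, tolerance = 1e-12)
  }
})

test_that("terminal drift isolates injected bias and impulse", {
  clean <- sim_one_stride("LEVEL")
  expect_lt(max(abs(clean$drift$dv)), 1e-10)
  expect_lt(abs(clean$drift$dpz), 1e-10)

  b <- c(0.03, -0.02, 0.05)
  biased <- sim_one_stride("LEVEL", a_bias = b)
  drift <- terminal_drift(biased$win, biased$stream)
  # forward model: dv = La(N) b dt
  expect_equal(drift$dv, drop(biased$st$La %*% b) * biased$st$dt,
               tolerance = 1e-9)

  # raw vertical acceleration spike of integral +v at step khs
  v <- 0.2
  x <- sim_one_stride("LEVEL")
  stream <- x$stream
  k_global <- x$win$k0 + x$win$khs - 1L
  R <- quat_to_rotmat(stream$q[k_global, ])
  stream$a[k_global, ] <- stream$a[k_global, ] +
    drop(crossprod(R, c(0, 0, v / x$st$dt)))
  drift2 <- terminal_drift(x$win, stream)
  expect_equal(drift2$dv, c(0, 0, v), tolerance = 1e-9)
  # position gains 1/2 v dt at the spike sample plus v dt per later step
  expect_equal(drift2$dpz, v * (x$st$M - x$st$khs_step + 0.5) * x$st$dt,
               tolerance = 1e-9)
})

test_that("full constraint solve recovers injected bias and impulse exactly", {
  zero <- sim_one_stride("LEVEL")
  s0 <- solve_full_of(zero)
  expect_lt(max(abs(s0$a_bias)), 1e-10)
  expect_lt(abs(s0$v_error_hs), 1e-10)
  expect_gte(s0$cond, 1)

  b <- c(0.02, -0.01, 0.03); v <- 0.15
  x <- sim_one_stride("LEVEL", a_bias = b, v_error_hs = v)
  sol <- solve_full_of(x)
  expect_equal(sol$a_bias, b, tolerance = 1e-9)
  expect_equal(sol$v_error_hs, v, tolerance = 1e-9)

  # generic least-squares route agrees with the direct solve
  A <- zhcgait:::full_constraint_matrix(x$st$La, x$st$Lv3, x$st$M,
                                        x$st$khs_step, x$st$dt)
  ls <- qr.coef(qr(A), c(x$drift$dv, x$drift$dpz))
  expect_equal(unname(ls), c(sol$a_bias, sol$v_error_hs), tolerance = 1e-10)

  expect_error(
    solve_full_constraints(x$drift, x$st$La, x$st$Lv3, x$st$M,
                           khs_step = x$st$M, dt = x$st$dt),
    "degenerate heel-strike")
  expect_error(
    solve_full_constraints(x$drift, x$st$La, x$st$Lv3, x$st$M,
                           x$st$khs_step, x$st$dt, cond_cap = 1),
    "ill-conditioned")
})

test_that("velocity-only solve recovers bias and shows the ZUPT height residual", {
  b <- c(0.04, 0.01, -0.02)
  stair <- sim_one_stride("STAIR_ASCEND", a_bias = b)
  sv <- solve_vonly_of(stair)
  expect_equal(sv$a_bias, b, tolerance = 1e-9)
  expect_identical(sv$v_error_hs, 0)
  expect_identical(sv$mode, "velocity_only")

  # level stride with impulse, corrected velocity-only: terminal velocity is
  # zero but the height does not return to its start (the ZUPT failure mode)
  lvl <- sim_one_stride("LEVEL", a_bias = c(0.02, 0, 0.01), v_error_hs = 0.2)
  sv2 <- solve_vonly_of(lvl)
  tr <- reconstruct_corrected(lvl$win, lvl$stream, sv2, "RAMP_ASCEND")
  N <- nrow(tr$p)
  expect_lt(max(abs(tr$v[N, ])), 1e-9)
  expect_gt(abs(tr$p[N, 3] - tr$p[1, 3]), 0.01)
})

test_that("corrected reconstruction enforces the stride constraints", {
  x <- sim_one_stride("LEVEL", a_bias = c(0.02, -0.01, 0.03),
                      v_error_hs = 0.15)
  tr <- reconstruct_corrected(x$win, x$stream, solve_full_of(x), "LEVEL")
  N <- nrow(tr$p)
  expect_lt(max(abs(tr$v[N, ])), 1e-9)
  expect_lt(abs(tr$p[N, 3] - tr$p[1, 3]), 1e-9)

  # clean stair-ascent stride over two 0.17 m steps, velocity-only
  st <- sim_one_stride("STAIR_ASCEND")
  tr2 <- reconstruct_corrected(st$win, st$stream, solve_vonly_of(st),
                               "STAIR_ASCEND")
  expect_equal(tr2$p[nrow(tr2$p), 3] - tr2$p[1, 3], 0.34, tolerance = 1e-3)

  # clean signal: corrected trajectory equals simulator ground truth
  cl <- sim_one_stride("LEVEL")
  tr3 <- reconstruct_corrected(cl$win, cl$stream, solve_full_of(cl), "LEVEL")
  truth <- cl$sim$truth$p[cl$win$k0:cl$win$k1, ]
  truth <- sweep(truth, 2, truth[1, ])
  expect_lt(max(abs(tr3$p - truth)), 1e-6)

  # mode/activity contract
  expect_error(reconstruct_corrected(st$win, st$stream, solve_vonly_of(st),
                                     "LEVEL"),
               "full-constraint")
  expect_error(reconstruct_corrected(x$win, x$stream, solve_full_of(x),
                                     "STAIR_ASCEND"),
               "velocity-only")
})

test_that("constraint system stays well-conditioned across activities", {
  for (act in activity_labels()) {
    x <- sim_one_stride(act, accel_noise_sd = 0.03, gyro_noise_sd = 0.01,
                        seed = 17)
    sol <- solve_full_of(x)
    expect_true(is.finite(sol$cond))
    expect_lt(sol$cond, 1e6)
  }
})

test_that("bias recovery error under noise shrinks like 1/sqrt(N)", {
  # Monte-Carlo over stride lengths: log-log slope of rms bias error vs
  # stride sample count should be near -1/2
  set.seed(29)
  rate <- 60
  b <- c(0.02, -0.01, 0.03)
  sizes <- c(30, 60, 120)
  rms <- vapply(sizes, function(M) {
    err <- replicate(500, {
      n <- M + 1L
      a_b <- matrix(c(0, 0, 9.81), n, 3, byrow = TRUE) +
        matrix(b, n, 3, byrow = TRUE) +
        matrix(rnorm(3 * n, sd = 0.05), n, 3)
      stream <- imu_stream(
        t = (0:(n - 1)) / rate, a = a_b, w = matrix(0, n, 3),
        q = matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE), rate_hz = rate)
      win <- stride_window(1L, n)
      drift <- terminal_drift(win, stream)
      sol <- solve_velocity_only(drift, M * diag(3), 1 / rate)
      sqrt(mean((sol$a_bias - b)^2))
    })
    sqrt(mean(err^2))
  }, numeric(1))
  slope <- coef(lm(log(rms) ~ log(sizes)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})
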