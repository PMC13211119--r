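# Per-activity heel-strike velocity error distributions typical of adult
# gait, used as the generating model for classifier tests: near zero on
# level ground, moderate positive/negative on ramps, large on stairs.
hs_error_params <- data.frame(
  activity = c("LEVEL", "RAMP_ASCEND", "RAMP_DESCEND",
               "STAIR_ASCEND", "STAIR_DESCEND"),
  mean = c(0.001, 0.173, -0.193, 0.590, -0.740),
  sd = c(0.013, 0.019, 0.038, 0.109, 0.129),
  stringsAsFactors = FALSE
)

draw_hs_errors <- function(n_per_class) {
  v <- unlist(lapply(seq_len(nrow(hs_error_params)), function(i) {
    rnorm(n_per_class, hs_error_params$mean[i], hs_error_params$sd[i])
  }))
  list(v = v, labels = rep(hs_error_params$activity, each = n_per_class))
}

test_that("baseline calibration applies the IQR-median / scaled-MAD recipe", {
  expect_error(calibrate_baseline(c(0, 0, 0)), "at least 4")

  cal <- calibrate_baseline(rep(0.02, 10))
  expect_equal(cal$mu_hs, 0.02)
  expect_equal(cal$sigma_hs, 0)

  # step-by-step definitional oracle on a small list with an outlier
  v <- c(-0.02, -0.01, 0.00, 0.01, 0.02, 0.30)
  av <- abs(v)
  qs <- quantile(av, c(0.25, 0.75), names = FALSE, type = 7)
  sel <- v[av >= qs[1] & av <= qs[2]]
  mu_o <- median(sel)
  sig_o <- 1.4826 * median(abs(v - mu_o))
  cal2 <- calibrate_baseline(v)
  expect_identical(cal2$mu_hs, mu_o)
  expect_identical(cal2$sigma_hs, sig_o)
  # the 0.30 outlier is excluded from the baseline median
  expect_lt(abs(cal2$mu_hs), 0.02)

  # large Gaussian sample from level-walking parameters: the magnitude-IQR
  # baseline median carries a small inherent bias (a fraction of the sd) on
  # near-symmetric data, since the baseline set excludes the smallest
  # magnitudes; the spread estimate is consistent
  set.seed(31)
  g <- rnorm(1e4, 0.001, 0.013)
  cal3 <- calibrate_baseline(g)
  expect_lt(abs(cal3$mu_hs - 0.001), 0.5 * 0.013)
  expect_lt(abs(cal3$sigma_hs - 0.013) / 0.013, 0.05)

  # 1.4826 * MAD converges to the sd for Gaussian data
  set.seed(37)
  z <- rnorm(1e5)
  expect_equal(1.4826 * median(abs(z - median(z))), 1, tolerance = 0.02)
})

test_that("threshold construction and ordering", {
  th <- build_thresholds(0, 1, k1 = 2, k2 = 5)
  expect_equal(unlist(th), c(t_ramp_up = 2, t_stair_up = 5,
                             t_ramp_dn = -2, t_stair_dn = -5))
  th2 <- build_thresholds(0.001, 0.013, 3, 15)
  expect_equal(th2$t_ramp_up, 0.040)
  expect_equal(th2$t_stair_up, 0.196)
  expect_error(build_thresholds(0, 1, 5, 2), "k2 > k1")

  # degenerate zero spread: every threshold collapses to the baseline
  th0 <- build_thresholds(0.01, 0, 1, 2)
  expect_true(all(unlist(th0) == 0.01))
  expect_identical(classify_stride(0.01, th0), "LEVEL")
  expect_identical(classify_stride(0.02, th0), "STAIR_ASCEND")
})

test_that("classification bands partition the line and respect boundaries", {
  th <- build_thresholds(0.001, 0.013, k1 = 6, k2 = 25)
  expect_identical(classify_stride(0, th), "LEVEL")
  expect_identical(classify_stride(0.59, th), "STAIR_ASCEND")
  expect_identical(classify_stride(-0.193, th), "RAMP_DESCEND")
  # boundary values fall toward the less extreme activity
  expect_identical(classify_stride(th$t_ramp_up, th), "LEVEL")
  expect_identical(classify_stride(th$t_stair_up, th), "RAMP_ASCEND")
  expect_identical(classify_stride(th$t_ramp_dn, th), "LEVEL")
  expect_identical(classify_stride(th$t_stair_dn, th), "RAMP_DESCEND")

  # partition: exactly one label for any input
  set.seed(41)
  v <- c(rnorm(500, 0, 0.5), unlist(th))
  labs <- classify_stride(v, th)
  expect_true(all(labs %in% activity_labels()))

  # monotone in the order SD < RD < LEVEL < RA < SA
  ord <- c(STAIR_DESCEND = 1, RAMP_DESCEND = 2, LEVEL = 3,
           RAMP_ASCEND = 4, STAIR_ASCEND = 5)
  expect_true(all(diff(ord[classify_stride(sort(v), th)]) >= 0))
})

test_that("grid search maximizes accuracy and matches an exhaustive oracle", {
  # perfectly separated two-point masses at the per-activity means, with a
  # level-class spread on the usual gait scale so the separating bands fall
  # inside the multiplier grid
  pm <- rep(hs_error_params$mean, each = 8)
  pm_lab <- rep(hs_error_params$activity, each = 8)
  jit <- pm + rep(c(-1, 1) * 0.013, length.out = length(pm))
  opt <- optimize_thresholds(jit, pm_lab)
  expect_equal(opt$accuracy, 1)

  # single-class level set: trivially perfect
  set.seed(43)
  lv <- rnorm(30, 0.001, 0.013)
  expect_equal(optimize_thresholds(lv, rep("LEVEL", 30))$accuracy, 1)

  expect_error(optimize_thresholds(1:5, rep("STAIR_ASCEND", 5)),
               "level-ground")

  # five-class Gaussian set against a brute-force oracle over the same grid
  set.seed(47)
  d <- draw_hs_errors(60)
  k1g <- seq(1, 8, by = 1); k2g <- seq(10, 30, by = 2)
  opt2 <- optimize_thresholds(d$v, d$labels, k1g, k2g)
  cal <- calibrate_baseline(d$v[d$labels == "LEVEL"])
  best <- c(NA, NA, -Inf)
  for (k1 in k1g) for (k2 in k2g) {
    if (k2 <= k1) next
    th <- build_thresholds(cal$mu_hs, cal$sigma_hs, k1, k2)
    acc <- mean(classify_stride(d$v - cal$mu_hs, th) == d$labels)
    if (acc > best[3]) best <- c(k1, k2, acc)
  }
  expect_equal(c(opt2$k1, opt2$k2, opt2$accuracy), best)
})

test_that("calibration parameters survive a JSON round trip", {
  p <- list(mu_hs = 0.0012, sigma_hs = 0.0131, k1 = 8, k2 = 30, w_init = 20)
  path <- withr::local_tempfile(fileext = ".json")
  save_calibration(p, path)
  back <- load_calibration(path)
  expect_equal(back[c("mu_hs", "sigma_hs", "k1", "k2")],
               p[c("mu_hs", "sigma_hs", "k1", "k2")])
  expect_equal(back$thresholds,
               build_thresholds(p$mu_hs, p$sigma_hs, p$k1, p$k2))
})

test_that("activity codes round-trip through their labels", {
  expect_identical(activity_from_code(0:4), activity_labels())
  expect_identical(activity_to_code(activity_labels()), 0:4)
  expect_error(activity_from_code(7), "0..4")
  expect_error(activity_to_code("JUMP"), "unknown")
})
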