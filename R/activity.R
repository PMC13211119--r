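# Adaptive five-class locomotion activity recognition from the per-stride
# heel-strike velocity error: robust baseline calibration (IQR-median +
# scaled MAD), multiplier-based thresholds, band classification, and grid
# search over the multipliers.

#' Activity labels
#'
#' The closed set of locomotion activities, in the order of their integer
#' serialization codes 0..4 (level ground, ramp ascend, ramp descend, stair
#' ascend, stair descend).
#'
#' @return Character vector of the five labels.
#' @export
activity_labels <- function() {
  c("LEVEL", "RAMP_ASCEND", "RAMP_DESCEND", "STAIR_ASCEND", "STAIR_DESCEND")
}

#' Convert activity codes to labels and back
#'
#' @param code Integer vector of codes in 0..4.
#' @return `activity_from_code`: character labels; `activity_to_code`:
#'   integer codes.
#' @export
activity_from_code <- function(code) {
  labs <- activity_labels()
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 0L | code > 4L)) {
    stop("activity codes must be integers in 0..4")
  }
  labs[code + 1L]
}

#' @rdname activity_from_code
#' @param label Character vector of activity labels.
#' @export
activity_to_code <- function(label) {
  m <- match(label, activity_labels())
  if (any(is.na(m))) {
    stop(sprintf("unknown activity label(s): %s",
                 paste(unique(label[is.na(m)]), collapse = ", ")))
  }
  m - 1L
}

#' Calibrate the level-ground baseline of the heel-strike velocity error
#'
#' Robust two-stage baseline: strides whose absolute heel-strike velocity
#' error lies between the 25th and 75th percentiles of the absolute errors
#' (inclusive; linear interpolation between order statistics) form the
#' baseline set, and `mu_hs` is the median of the signed errors over that
#' set. Deviations from `mu_hs` over all strides give the median absolute
#' deviation, scaled by 1.4826 (the Gaussian consistency factor
#' `1/qnorm(0.75)`) into the robust spread `sigma_hs`.
#'
#' @param v_errors Numeric vector of per-stride heel-strike velocity errors
#'   (m/s) from an initial bout of level-ground walking; at least 4 strides.
#' @return A list with `mu_hs` and `sigma_hs` (m/s).
#' @export
calibrate_baseline <- function(v_errors) {
  v_errors <- as.numeric(v_errors)
  if (length(v_errors) < 4L || any(!is.finite(v_errors))) {
    stop("calibration requires at least 4 finite heel-strike velocity errors")
  }
  av <- abs(v_errors)
  qs <- stats::quantile(av, c(0.25, 0.75), names = FALSE, type = 7)
  in_iqr <- av >= qs[1] & av <= qs[2]
  mu_hs <- stats::median(v_errors[in_iqr])
  vhat <- v_errors - mu_hs
  sigma_hs <- 1.4826 * stats::median(abs(vhat))
  list(mu_hs = mu_hs, sigma_hs = sigma_hs)
}

#' Build the four classification thresholds
#'
#' Ramp and stair boundaries on each side of the baseline:
#' `T_ramp+/- = mu_hs +/- k1 sigma_hs`, `T_stair+/- = mu_hs +/- k2 sigma_hs`
#' with `k2 > k1 > 0`.
#'
#' @param mu_hs Baseline heel-strike velocity error (m/s).
#' @param sigma_hs Robust spread (m/s, non-negative).
#' @param k1,k2 Threshold multipliers, `k2 > k1 > 0`.
#' @return A list with `t_ramp_up`, `t_stair_up`, `t_ramp_dn`, `t_stair_dn`.
#' @export
build_thresholds <- function(mu_hs, sigma_hs, k1, k2) {
  if (!(k2 > k1 && k1 > 0)) stop("threshold multipliers must satisfy k2 > k1 > 0")
  if (sigma_hs < 0) stop("sigma_hs must be non-negative")
  list(
    t_ramp_up = mu_hs + k1 * sigma_hs,
    t_stair_up = mu_hs + k2 * sigma_hs,
    t_ramp_dn = mu_hs - k1 * sigma_hs,
    t_stair_dn = mu_hs - k2 * sigma_hs
  )
}

#' Classify strides by normalized heel-strike velocity error
#'
#' Band rule: values above the stair-ascent threshold are stair ascent,
#' values between the ramp- and stair-ascent thresholds are ramp ascent,
#' the central band is level ground, and symmetrically for descent. A value
#' exactly on a threshold is assigned to the band closer to level ground
#' (ties favor the less extreme activity).
#'
#' @param v_hat Numeric vector of normalized heel-strike velocity errors
#'   (m/s), i.e. raw errors minus `mu_hs`.
#' @param thresholds A list as returned by [build_thresholds()].
#' @return Character vector of activity labels.
#' @export
classify_stride <- function(v_hat, thresholds) {
  th <- thresholds
  if (!(th$t_stair_up >= th$t_ramp_up && th$t_ramp_up >= th$t_ramp_dn &&
        th$t_ramp_dn >= th$t_stair_dn)) {
    stop("thresholds must be ordered t_stair_dn <= t_ramp_dn <= t_ramp_up <= t_stair_up")
  }
  out <- character(length(v_hat))
  out[v_hat > th$t_stair_up] <- "STAIR_ASCEND"
  out[v_hat <= th$t_stair_up & v_hat > th$t_ramp_up] <- "RAMP_ASCEND"
  out[v_hat <= th$t_ramp_up & v_hat >= th$t_ramp_dn] <- "LEVEL"
  out[v_hat < th$t_ramp_dn & v_hat >= th$t_stair_dn] <- "RAMP_DESCEND"
  out[v_hat < th$t_stair_dn] <- "STAIR_DESCEND"
  out
}

#' Grid-search the threshold multipliers on labeled strides
#'
#' Calibrates `(mu_hs, sigma_hs)` on the level-labeled subset, then
#' exhaustively evaluates stride-level classification accuracy for every
#' `(k1, k2)` pair on the grid with `k2 > k1`, classifying the normalized
#' errors of all strides. Ties are broken toward the smallest `k1`, then
#' the smallest `k2`.
#'
#' @param v_errors Numeric vector of per-stride heel-strike velocity errors
#'   (m/s).
#' @param labels Character vector of true activity labels (same length).
#' @param k1_grid,k2_grid Numeric candidate grids (defaults: 0.5 to 10 by
#'   0.5, and 2 to 40 by 1).
#' @return A list with `k1`, `k2`, `accuracy`, plus the calibration
#'   (`mu_hs`, `sigma_hs`) and the winning `thresholds`.
#' @export
optimize_thresholds <- function(v_errors, labels,
                                k1_grid = seq(0.5, 10, by = 0.5),
                                k2_grid = seq(2, 40, by = 1)) {
  if (length(v_errors) != length(labels)) {
    stop("v_errors and labels must have equal length")
  }
  labels <- as.character(labels)
  if (!any(labels == "LEVEL")) {
    stop("calibration requires level-ground strides in the labeled set")
  }
  cal <- calibrate_baseline(v_errors[labels == "LEVEL"])
  v_hat <- v_errors - cal$mu_hs
  best <- list(k1 = NA_real_, k2 = NA_real_, accuracy = -Inf)
  for (k1 in sort(k1_grid)) {
    for (k2 in sort(k2_grid)) {
      if (k2 <= k1) next
      th <- build_thresholds(cal$mu_hs, cal$sigma_hs, k1, k2)
      acc <- mean(classify_stride(v_hat, th) == labels)
      if (acc > best$accuracy) best <- list(k1 = k1, k2 = k2, accuracy = acc)
    }
  }
  if (!is.finite(best$accuracy)) stop("empty multiplier grid (need k2 > k1)")
  c(best, cal,
    list(thresholds = build_thresholds(cal$mu_hs, cal$sigma_hs,
                                       best$k1, best$k2)))
}

#' Save or load calibration parameters
#'
#' Serializes the baseline, spread, multipliers and thresholds to a JSON
#' sidecar for reuse across runs.
#'
#' @param params List with at least `mu_hs`, `sigma_hs`, `k1`, `k2`.
#' @param path JSON file path.
#' @return `save_calibration`: `path`, invisibly. `load_calibration`: the
#'   parameter list with thresholds rebuilt.
#' @export
save_calibration <- function(params, path) {
  keep <- intersect(c("mu_hs", "sigma_hs", "k1", "k2", "w_init"),
                    names(params))
  jsonlite::write_json(params[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$thresholds <- build_thresholds(p$mu_hs, p$sigma_hs, p$k1, p$k2)
  p
}
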