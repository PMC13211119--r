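# Streaming stride-by-stride orchestration: ZVP segmentation, heel-strike
# detection, constraint solves, baseline calibration, activity
# classification, activity-conditioned reconstruction, stride metrics and
# cumulative height accounting.

#' Pipeline configuration
#'
#' Nested defaults for the full processing pipeline. Any subset can be
#' overridden; see [zvp_config()] for the detector parameters.
#'
#' @param zvp A [zvp_config()].
#' @param k1,k2 Classification threshold multipliers (k2 > k1 > 0).
#' @param w_init Number of level-ground calibration strides before
#'   classification starts.
#' @param g Gravity magnitude (m/s^2).
#' @param cond_cap Condition-number cap above which a full solve falls back
#'   to the velocity-only solve (flagged).
#' @param min_stride_samples Minimum stride window length (samples).
#' @param toe_d IMU-to-toe distance (m) for toe metrics, or `NULL` to skip.
#' @return A list of class `gait_config`.
#' @export
gait_config <- function(zvp = zvp_config(), k1 = 8, k2 = 30, w_init = 20L,
                        g = 9.81, cond_cap = 1e8,
                        min_stride_samples = zvp$min_stride_samples,
                        toe_d = NULL) {
  stopifnot(k2 > k1, k1 > 0, w_init >= 4L, g > 0, cond_cap > 1)
  structure(list(zvp = zvp, k1 = k1, k2 = k2, w_init = as.integer(w_init),
                 g = g, cond_cap = cond_cap,
                 min_stride_samples = as.integer(min_stride_samples),
                 toe_d = toe_d),
            class = "gait_config")
}

#' Read a pipeline configuration file
#'
#' Accepts YAML or JSON with sections `zvp` (`ta`, `tw`, `wcap`, `tmax`,
#' `min_stride_samples`), `classify` (`k1`, `k2`, `w_init`), `kinematics`
#' (`g`, `cond_cap`) and `geometry` (`toe_d`); unspecified keys keep their
#' defaults.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A [gait_config()].
#' @export
read_gait_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  z <- raw$zvp %||% list()
  cl <- raw$classify %||% list()
  kin <- raw$kinematics %||% list()
  geo <- raw$geometry %||% list()
  zd <- zvp_config()
  zvp <- zvp_config(
    ta = z$ta %||% zd$ta, tw = z$tw %||% zd$tw,
    wcap = z$wcap %||% zd$wcap, tmax = z$tmax %||% zd$tmax,
    g = kin$g %||% zd$g,
    min_stride_samples = z$min_stride_samples %||% zd$min_stride_samples
  )
  gd <- gait_config()
  gait_config(zvp = zvp,
              k1 = cl$k1 %||% gd$k1, k2 = cl$k2 %||% gd$k2,
              w_init = cl$w_init %||% gd$w_init,
              g = kin$g %||% gd$g, cond_cap = kin$cond_cap %||% gd$cond_cap,
              toe_d = geo$toe_d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Process an IMU stream into per-stride records
#'
#' Runs the full stride-by-stride pipeline: consecutive detected ZVPs bound
#' each stride; the heel strike is the intra-window pitch maximum; the full
#' four-unknown constraint solve yields the stride's accelerometer bias and
#' heel-strike velocity error (the classification feature, computed for
#' every stride under the level-ground assumption). The first `w_init`
#' strides are treated as level-ground calibration strides; at stride
#' `w_init` the baseline and thresholds are computed, and later strides are
#' classified by their normalized error. Level strides are reconstructed
#' with the full correction (bias plus heel-strike impulse), non-level
#' strides with the velocity-only correction, preserving natural height
#' changes. Degenerate heel-strike timing or an ill-conditioned full system
#' falls back to the velocity-only solve with a flag. A terminal incomplete
#' stride (no closing ZVP) is discarded.
#'
#' @param stream An [imu_stream].
#' @param cfg A [gait_config()].
#' @param keep_trajectories If `TRUE`, each record retains the corrected
#'   trajectory matrix.
#' @return An object of class `stride_records`: a list with `records` (one
#'   list per stride), `calibration` (or `NULL` if the stream ended before
#'   `w_init` strides) and `config`. See [as.data.frame.stride_records()].
#' @export
process_stream <- function(stream, cfg = gait_config(),
                           keep_trajectories = FALSE) {
  zvps <- detect_zvp(stream, cfg$zvp)
  n_str <- max(0L, length(zvps) - 1L)
  records <- vector("list", n_str)
  v_errors <- rep(NA_real_, n_str)
  calibration <- NULL
  cum_height <- 0
  dt <- 1 / stream$rate_hz

  for (i in seq_len(n_str)) {
    win <- stride_window(zvps[i], zvps[i + 1L],
                         min_len = cfg$min_stride_samples)
    pitch <- pitch_from_quaternion(stream$q[win$k0:win$k1, , drop = FALSE])
    win$khs <- detect_heel_strike(as.numeric(pitch))
    st <- stride_drift_state(win, stream, cfg$g)
    drift <- list(dv = st$dv, dpz = st$dpz)
    flags <- character(0)

    sol_full <- tryCatch(
      solve_full_constraints(drift, st$La, st$Lv3, st$M, st$khs_step, st$dt,
                             cond_cap = cfg$cond_cap),
      error = function(e) e
    )
    if (inherits(sol_full, "error")) {
      flags <- c(flags, if (grepl("ill-conditioned", conditionMessage(sol_full)))
        "ill_conditioned" else "degenerate_khs")
      sol_full <- NULL
    }
    v_err <- if (is.null(sol_full)) 0 else sol_full$v_error_hs
    v_errors[i] <- v_err

    if (i <= cfg$w_init) {
      activity <- "LEVEL"
      flags <- c(flags, "calibration")
      if (i == cfg$w_init) {
        calibration <- calibrate_baseline(v_errors[seq_len(cfg$w_init)])
        calibration$k1 <- cfg$k1
        calibration$k2 <- cfg$k2
        calibration$w_init <- cfg$w_init
        calibration$thresholds <- build_thresholds(
          calibration$mu_hs, calibration$sigma_hs, cfg$k1, cfg$k2)
      }
    } else {
      activity <- classify_stride(v_err - calibration$mu_hs,
                                  calibration$thresholds)
    }

    use_full <- identical(activity, "LEVEL") && !is.null(sol_full)
    sol <- if (use_full) sol_full else
      tryCatch(solve_velocity_only(drift, st$La, st$dt, cfg$cond_cap),
               error = function(e) NULL)
    traj <- NULL
    metrics <- NULL
    if (!is.null(sol)) {
      traj <- reconstruct_corrected(
        win, stream, sol,
        activity = if (use_full) "LEVEL" else "NONLEVEL_RECON",
        g = cfg$g
      )
      metrics <- stride_metrics(traj, activity = activity)
      if (!is.null(cfg$toe_d)) {
        Rs <- stream_rotations(stream, win$k0:win$k1)
        toe_p <- toe_position(traj$p, Rs, cfg$toe_d)
        metrics$toe_stride_height <- toe_p[nrow(toe_p), 3] - toe_p[1, 3]
      }
      cum_height <- cum_height + metrics$stride_height
    } else {
      flags <- c(flags, "reconstruction_failed")
    }

    records[[i]] <- list(
      stride_index = i,
      window = win,
      solution = sol,
      v_error_full = if (is.null(sol_full)) NA_real_ else sol_full$v_error_hs,
      activity = activity,
      metrics = metrics,
      cumulative_height = cum_height,
      flags = flags,
      trajectory = if (keep_trajectories) traj else NULL
    )
  }
  if (n_str > 0L && n_str < cfg$w_init) {
    warning(sprintf("stream ended after %d strides, before the %d-stride calibration completed",
                    n_str, cfg$w_init))
  }
  structure(list(records = records, calibration = calibration, config = cfg),
            class = "stride_records")
}

#' @export
print.stride_records <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<stride_records> %d strides, cumulative height %.3f m\n",
              nrow(df), if (nrow(df)) df$cumulative_height[nrow(df)] else 0))
  if (nrow(df)) print(table(df$activity))
  invisible(x)
}

#' Flatten stride records to a data frame
#'
#' @param x A `stride_records` object.
#' @param ... Unused.
#' @return A data frame with one row per stride: window indices, solve
#'   mode, bias components, heel-strike velocity error, activity, the four
#'   stride metrics, cumulative height and flags.
#' @export
as.data.frame.stride_records <- function(x, ...) {
  rows <- lapply(x$records, function(r) {
    m <- r$metrics
    s <- r$solution
    data.frame(
      stride = r$stride_index,
      k0 = r$window$k0, k1 = r$window$k1, khs = r$window$khs,
      n = r$window$N,
      mode = if (is.null(s)) NA_character_ else s$mode,
      bias_x = if (is.null(s)) NA_real_ else s$a_bias[1],
      bias_y = if (is.null(s)) NA_real_ else s$a_bias[2],
      bias_z = if (is.null(s)) NA_real_ else s$a_bias[3],
      v_error_hs = r$v_error_full,
      cond = if (is.null(s)) NA_real_ else s$cond,
      activity = r$activity,
      stride_height = if (is.null(m)) NA_real_ else m$stride_height,
      max_stride_height = if (is.null(m)) NA_real_ else m$max_stride_height,
      stride_length = if (is.null(m)) NA_real_ else m$stride_length,
      max_stride_length = if (is.null(m)) NA_real_ else m$max_stride_length,
      toe_stride_height = if (is.null(m$toe_stride_height)) NA_real_
                          else m$toe_stride_height,
      cumulative_height = r$cumulative_height,
      calibrating = "calibration" %in% r$flags,
      flags = paste(setdiff(r$flags, "calibration"), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame())
  }
  do.call(rbind, rows)
}

#' Evaluate stride classification against ground truth
#'
#' Confusion matrix and the standard derived rates. When given a
#' `stride_records` object, calibration strides are excluded before
#' alignment with the truth labels.
#'
#' @param predicted A `stride_records` object or a character vector of
#'   predicted labels.
#' @param truth Character vector of true activity labels for the same
#'   strides (after calibration-stride exclusion when `predicted` is a
#'   `stride_records`).
#' @return A list with `confusion` (5 x 5 table, truth in rows),
#'   `accuracy`, per-class `precision`, `recall`, `f1`, and their macro
#'   averages.
#' @export
evaluate_classification <- function(predicted, truth) {
  if (inherits(predicted, "stride_records")) {
    df <- as.data.frame(predicted)
    predicted <- df$activity[!df$calibrating]
  }
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop(sprintf("prediction/truth length mismatch: %d vs %d",
                 length(predicted), length(truth)))
  }
  labs <- activity_labels()
  confusion <- table(factor(truth, levels = labs),
                     factor(predicted, levels = labs),
                     dnn = c("truth", "predicted"))
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), NA_real_)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), NA_real_)
  f1 <- ifelse(is.na(prec) | is.na(rec) | (prec + rec) == 0, NA_real_,
               2 * prec * rec / (prec + rec))
  list(
    confusion = confusion,
    accuracy = sum(tp) / sum(confusion),
    precision = prec, recall = rec, f1 = f1,
    macro_precision = mean(prec, na.rm = TRUE),
    macro_recall = mean(rec, na.rm = TRUE),
    macro_f1 = mean(f1, na.rm = TRUE)
  )
}
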