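# Per-squat biomechanical features and instability labeling.
#
# Five features per squat, in the fixed channel order the rest of the
# pipeline relies on:
#   1 KS  knee shakiness   sum of left/right ML knee velocity magnitudes, m/s
#   2 KD  knee distance    ML separation of the two knees, m
#   3 SD  squat depth      baseline torso height minus torso height, m
#   4 SV  sway velocity    per-step CoP path displacement over the step, m/s
#   5 SA  sway area        origin-anchored shoelace triangle increments, m^2
#
# Axis convention: x is mediolateral, y is vertical (torso) or anteroposterior
# (CoP).  The instability label is 1 (KI) when the per-squat peak |KS|,
# computed on physical-unit filtered data, reaches 0.03 m/s.

feature_names <- function() c("ks", "kd", "sd", "sv", "sa")

#' Knee shakiness (feature 1)
#'
#' Backward-difference knee velocities `Vl(t) = (x_lk(t) - x_lk(t-1)) / dt`
#' and `Vr` likewise; the first sample is set equal to the second.  The
#' default `"magnitude"` mode returns `|Vl| + |Vr|` so that antiphase
#' (valgus-like) shake does not cancel; `"signed"` returns `Vl + Vr` as the
#' plain sum of the two velocities.
#'
#' @param x_lk,x_rk Left/right knee ML positions, meters.
#' @param dt Sample step, seconds.
#' @param mode `"magnitude"` (default) or `"signed"`.
#' @return Knee shakiness series, m/s, same length as the inputs.
#' @export
knee_shakiness <- function(x_lk, x_rk, dt, mode = c("magnitude", "signed")) {
  mode <- match.arg(mode)
  abort_if(dt <= 0, "parameter error: dt must be positive")
  abort_if(length(x_lk) < 2 || length(x_lk) != length(x_rk),
           "knee_shakiness: series must have equal length >= 2")
  vl <- diff(x_lk) / dt
  vr <- diff(x_rk) / dt
  ks <- if (mode == "magnitude") abs(vl) + abs(vr) else vl + vr
  c(ks[1], ks)
}

#' Knee distance (feature 2)
#'
#' Mediolateral knee separation per sample.  The default takes the absolute
#' value so the result does not depend on which knee carries the larger
#' coordinate; `signed = TRUE` returns the raw left-minus-right difference.
#'
#' @param x_lk,x_rk Knee ML positions, meters.
#' @param signed Return the signed difference instead of its magnitude.
#' @return Knee distance series, meters.
#' @export
knee_distance <- function(x_lk, x_rk, signed = FALSE) {
  abort_if(length(x_lk) != length(x_rk),
           "knee_distance: series lengths differ")
  d <- x_lk - x_rk
  if (signed) d else abs(d)
}

#' Squat depth (feature 3)
#'
#' Instantaneous depth series `max(0, y_t1 - y_torso(t))` and the per-squat
#' scalar depth `y_t1 - min(y_torso)` (positive-depth convention; the raw
#' minimum-minus-baseline difference is its negative and is available via
#' `as_printed`).
#'
#' @param y_torso Vertical torso position series, meters.
#' @param y_t1 Baseline (standing) torso height, meters.
#' @param as_printed Return the scalar as `min(y_torso) - y_t1` (negative).
#' @return List with `series` (m) and `scalar` (m).
#' @export
squat_depth <- function(y_torso, y_t1, as_printed = FALSE) {
  series <- pmax(0, y_t1 - y_torso)
  scalar <- y_t1 - min(y_torso)
  list(series = series, scalar = if (as_printed) -scalar else scalar)
}

#' Sway velocity (feature 4)
#'
#' Step displacement `delta(t) = sqrt(dCoPx^2 + dCoPy^2)` of the CoP path.
#' The default returns `delta / dt` (m/s, standard posturography); the
#' `as_printed` form multiplies by `dt` instead, reproducing the product form
#' of the source equation.  The last sample is replicated so the series
#' matches the input length.
#'
#' @param cop_x,cop_y CoP coordinates, meters.
#' @param dt Sample step, seconds.
#' @param as_printed Use the `delta * dt` product form.
#' @return Sway series, same length as the inputs.
#' @export
sway_velocity <- function(cop_x, cop_y, dt, as_printed = FALSE) {
  abort_if(dt <= 0, "parameter error: dt must be positive")
  abort_if(length(cop_x) < 2 || length(cop_x) != length(cop_y),
           "sway_velocity: series must have equal length >= 2")
  delta <- sqrt(diff(cop_x)^2 + diff(cop_y)^2)
  sv <- if (as_printed) delta * dt else delta / dt
  c(sv, sv[length(sv)])
}

#' Sway area (feature 5)
#'
#' Incremental origin-anchored triangle areas of the CoP trajectory,
#' `a(t) = |CoPx(t+1) * CoPy(t) - CoPx(t) * CoPy(t+1)| / 2` (shoelace with the
#' origin).  The series is prefixed with a zero increment at onset so it
#' matches the input length; the scalar is the per-squat sum, divided by the
#' window duration by default (area per second).  `as_printed` multiplies
#' each increment by `dt` as in the product form of the source equation.
#'
#' @param cop_x,cop_y CoP coordinates, meters.
#' @param dt Sample step, seconds.
#' @param as_printed Multiply increments by `dt`; scalar becomes their sum.
#' @return List with `series` (increments) and `scalar`.
#' @export
sway_area <- function(cop_x, cop_y, dt, as_printed = FALSE) {
  n <- length(cop_x)
  abort_if(n < 2 || n != length(cop_y),
           "sway_area: series must have equal length >= 2")
  a <- abs(cop_x[-1] * cop_y[-n] - cop_x[-n] * cop_y[-1]) / 2
  if (as_printed) {
    series <- c(0, a * dt)
    scalar <- sum(a * dt)
  } else {
    series <- c(0, a)
    scalar <- sum(a) / ((n - 1) * dt)
  }
  list(series = series, scalar = scalar)
}

#' Label a squat as knee-instability (KI) or not (NKI)
#'
#' Applies the dimensional threshold to a physical-unit (pre min-max
#' normalization) knee-shakiness series: label 1 (KI) when the per-squat
#' statistic of `|ks|` reaches `threshold`, else 0 (NKI).  The boundary is
#' inclusive.
#'
#' @param ks Knee shakiness series, m/s, physical units.
#' @param threshold Threshold, m/s (default 0.03).
#' @param stat `"max"` (default) or `"mean"` aggregation of `|ks|`.
#' @return List with `label` (0/1) and `ks_stat` (m/s).
#' @export
label_squat <- function(ks, threshold = 0.03, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  abort_if(length(ks) == 0, "label_squat: empty series")
  ks_stat <- if (stat == "max") max(abs(ks)) else mean(abs(ks))
  list(label = as.integer(ks_stat >= threshold), ks_stat = ks_stat)
}

#' Compute features and label for one squat cycle
#'
#' The label and `ks_stat` are computed on the full-rate physical window
#' (the 20-sample grid under-samples oscillations above ~2.5 Hz); the feature
#' series are then computed on the time-normalized cycle for the classifier
#' tensor.
#'
#' @param cycle A physical-unit `squat_cycle` from [extract_window()].
#' @param n Time-normalization length (default 20).
#' @param threshold,stat Passed to [label_squat()].
#' @param ks_mode Passed to [knee_shakiness()].
#' @return A `squat_features` list: `series` (n x 5 matrix, channels
#'   KS,KD,SD,SV,SA), `label`, `ks_stat`, `sd_scalar`, `sa_total`, metadata.
#' @export
squat_features <- function(cycle, n = 20L, threshold = 0.03,
                           stat = "max", ks_mode = "magnitude") {
  ch <- cycle$channels
  ks_full <- knee_shakiness(ch$x_lk, ch$x_rk, cycle$dt, mode = ks_mode)
  lab <- label_squat(ks_full, threshold = threshold, stat = stat)
  sd_scalar <- squat_depth(ch$y_torso, cycle$y_t1)$scalar

  norm <- if (isTRUE(cycle$time_normalized) && cycle$n_samples == n) cycle else
    time_normalize(cycle, n)
  nc <- norm$channels
  sa <- sway_area(nc$cop_x, nc$cop_y, norm$dt)
  series <- cbind(
    ks = knee_shakiness(nc$x_lk, nc$x_rk, norm$dt, mode = ks_mode),
    kd = knee_distance(nc$x_lk, nc$x_rk),
    sd = squat_depth(nc$y_torso, cycle$y_t1)$series,
    sv = sway_velocity(nc$cop_x, nc$cop_y, norm$dt),
    sa = sa$series
  )
  structure(list(
    subject = cycle$subject, squat = cycle$squat,
    series = series, dt = norm$dt,
    label = lab$label, ks_stat = lab$ks_stat,
    sd_scalar = sd_scalar, sa_total = sa$scalar,
    t_on = cycle$t_on, t_off = cycle$t_off
  ), class = "squat_features")
}

#' Assemble the labeled dataset tensor
#'
#' Stacks the five 20-sample feature series of every squat into an
#' `n_squats x n_time x 5` tensor (channel order KS, KD, SD, SV, SA), applies
#' min-max normalization to the feature channels, and attaches the labels
#' computed on physical units before normalization.  Per-squat scalar
#' summaries (KS -> peak |KS| at full rate, KD -> mean, SD -> scalar depth,
#' SV -> mean, SA -> total) are retained for feature ranking.
#'
#' @param features List of `squat_features`.
#' @param scope Min-max scope, `"per_subject"` (default) or `"global"`.
#' @param ground_truth Optional generator ground-truth table; rows are matched
#'   to detected squats by subject and onset time (within `match_tol`
#'   seconds) to attach `true_unstable` flags.
#' @param match_tol Onset-time matching tolerance, seconds.
#' @return A `labeled_dataset`: normalized tensor `x`, `labels`, `subject`,
#'   `squat`, `ks_stat`, `summaries` (n x 5, physical units), normalization
#'   `record`/`scope`, `feature_ids`, optional `truth`.
#' @export
build_dataset <- function(features, scope = c("per_subject", "global"),
                          ground_truth = NULL, match_tol = 0.5) {
  scope <- match.arg(scope)
  abort_if(length(features) == 0, "build_dataset: no squats")
  n <- length(features)
  nt <- nrow(features[[1]]$series)
  x <- array(NA_real_, c(n, nt, 5),
             dimnames = list(NULL, NULL, feature_names()))
  labels <- integer(n); subject <- integer(n); squat <- integer(n)
  ks_stat <- numeric(n); t_on <- numeric(n)
  summaries <- matrix(NA_real_, n, 5, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    f <- features[[i]]
    x[i, , ] <- f$series
    labels[i] <- f$label
    subject[i] <- f$subject
    squat[i] <- f$squat
    ks_stat[i] <- f$ks_stat
    t_on[i] <- f$t_on
    summaries[i, ] <- c(f$ks_stat, mean(f$series[, "kd"]), f$sd_scalar,
                        mean(f$series[, "sv"]), f$sa_total)
  }
  nrm <- minmax_normalize(x, subject, scope = scope,
                          channel_names = feature_names())
  truth <- NULL
  if (!is.null(ground_truth)) {
    truth <- rep(NA, n)
    for (i in seq_len(n)) {
      g <- ground_truth[ground_truth$subject == subject[i], ]
      j <- which.min(abs(g$t_on - t_on[i]))
      if (length(j) && abs(g$t_on[j] - t_on[i]) <= match_tol) {
        truth[i] <- g$true_unstable[j]
      }
    }
  }
  structure(list(
    x = nrm$x, labels = labels, subject = subject, squat = squat,
    ks_stat = ks_stat, summaries = summaries,
    record = nrm$record, scope = scope,
    feature_ids = 1:5, truth = truth
  ), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d squats x %d steps x %d channels (%s); %d KI / %d NKI\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3],
              paste(x$feature_ids, collapse = ","),
              sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Serialize a labeled dataset to CSV
#'
#' Writes the long-format features table
#' (`subject,squat,row,ks,kd,sd,sv,sa`) and the labels table
#' (`subject,squat,label,ks_stat`).
#'
#' @param dataset A `labeled_dataset`.
#' @param features_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset_csv <- function(dataset, features_path, labels_path) {
  n <- dim(dataset$x)[1]; nt <- dim(dataset$x)[2]
  long <- data.frame(
    subject = rep(dataset$subject, each = nt),
    squat = rep(dataset$squat, each = nt),
    row = rep(seq_len(nt), times = n)
  )
  flat <- matrix(aperm(dataset$x, c(2, 1, 3)), n * nt, dim(dataset$x)[3])
  colnames(flat) <- dimnames(dataset$x)[[3]]
  utils::write.csv(cbind(long, flat), features_path, row.names = FALSE)
  utils::write.csv(data.frame(subject = dataset$subject, squat = dataset$squat,
                              label = dataset$labels, ks_stat = dataset$ks_stat),
                   labels_path, row.names = FALSE)
  invisible(c(features_path, labels_path))
}
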