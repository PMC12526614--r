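# Squat-cycle detection, window extraction, time normalization, and min-max
# amplitude normalization.

#' Detect squat cycles in a synchronized session
#'
#' The torso depth signal `d(t) = y_t1 - y_torso(t)` is thresholded to find
#' candidate squats.  The standing baseline `y_t1` is estimated iteratively as
#' the median of `y_torso` over non-squat samples (samples where the depth
#' signal is below 25% of its 95th percentile).  A candidate is a maximal run
#' where `d > max(min_depth_on, 0.2 * run peak depth)`; onset and end are then
#' extended outward to the crossing of a small fraction of the peak so cycle
#' boundaries approximate the true movement onset.  The hold span is where
#' `d >= 0.9 * peak`.  Candidates shallower than `min_depth` or outside
#' `dur_bounds` are rejected and counted.
#'
#' @param session A filtered `synced_session`.
#' @param min_depth Minimum valid squat depth, meters.
#' @param dur_bounds Valid cycle duration bounds `(min, max)`, seconds.
#' @param min_depth_on Onset detection threshold, meters.
#' @return A data frame of cycle boundaries (`onset`, `hold_start`,
#'   `hold_end`, `end` sample indices; `t_on`, `t_off`; `peak_depth`) with
#'   attributes `y_t1` (baseline) and `n_rejected`.  Zero rows when no
#'   candidate survives (not an error).
#' @export
detect_squats <- function(session, min_depth = 0.15, dur_bounds = c(1, 10),
                          min_depth_on = 0.05) {
  y <- session$y_torso
  empty <- data.frame(onset = integer(), hold_start = integer(),
                      hold_end = integer(), end = integer(),
                      t_on = numeric(), t_off = numeric(),
                      peak_depth = numeric())
  # iterative standing-baseline estimate, seeded near the standing height
  y_t1 <- stats::quantile(y, 0.95, names = FALSE)
  for (it in 1:3) {
    d <- y_t1 - y
    q95 <- stats::quantile(d, 0.95, names = FALSE)
    if (q95 <= 0) break
    standing <- d < 0.25 * q95
    if (!any(standing)) break
    y_t1 <- stats::median(y[standing])
  }
  d <- y_t1 - y
  if (max(d) <= min_depth_on) {
    attr(empty, "y_t1") <- y_t1
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  r <- rle(d > min_depth_on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])

  out <- list()
  n_rejected <- 0L
  prev_end <- 0L
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    peak <- max(d[a:b])
    ipk <- a - 1L + which.max(d[a:b])
    th <- max(min_depth_on, 0.2 * peak)
    # maximal run containing the peak at the refined threshold
    on <- ipk; while (on > a && d[on - 1L] > th) on <- on - 1L
    off <- ipk; while (off < b && d[off + 1L] > th) off <- off + 1L
    # extend to near-zero crossing so boundaries track the true onset/end
    ext <- max(0.01 * peak, 0.005)
    while (on > prev_end + 1L && d[on - 1L] > ext) on <- on - 1L
    while (off < length(d) && d[off + 1L] > ext) off <- off + 1L
    duration <- session$t[off] - session$t[on]
    if (peak < min_depth || duration < dur_bounds[1] || duration > dur_bounds[2]) {
      n_rejected <- n_rejected + 1L
      prev_end <- max(prev_end, off)
      next
    }
    hold <- which(d[on:off] >= 0.9 * peak) + on - 1L
    out[[length(out) + 1L]] <- data.frame(
      onset = on, hold_start = hold[1], hold_end = hold[length(hold)],
      end = off, t_on = session$t[on], t_off = session$t[off],
      peak_depth = peak)
    prev_end <- off
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  attr(res, "y_t1") <- y_t1
  attr(res, "n_rejected") <- n_rejected
  res
}

#' Extract the physical-unit window of one detected squat
#'
#' @param session A `synced_session`.
#' @param boundary One row of the [detect_squats()] result.
#' @param y_t1 Baseline torso height, meters; defaults to the `y_t1` attribute
#'   of the full [detect_squats()] result (pass it explicitly when `boundary`
#'   is a sliced row, which drops attributes).
#' @param squat Squat index recorded on the cycle.
#' @return A `squat_cycle`: channel windows (onset..end inclusive), grid step
#'   `dt`, baseline torso height `y_t1`, and the boundary metadata.
#' @export
extract_window <- function(session, boundary, y_t1 = attr(boundary, "y_t1"),
                           squat = 1L) {
  i0 <- boundary$onset; i1 <- boundary$end
  abort_if(i0 < 1 || i1 > length(session$t) || i0 >= i1,
           "index error: cycle boundary [", i0, ", ", i1,
           "] outside the session grid")
  channels <- lapply(stats::setNames(session_channels(), session_channels()),
                     function(nm) session[[nm]][i0:i1])
  structure(list(
    subject = session$subject, squat = as.integer(squat),
    t = session$t[i0:i1], dt = session$dt,
    channels = channels,
    y_t1 = y_t1 %||% NA_real_,
    t_on = boundary$t_on, t_off = boundary$t_off,
    hold = c(boundary$hold_start, boundary$hold_end) - i0 + 1L,
    n_samples = i1 - i0 + 1L
  ), class = "squat_cycle")
}

#' @export
print.squat_cycle <- function(x, ...) {
  cat(sprintf("<squat_cycle> subject %s squat %d: %d samples, [%.2f, %.2f] s\n",
              x$subject, x$squat, x$n_samples, x$t_on, x$t_off))
  invisible(x)
}

#' Time-normalize a squat cycle to a fixed number of samples
#'
#' Linearly interpolates every channel onto `n` equally spaced points from
#' onset to end inclusive; `dt` is rescaled to `duration / (n - 1)` so that
#' time-step-dependent features remain dimensionally correct.
#'
#' @param cycle A `squat_cycle`.
#' @param n Number of output samples (default 20).
#' @return The resampled `squat_cycle`.
#' @export
time_normalize <- function(cycle, n = 20L) {
  abort_if(cycle$n_samples < 2L, "time_normalize: window shorter than 2 samples")
  grid <- seq(cycle$t[1], cycle$t[length(cycle$t)], length.out = n)
  cycle$channels <- lapply(cycle$channels, function(x) {
    stats::approx(cycle$t, x, xout = grid, method = "linear")$y
  })
  cycle$t <- grid
  cycle$dt <- (grid[n] - grid[1]) / (n - 1)
  cycle$n_samples <- as.integer(n)
  cycle$time_normalized <- TRUE
  cycle
}

#' Min-max normalize channel matrices across cycles
#'
#' Per channel, maps `x` to `(x - min) / (max - min)` with the extrema taken
#' across all cycles of the scope group (`per_subject` keeps subject-specific
#' biomechanics; `global` pools all subjects).  Degenerate constant channels
#' map to all zeros with a warning.  The normalization record (per group and
#' channel min/max) is returned for exact inversion.
#'
#' @param x Array `n_cycles x n_time x n_channels`.
#' @param subjects Subject id per cycle (length `n_cycles`).
#' @param scope `"per_subject"` (default) or `"global"`.
#' @param channel_names Optional channel names for the record.
#' @return List with the normalized array `x` and the `record` data frame
#'   (`group`, `channel`, `min`, `max`).
#' @export
minmax_normalize <- function(x, subjects, scope = c("per_subject", "global"),
                             channel_names = NULL) {
  scope <- match.arg(scope)
  abort_if(length(dim(x)) != 3, "minmax_normalize expects a 3-d array")
  abort_if(dim(x)[1] < 1, "minmax_normalize: need at least one cycle")
  nc <- dim(x)[3]
  channel_names <- channel_names %||% dimnames(x)[[3]] %||% as.character(seq_len(nc))
  groups <- if (scope == "global") rep("all", dim(x)[1]) else as.character(subjects)
  record <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    for (ch in seq_len(nc)) {
      v <- x[idx, , ch]
      lo <- min(v); hi <- max(v)
      if (hi - lo <= 0) {
        warning("minmax_normalize: constant channel '", channel_names[ch],
                "' in group ", g, "; set to 0", call. = FALSE)
        x[idx, , ch] <- 0
      } else {
        x[idx, , ch] <- (v - lo) / (hi - lo)
      }
      record[[length(record) + 1L]] <- data.frame(
        group = g, channel = channel_names[ch], min = lo, max = hi)
    }
  }
  list(x = x, record = do.call(rbind, record), scope = scope)
}

#' Invert a stored min-max normalization
#'
#' @param x Normalized array `n x t x c`.
#' @param subjects Subject id per cycle.
#' @param record,scope The record and scope returned by [minmax_normalize()].
#' @return The array in physical units.
#' @export
minmax_invert <- function(x, subjects, record, scope = "per_subject") {
  groups <- if (scope == "global") rep("all", dim(x)[1]) else as.character(subjects)
  channel_names <- unique(record$channel)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    for (ch in seq_along(channel_names)) {
      r <- record[record$group == g & record$channel == channel_names[ch], ]
      if (r$max - r$min > 0) {
        x[idx, , ch] <- x[idx, , ch] * (r$max - r$min) + r$min
      } else {
        x[idx, , ch] <- r$min
      }
    }
  }
  x
}
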