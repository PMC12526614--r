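# Synthetic squat-exergame cohort generator.
#
# Emulates a squat-exergame recording setup: a depth camera tracking the
# mediolateral (ML) position of both knees and the vertical torso position at
# ~60 Hz, and a force plate sampling the center of pressure (CoP, ML and AP)
# at 50 Hz.  Each squat is a smooth raised-cosine descent / hold / ascent of
# the torso; unstable squats superimpose a lateral sinusoidal knee oscillation
# whose peak shakiness straddles the 0.03 m/s labeling threshold, partially
# coupled into the ML CoP channel.  Every squat carries ground truth.

#' Configuration for the synthetic squat cohort generator
#'
#' Defaults mirror the emulated study conditions: 28 subjects performing 130
#' squats each (3640 squats), camera at 60 Hz, force plate at 50 Hz, start
#' offsets of up to a few seconds between the two recorders, and an
#' instability prevalence of 6.5%.
#'
#' Oscillation amplitudes are calibrated analytically against the 0.03 m/s
#' knee-shakiness threshold: the peak shakiness of a sinusoidal antiphase
#' oscillation of amplitude `a` (m) and frequency `f` (Hz) is `2 * (2*pi*f*a)`
#' m/s, so with `f ~ U(1, 4)` Hz the stable cap of 4e-4 m keeps stable squats
#' below ~0.020 m/s while the unstable floor of 2.5e-3 m keeps unstable
#' squats above ~0.031 m/s.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param squats_per_subject Squats generated per subject session.
#' @param camera_rate Camera sampling rate, Hz.
#' @param plate_rate Force-plate sampling rate, Hz.
#' @param start_offset_max Maximum uniform start-time offset between the two
#'   recorders, seconds.
#' @param standing_height Standing torso marker height, meters.
#' @param depth_range Min/max squat depth, meters.
#' @param stance_width_range Min/max ML knee separation, meters.
#' @param cycle_duration_range Min/max squat cycle duration, seconds.
#' @param hold_fraction Fraction of the cycle spent in the parallel-squat hold.
#' @param rest_duration Standing rest between consecutive squats, seconds.
#' @param instability_prevalence Probability that a squat is unstable.
#' @param osc_amp_stable Max ML oscillation amplitude for stable squats, m.
#' @param osc_amp_unstable Min/max oscillation amplitude for unstable squats, m.
#' @param osc_freq_range Oscillation frequency band, Hz; must stay below the
#'   5 Hz low-pass cutoff so injected instability survives filtering.
#' @param knee_coupling `"antiphase"` (valgus-like, default) or `"inphase"`.
#' @param cop_coupling_gain Unitless gain coupling the knee oscillation (m,
#'   scaled to mm) into the ML CoP channel.
#' @param noise_sd_camera White measurement noise SD on camera channels, m.
#' @param noise_sd_cop White measurement noise SD on CoP channels, mm.
#' @param seed Integer seed; per-subject substreams are derived from
#'   `(seed, subject_id)` so cohorts are reproducible and order-independent.
#' @return A validated `synth_config` object (a list).
#' @export
synth_config <- function(n_subjects = 28L,
                         squats_per_subject = 130L,
                         camera_rate = 60,
                         plate_rate = 50,
                         start_offset_max = 3,
                         standing_height = 1.0,
                         depth_range = c(0.25, 0.45),
                         stance_width_range = c(0.18, 0.30),
                         cycle_duration_range = c(3, 5),
                         hold_fraction = 0.3,
                         rest_duration = 1.5,
                         instability_prevalence = 0.065,
                         osc_amp_stable = 4e-4,
                         osc_amp_unstable = c(2.5e-3, 8e-3),
                         osc_freq_range = c(1, 4),
                         knee_coupling = c("antiphase", "inphase"),
                         cop_coupling_gain = 0.5,
                         noise_sd_camera = 2e-4,
                         noise_sd_cop = 0.3,
                         seed = 1L) {
  knee_coupling <- match.arg(knee_coupling)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    squats_per_subject = as.integer(squats_per_subject),
    camera_rate = camera_rate, plate_rate = plate_rate,
    start_offset_max = start_offset_max,
    standing_height = standing_height,
    depth_range = depth_range,
    stance_width_range = stance_width_range,
    cycle_duration_range = cycle_duration_range,
    hold_fraction = hold_fraction,
    rest_duration = rest_duration,
    instability_prevalence = instability_prevalence,
    osc_amp_stable = osc_amp_stable,
    osc_amp_unstable = osc_amp_unstable,
    osc_freq_range = osc_freq_range,
    knee_coupling = knee_coupling,
    cop_coupling_gain = cop_coupling_gain,
    noise_sd_camera = noise_sd_camera,
    noise_sd_cop = noise_sd_cop,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

# Filter cutoff the downstream pipeline applies; generator invariants are
# checked against it so injected instability survives low-pass filtering.
.default_cutoff_hz <- 5

validate_synth_config <- function(cfg) {
  abort_if(cfg$n_subjects < 1L, "configuration error: n_subjects must be >= 1")
  abort_if(cfg$squats_per_subject < 1L,
           "configuration error: squats_per_subject must be >= 1")
  abort_if(cfg$camera_rate <= 2 * .default_cutoff_hz,
           "configuration error: camera_rate must exceed twice the filter cutoff (",
           2 * .default_cutoff_hz, " Hz)")
  abort_if(cfg$plate_rate <= 2 * .default_cutoff_hz,
           "configuration error: plate_rate must exceed twice the filter cutoff (",
           2 * .default_cutoff_hz, " Hz)")
  abort_if(cfg$instability_prevalence < 0 || cfg$instability_prevalence > 1,
           "configuration error: instability_prevalence must lie in [0, 1]")
  abort_if(cfg$depth_range[1] <= 0.15,
           "configuration error: depth_range minimum must exceed the ",
           "spurious-rejection minimum depth (0.15 m)")
  abort_if(diff(cfg$depth_range) < 0,
           "configuration error: depth_range must be (min, max)")
  abort_if(max(cfg$osc_freq_range) >= .default_cutoff_hz,
           "configuration error: osc_freq_range upper bound must be below the ",
           .default_cutoff_hz, " Hz low-pass cutoff")
  abort_if(cfg$start_offset_max < 0,
           "configuration error: start_offset_max must be >= 0")
  abort_if(cfg$hold_fraction <= 0 || cfg$hold_fraction >= 1,
           "configuration error: hold_fraction must lie in (0, 1)")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  cohort: %d subjects x %d squats (prevalence %.3f)\n",
              x$n_subjects, x$squats_per_subject, x$instability_prevalence))
  cat(sprintf("  camera %.0f Hz, plate %.0f Hz, start offset <= %.1f s\n",
              x$camera_rate, x$plate_rate, x$start_offset_max))
  cat(sprintf("  oscillation: %s, %.3g-%.3g m unstable, <= %.3g m stable, %.1f-%.1f Hz\n",
              x$knee_coupling, x$osc_amp_unstable[1], x$osc_amp_unstable[2],
              x$osc_amp_stable, x$osc_freq_range[1], x$osc_freq_range[2]))
  invisible(x)
}

# Raised-cosine squat depth profile: 0 -> 1 descent, hold at 1, 1 -> 0 ascent.
squat_profile <- function(t, t0, duration, hold_fraction) {
  ramp <- duration * (1 - hold_fraction) / 2
  tau <- t - t0
  p <- numeric(length(t))
  i <- tau >= 0 & tau < ramp
  p[i] <- (1 - cos(pi * tau[i] / ramp)) / 2
  i <- tau >= ramp & tau <= duration - ramp
  p[i] <- 1
  i <- tau > duration - ramp & tau <= duration
  p[i] <- (1 - cos(pi * (duration - tau[i]) / ramp)) / 2
  p
}

#' Generate one synthetic squat-exergame session
#'
#' @param config A [synth_config()].
#' @param subject_id Integer subject identifier; seeds the subject's
#'   deterministic random substream.
#' @return A list with elements `camera` (a [sensor_stream()] with channels
#'   `x_lk`, `x_rk`, `y_torso`, meters), `plate` (channels `cop_x`, `cop_y`,
#'   millimeters, force-plate convention), and `ground_truth` (one row per
#'   squat: `subject`, `squat`, `true_unstable`, `osc_amp_m`, `osc_freq_hz`,
#'   `depth_m`, `t_on`, `t_off`).
#' @export
generate_session <- function(config, subject_id = 1L) {
  validate_synth_config(config)
  with_seed(subject_seed(config$seed, subject_id), {
    ns <- config$squats_per_subject
    dur <- runif(ns, config$cycle_duration_range[1], config$cycle_duration_range[2])
    depth <- runif(ns, config$depth_range[1], config$depth_range[2])
    unstable <- runif(ns) < config$instability_prevalence
    amp <- ifelse(unstable,
                  runif(ns, config$osc_amp_unstable[1], config$osc_amp_unstable[2]),
                  runif(ns, 0, config$osc_amp_stable))
    freq <- runif(ns, config$osc_freq_range[1], config$osc_freq_range[2])
    phase <- runif(ns, 0, 2 * pi)
    stance <- runif(1, config$stance_width_range[1], config$stance_width_range[2])
    plate_offset <- runif(1, 0, config$start_offset_max)

    # exercise begins only after both recorders are running: lead-in rest is
    # appended to the largest possible start offset so no squat is clipped by
    # the common grid
    t_on <- config$start_offset_max + config$rest_duration +
      c(0, cumsum(dur[-ns] + config$rest_duration))
    t_off <- t_on + dur
    t_total <- t_off[ns] + config$rest_duration

    t_cam <- seq(0, t_total, by = 1 / config$camera_rate)
    t_pl <- seq(plate_offset, t_total, by = 1 / config$plate_rate)

    eval_channels <- function(t) {
      prof <- numeric(length(t))
      osc <- numeric(length(t))
      for (j in seq_len(ns)) {
        pj <- squat_profile(t, t_on[j], dur[j], config$hold_fraction)
        prof <- prof + depth[j] * pj
        osc <- osc + amp[j] * sin(2 * pi * freq[j] * (t - t_on[j]) + phase[j]) * pj
      }
      list(profile = prof, osc = osc)
    }

    ch_cam <- eval_channels(t_cam)
    osc_sign_r <- if (config$knee_coupling == "antiphase") -1 else 1
    x_lk <- stance / 2 + ch_cam$osc +
      rnorm(length(t_cam), 0, config$noise_sd_camera)
    x_rk <- -stance / 2 + osc_sign_r * ch_cam$osc +
      rnorm(length(t_cam), 0, config$noise_sd_camera)
    y_torso <- config$standing_height - ch_cam$profile +
      rnorm(length(t_cam), 0, config$noise_sd_camera)

    ch_pl <- eval_channels(t_pl)
    # Baseline postural sway (mm) plus depth-locked AP shift and the ML
    # oscillation coupled through the kinetic chain.
    cop_x <- 2.0 * sin(2 * pi * 0.25 * t_pl + phase[1]) +
      config$cop_coupling_gain * 1000 * ch_pl$osc +
      rnorm(length(t_pl), 0, config$noise_sd_cop)
    cop_y <- 3.0 * sin(2 * pi * 0.20 * t_pl + phase[ns]) +
      15 * ch_pl$profile / max(config$depth_range) +
      rnorm(length(t_pl), 0, config$noise_sd_cop)

    camera <- sensor_stream("camera", t_cam,
                            list(x_lk = x_lk, x_rk = x_rk, y_torso = y_torso),
                            nominal_rate = config$camera_rate, units = "m")
    plate <- sensor_stream("plate", t_pl,
                           list(cop_x = cop_x, cop_y = cop_y),
                           nominal_rate = config$plate_rate, units = "mm")
    ground_truth <- data.frame(
      subject = as.integer(subject_id),
      squat = seq_len(ns),
      true_unstable = unstable,
      osc_amp_m = amp,
      osc_freq_hz = freq,
      depth_m = depth,
      t_on = t_on,
      t_off = t_off
    )
    list(camera = camera, plate = plate, ground_truth = ground_truth)
  })
}

#' Generate a full synthetic cohort
#'
#' @param config A [synth_config()].
#' @param subjects Subject ids; defaults to `1:n_subjects`.
#' @return A list with `sessions` (list of [generate_session()] results, named
#'   by subject) and `ground_truth` (row-bound table across subjects).
#' @export
generate_cohort <- function(config, subjects = seq_len(config$n_subjects)) {
  validate_synth_config(config)
  sessions <- lapply(subjects, function(s) generate_session(config, s))
  names(sessions) <- paste0("subject_", subjects)
  list(sessions = sessions,
       ground_truth = do.call(rbind, lapply(sessions, `[[`, "ground_truth")))
}

#' Write a sensor stream or ground-truth table to CSV
#'
#' Streams are written with columns `t_sec, <channel...>`; ground truth with
#' `subject,squat,true_unstable,osc_amp_m,osc_freq_hz,depth_m,t_on,t_off`.
#'
#' @param x A `sensor_stream` or ground-truth data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream_csv <- function(x, path) {
  if (inherits(x, "sensor_stream")) {
    df <- data.frame(t_sec = x$timestamps)
    for (nm in names(x$channels)) df[[nm]] <- x$channels[[nm]]
  } else {
    df <- as.data.frame(x)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
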