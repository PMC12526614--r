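# Shared fixtures: small synthetic configurations and a cohort-to-dataset
# pipeline helper used across module tests.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 2L, squats_per_subject = 8L, seed = 42L)
  do.call(synth_config, utils::modifyList(defaults, args))
}

noiseless_config <- function(...) {
  tiny_config(noise_sd_camera = 0, noise_sd_cop = 0, ...)
}

# Run synth -> preprocess -> segment -> features -> dataset for a cohort.
cohort_dataset <- function(config, scope = "per_subject") {
  feats <- list()
  gts <- list()
  for (s in seq_len(config$n_subjects)) {
    sess <- generate_session(config, s)
    gts[[s]] <- sess$ground_truth
    fl <- lowpass(synchronize(sess$camera, sess$plate, subject = s))
    b <- detect_squats(fl)
    y_t1 <- attr(b, "y_t1")
    for (i in seq_len(nrow(b))) {
      cyc <- extract_window(fl, b[i, ], y_t1 = y_t1, squat = i)
      feats[[length(feats) + 1L]] <- squat_features(cyc)
    }
  }
  build_dataset(feats, scope = scope, ground_truth = do.call(rbind, gts))
}

# Pairwise (Mann-Whitney) AUC oracle: probability a random positive outscores
# a random negative, ties counted one half.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# A synced_session built directly from channel values on a uniform grid.
make_session <- function(t, x_lk = 0 * t, x_rk = 0 * t, y_torso = 0 * t + 1,
                         cop_x = 0 * t, cop_y = 0 * t, subject = 1L) {
  structure(list(subject = subject, t = t, dt = t[2] - t[1],
                 x_lk = x_lk, x_rk = x_rk, y_torso = y_torso,
                 cop_x = cop_x, cop_y = cop_y),
            class = "synced_session")
}

# Amplitude of the tone at frequency f in a series (least squares on a
# sin/cos basis over the central portion, avoiding filter edge effects).
tone_amplitude <- function(x, t, f, trim = 0.2) {
  n <- length(t)
  keep <- seq.int(floor(n * trim) + 1L, ceiling(n * (1 - trim)))
  fit <- stats::lm(x[keep] ~ sin(2 * pi * f * t[keep]) + cos(2 * pi * f * t[keep]))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
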