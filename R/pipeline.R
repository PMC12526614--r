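# End-to-end pipeline orchestration: synth -> preprocess -> segment ->
# features -> select -> classify -> evaluate, from a single nested config.

#' Default pipeline configuration
#'
#' Nested blocks mirror the pipeline stages.  Stage defaults follow the
#' emulated protocol where it states a value (4th-order 5 Hz low-pass,
#' 20-sample time normalization, 0.03 m/s threshold, 50/60 Hz rates); the
#' rest are documented package choices.
#'
#' @param seed Mandatory integer seed driving every random stage.
#' @param ... Named overrides for top-level blocks (`synth`, `filter`,
#'   `segmentation`, `features`, `selection`, `train`, `sets`), each a list
#'   of field overrides, plus scalar fields `target_rate`.
#' @return A `pipeline_config` nested list.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    target_rate = 50,
    synth = unclass(synth_config())[setdiff(names(unclass(synth_config())),
                                            "seed")],
    filter = list(cutoff = 5, order = 4, zero_phase = TRUE, method = "fft"),
    segmentation = list(min_depth = 0.15, dur_bounds = c(1, 10),
                        min_depth_on = 0.05, n_time = 20L),
    features = list(threshold = 0.03, stat = "max", ks_mode = "magnitude",
                    scope = "per_subject"),
    train = list(hidden = 32L, epochs = 100L, batch = 32L, lr = 1e-3,
                 split = 0.8, class_weights = FALSE, svm_cost = 1),
    sets = default_feature_sets(),
    models = c("lstm", "svm")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    abort_if(!nm %in% names(cfg), "unknown config block '", nm, "'")
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) && nm != "sets") {
      for (k in names(dots[[nm]])) {
        abort_if(!k %in% names(cfg[[nm]]),
                 "unknown config key '", nm, ".", k, "'")
        cfg[[nm]][[k]] <- dots[[nm]][[k]]
      }
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema check (unknown keys are errors at construction) plus cross-field
#' invariants; returns diagnostics instead of stopping so a CLI can report
#' them all.
#'
#' @param cfg A `pipeline_config`, or a path to a YAML/JSON file of overrides.
#' @return Character vector of diagnostics; empty when valid.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  diags <- character(0)
  if (is.null(cfg$seed)) diags <- c(diags, "seed is mandatory")
  nyq <- cfg$target_rate / 2
  if (cfg$filter$cutoff >= nyq) {
    diags <- c(diags, sprintf(
      "filter.cutoff (%g Hz) must be below the grid Nyquist rate (%g Hz)",
      cfg$filter$cutoff, nyq))
  }
  sy <- tryCatch({
    do.call(synth_config, c(cfg$synth, list(seed = cfg$seed %||% 1L)))
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(sy)) diags <- c(diags, sy)
  if (cfg$train$split <= 0 || cfg$train$split >= 1) {
    diags <- c(diags, "train.split must lie in (0, 1)")
  }
  diags
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys must name known config blocks; unknown keys are errors
#' (typo safety).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file of overrides.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- raw$seed
  abort_if(is.null(seed), "configuration error: seed is mandatory")
  raw$seed <- NULL
  if (!is.null(raw$sets)) {
    raw$sets <- stats::setNames(
      lapply(raw$sets, function(s) as.integer(strsplit(as.character(s), ",")[[1]])),
      vapply(raw$sets, as.character, ""))
  }
  do.call(pipeline_config, c(list(seed = seed), raw))
}

# Process one generated session through preprocess/segment/features.
process_session <- function(session, cfg) {
  synced <- synchronize(session$camera, session$plate,
                        target_rate = cfg$target_rate,
                        subject = session$ground_truth$subject[1])
  filtered <- lowpass(synced, cutoff = cfg$filter$cutoff,
                      order = cfg$filter$order,
                      zero_phase = cfg$filter$zero_phase,
                      method = cfg$filter$method)
  bounds <- detect_squats(filtered, min_depth = cfg$segmentation$min_depth,
                          dur_bounds = cfg$segmentation$dur_bounds,
                          min_depth_on = cfg$segmentation$min_depth_on)
  y_t1 <- attr(bounds, "y_t1")
  feats <- lapply(seq_len(nrow(bounds)), function(i) {
    cyc <- extract_window(filtered, bounds[i, ], y_t1 = y_t1, squat = i)
    squat_features(cyc, n = cfg$segmentation$n_time,
                   threshold = cfg$features$threshold,
                   stat = cfg$features$stat, ks_mode = cfg$features$ks_mode)
  })
  list(synced = filtered, bounds = bounds, features = feats,
       n_rejected = attr(bounds, "n_rejected"))
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, synchronizes and filters each session,
#' segments squats, computes features and labels, builds the dataset, ranks
#' features, trains and evaluates both classifiers on the configured feature
#' sets, and writes every stage artifact plus a manifest to `out_dir`.
#' Reruns with an identical config are bit-identical.
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param write_streams Also write the per-subject raw stream CSVs (large;
#'   default writes only the first subject as a format witness).
#' @return Invisibly, a list with `dataset`, `ranking`, `report`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir, write_streams = FALSE) {
  diags <- validate_config(cfg)
  abort_if(length(diags) > 0, "invalid pipeline config: ",
           paste(diags, collapse = "; "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(synth_config, c(cfg$synth, list(seed = cfg$seed)))

  stage <- function(name) message("[squatstab] stage: ", name)
  paths <- character(0)

  stage("synth")
  all_features <- list()
  gt <- list()
  n_det <- 0L; n_rej <- 0L
  for (s in seq_len(scfg$n_subjects)) {
    sess <- generate_session(scfg, s)
    gt[[s]] <- sess$ground_truth
    if (write_streams || s == 1L) {
      p1 <- file.path(out_dir, sprintf("subject%02d_camera.csv", s))
      p2 <- file.path(out_dir, sprintf("subject%02d_plate.csv", s))
      write_stream_csv(sess$camera, p1)
      write_stream_csv(sess$plate, p2)
      paths <- c(paths, p1, p2)
    }
    proc <- process_session(sess, cfg)
    if (s == 1L) {
      p <- file.path(out_dir, "subject01_synced.csv")
      write_session_csv(proc$synced, p)
      paths <- c(paths, p)
    }
    n_det <- n_det + length(proc$features)
    n_rej <- n_rej + proc$n_rejected
    all_features <- c(all_features, proc$features)
  }
  ground_truth <- do.call(rbind, gt)
  p <- file.path(out_dir, "ground_truth.csv")
  write_stream_csv(ground_truth, p)
  paths <- c(paths, p)
  message(sprintf("[squatstab] segmented %d squats (%d rejected)", n_det, n_rej))

  stage("features")
  dataset <- build_dataset(all_features, scope = cfg$features$scope,
                           ground_truth = ground_truth)
  fp <- file.path(out_dir, "features.csv")
  lp <- file.path(out_dir, "labels.csv")
  write_dataset_csv(dataset, fp, lp)
  paths <- c(paths, fp, lp)
  message(sprintf("[squatstab] labeled %d KI / %d NKI",
                  sum(dataset$labels == 1), sum(dataset$labels == 0)))

  stage("rank")
  ranking <- rank_features(dataset)
  p <- file.path(out_dir, "ranking.csv")
  utils::write.csv(as.data.frame(ranking), p, row.names = FALSE)
  paths <- c(paths, p)

  stage("train/evaluate")
  tcfg <- do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  report <- compare_feature_sets(dataset, sets = cfg$sets,
                                 models = cfg$models, cfg = tcfg)
  full_ids <- cfg$sets[[1]]
  train_idx <- stratified_split(dataset$labels, tcfg$split, tcfg$seed)
  ds_full <- make_set(dataset, full_ids)
  models <- list()
  if ("lstm" %in% cfg$models) {
    models$lstm <- train_lstm(subset_dataset(ds_full, train_idx), tcfg)
  }
  if ("svm" %in% cfg$models) {
    models$svm <- train_svm(subset_dataset(ds_full, train_idx), tcfg)
  }
  for (nm in names(models)) {
    p <- file.path(out_dir, paste0("model_", nm, ".json"))
    write_model_json(models[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "report.csv")
  utils::write.csv(as.data.frame(report), p, row.names = FALSE)
  paths <- c(paths, p)

  stage("manifest")
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, cfg_path)
  manifest <- list(
    package = "squatstab",
    version = as.character(utils::packageVersion("squatstab")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = list(
      streams = basename(paths[grepl("camera|plate", paths)]),
      synced = "subject01_synced.csv",
      ground_truth = "ground_truth.csv",
      dataset = c("features.csv", "labels.csv"),
      ranking = "ranking.csv",
      models = paste0("model_", names(models), ".json"),
      report = "report.csv"
    ),
    counts = list(squats = n_det, rejected = n_rej,
                  ki = sum(dataset$labels == 1),
                  nki = sum(dataset$labels == 0)),
    file_md5 = as.list(tools::md5sum(sort(paths)))
  )
  names(manifest$file_md5) <- basename(sort(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dataset = dataset, ranking = ranking, report = report,
                 models = models, manifest = manifest))
}
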