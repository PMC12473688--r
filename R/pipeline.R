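# Run configuration and the end-to-end pipeline:
# tracks -> canonicalize -> steps -> indicators -> aggregate -> classify ->
# evaluate.

#' Default run configuration
#'
#' Nested list mirroring each stage's tunables. Unknown keys in a user
#' config are rejected at load time.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    io = list(max_gap = 3L),
    gait = list(speed_frac = 0.15, min_run = 3L, initial_phase_frac = 0.2),
    indicators = list(angle_mode = "raw", leg_window = 10L),
    aggregate = list(window = 5L, spine_blend = 0.5),
    expert = list(theta_head_7 = NA_real_, theta_spine_12_36 = NA_real_,
                  theta_spine_1_2 = NA_real_, theta_legs_3_46 = NA_real_,
                  theta_head_45_6 = NA_real_, merged_45_output = 4.5),
    ml = list(family = "random_forest", task = "grade7"),
    dl = list(seq_len = 120L, epochs = 30L, batch_size = 16L,
              learning_rate = 2e-3, dropout = 0),
    evaluate = list(task = "grade7")
  )
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys at
#' any level raise an error naming the key, so typos never silently fall
#' back to defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Merged configuration list.
#' @export
load_config <- function(path = NULL) {
  base <- default_config()
  if (is.null(path)) return(base)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(base))
        stop("unknown config key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(user[[k]]))
        base[[k]] <- merge_cfg(base[[k]], user[[k]], paste0(prefix, k, "."))
      else base[[k]] <- user[[k]]
    }
    base
  }
  merge_cfg(base, user)
}

#' Compute aggregated features for a set of tracks
#'
#' Runs ingestion (gap filling, canonicalization), step detection,
#' indicator computation and aggregation for each track, returning the
#' per-passage feature table.
#'
#' @param tracks list of [passage_track()] objects (raw or canonical).
#' @param config configuration list (see [default_config()]).
#' @return Data frame, one row per passage (see [build_features()]).
#' @export
pipeline_features <- function(tracks, config = default_config()) {
  rows <- lapply(tracks, function(tr) {
    tr <- interpolate_missing(tr, config$io$max_gap)
    tr <- canonicalize_track(tr)
    steps <- detect_steps(tr, speed_frac = config$gait$speed_frac,
                          min_run = config$gait$min_run)
    ser <- suppressWarnings(compute_indicators(
      tr, steps, angle_mode = config$indicators$angle_mode,
      leg_window = config$indicators$leg_window))
    build_features(ser, blend_weight = config$aggregate$spine_blend,
                   window = config$aggregate$window,
                   initial_phase_frac = config$gait$initial_phase_frac)
  })
  do.call(rbind, rows)
}

#' Run the full scoring pipeline over a track set
#'
#' Computes features, scores every passage with the chosen backend, and —
#' when ground-truth labels are present — assembles the evaluation report.
#' The pipeline is a pure function of (tracks, config, seed): rerunning
#' with the same inputs reproduces the predictions exactly.
#'
#' @param tracks list of [passage_track()] objects, or a directory path
#'   containing track files readable by [read_track()].
#' @param config configuration list (see [default_config()]).
#' @param backend `"expert"` (thresholds from config, or calibrated on the
#'   labeled tracks when the config thresholds are `NA`), `"ml"`
#'   (leave-one-out predictions of the configured family), or `"dl"`
#'   (sequence classifier; trained on the labeled tracks).
#' @return List with `features`, `predictions` (data frame
#'   `passage_id, prediction`), and `report` (an `evaluation_report`, or
#'   `NULL` without labels).
#' @export
run_pipeline <- function(tracks, config = default_config(),
                         backend = c("expert", "ml", "dl")) {
  backend <- match.arg(backend)
  if (is.character(tracks)) {
    files <- list.files(tracks, pattern = "\\.(json|csv)$", full.names = TRUE)
    files <- files[!grepl("manifest", files)]
    if (!length(files)) stop("stage read_tracks: no track files in ", tracks)
    tracks <- lapply(files, read_track)
  }
  feats <- pipeline_features(tracks, config)
  labels <- feats$label
  has_labels <- !all(is.na(labels))

  if (backend == "expert") {
    ec <- config$expert
    cfg <- if (any(is.na(unlist(ec[startsWith(names(ec), "theta")])))) {
      if (!has_labels)
        stop("stage expert: no thresholds in config and no labels to calibrate on")
      calibrate_thresholds(feats, merged_45_output = ec$merged_45_output)
    } else expert_config(ec$theta_head_7, ec$theta_spine_12_36,
                         ec$theta_spine_1_2, ec$theta_legs_3_46,
                         ec$theta_head_45_6, ec$merged_45_output)
    preds <- classify_expert(feats, cfg)
  } else if (backend == "ml") {
    if (!has_labels) stop("stage ml: labels required for LOO evaluation")
    spec <- ml_spec(config$ml$family, config$ml$task, seed = config$seed)
    lab <- if (config$ml$task == "binary") {
      bm <- binary_map(labels)
      keep <- !bm$excluded
      feats <- feats[keep, , drop = FALSE]
      labels <- labels[keep]
      as.character(bm$label[keep])
    } else labels
    preds <- fit_predict_loo(feats, lab, spec)
  } else {
    if (!has_labels) stop("stage dl: labels required to train")
    cfgd <- config$dl
    nc <- net_config(seq_len = cfgd$seq_len, epochs = cfgd$epochs,
                     batch_size = cfgd$batch_size,
                     learning_rate = cfgd$learning_rate,
                     dropout = cfgd$dropout, seed = config$seed)
    seqs <- lapply(tracks, function(tr) {
      tr <- canonicalize_track(interpolate_missing(tr, config$io$max_gap))
      build_sequence(suppressWarnings(compute_indicators(tr)), cfgd$seq_len)
    })
    model <- train_cnn_bilstm(seqs, labels, nc)
    preds <- predict_grades(model, seqs)
  }

  report <- NULL
  if (has_labels) {
    task <- if (backend == "ml") config$ml$task else config$evaluate$task
    yt <- labels[!is.na(labels)]
    yp <- preds[!is.na(labels)]
    report <- evaluate_predictions(yt, yp, task = task)
  }
  list(features = feats,
       predictions = data.frame(passage_id = feats$passage_id,
                                prediction = preds),
       report = report)
}
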