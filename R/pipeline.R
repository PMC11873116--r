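# Configuration-driven orchestration: synthetic cohort (or user manifest)
# -> preprocessing -> phonation + spectral features -> spectrograms ->
# repeated-holdout evaluation -> JSON/CSV report.

pipelineDefaults <- function() {
  list(
    synth = list(enabled = TRUE, n_pd = 10L, n_hc = 10L, seed = 1L),
    manifest = NULL,            # CSV path with subject_id,label,sex,path,channel
    channel = "smartphone",     # telephone | smartphone
    analysis_fs = 8820,         # telephone material at 8000 passes through
    clip_s = 1.5,
    features = list(spectral_kinds = c("mfcc"), stat = "var"),
    spectrograms = list(scales = c("mel"), image_size = 128L),
    model = "random_forest",    # random_forest | stepwise_lr | cnn_head
    rf = list(n_trees = 1000L, vars_per_split = 6L, min_node = 5L),
    cnn = list(epochs = 10L, batch_size = 4L, dropout = 0.2, lr = 0.001),
    n_iter = 100L,
    train_frac = 0.7,
    seed = 1L,
    out_dir = NULL
  )
}

# Recursively check cfg against the default skeleton: unknown keys are
# errors (no silent typos).
checkKeys <- function(cfg, defaults, path = "") {
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad))
    stop("unknown configuration key", if (length(bad) > 1) "s" else "", ": ",
         paste0(path, bad, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(cfg[[nm]]))
      checkKeys(cfg[[nm]], defaults[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a named list; unknown keys raise an
#' error naming the key, missing keys take the defaults (which equal the
#' evaluated protocol's printed settings: 1.5 s clips, 100 x 70/30
#' repeated holdout, RF with 1000 trees / 6 candidate variables / node
#' size 5, head training for 10 epochs at batch 4 with 20% dropout and
#' adam at 0.001).
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, a named list, or
#'   NULL for pure defaults.
#' @return Fully-defaulted configuration list (class
#'   `"PipelineConfig"`).
#' @export
validateConfig <- function(config = NULL) {
  defaults <- pipelineDefaults()
  cfg <- if (is.null(config)) list()
    else if (is.character(config)) {
      ext <- tolower(sub(".*\\.", "", config))
      if (ext %in% c("yaml", "yml")) {
        out <- yaml::read_yaml(config)
        if (is.null(out)) list() else out
      } else if (ext == "json") jsonlite::read_json(config, simplifyVector = TRUE)
      else stop("unsupported config format: ", ext)
    } else if (is.list(config)) config
    else stop("'config' must be a path, a list, or NULL")
  checkKeys(cfg, defaults)
  cfg <- utils::modifyList(defaults, cfg)
  if (cfg$n_iter < 1) stop("configuration violation: 'n_iter' must be >= 1")
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stop("configuration violation: 'train_frac' must lie in (0, 1)")
  if (!cfg$channel %in% c("telephone", "smartphone"))
    stop("configuration violation: unknown channel '", cfg$channel, "'")
  if (!cfg$model %in% c("random_forest", "stepwise_lr", "cnn_head"))
    stop("configuration violation: unknown model '", cfg$model, "'")
  structure(cfg, class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Stages in fixed order: obtain recordings (synthetic cohort or user
#' manifest of WAV files), preprocess each (normalize, decimate, trim,
#' longest voiced segment; recordings shorter than `clip_s` after
#' trimming are excluded with reason `too-short`), compute the 23-entry
#' phonation vector and the requested spectral summaries, build combined
#' feature vectors, generate spectrograms, and evaluate the configured
#' classifier by repeated holdout. Deterministic given the seeds in the
#' configuration.
#'
#' @param config a `PipelineConfig` (or anything [validateConfig()]
#'   accepts).
#' @param work_dir directory for synthetic audio and reports (default: a
#'   session temp directory).
#' @return A run-report list: per-stage counts, exclusions (with
#'   machine-readable reasons), the [EvalResult-class], importance table
#'   (random forest), feature table, and the config echo. Written as
#'   `report.json` plus CSVs when `out_dir` is set.
#' @export
runPipeline <- function(config = NULL, work_dir = NULL) {
  cfg <- if (inherits(config, "PipelineConfig")) config else validateConfig(config)
  if (is.null(work_dir)) work_dir <- file.path(tempdir(), "pdvoice-run")
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)

  # --- stage 1: recordings ---
  if (isTRUE(cfg$synth$enabled)) {
    cs <- cohortSpec(n_pd = cfg$synth$n_pd, n_hc = cfg$synth$n_hc,
                     channel = channelSpec(cfg$channel),
                     seed = stageSeed(cfg$seed, "cohort"))
    cohort <- generateCohort(cs, file.path(work_dir, "audio"))
    manifest <- cohort$manifest
  } else {
    if (is.null(cfg$manifest)) stop("no manifest configured and synth disabled")
    manifest <- utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
    need <- c("subject_id", "label", "path")
    if (!all(need %in% names(manifest)))
      stop("manifest must provide columns: ", paste(need, collapse = ", "))
  }

  # --- stage 2: preprocessing ---
  exclusions <- data.frame(subject_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  segments <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    res <- tryCatch(
      preprocessWaveform(readWav(manifest$path[i]),
                         analysis_fs = cfg$analysis_fs, min_s = cfg$clip_s),
      error = function(e) e)
    if (inherits(res, "error")) {
      reason <- if (grepl("^too-short", conditionMessage(res))) "too-short"
        else if (grepl("voiced", conditionMessage(res))) "unvoiced"
        else "unreadable"
      exclusions <- rbind(exclusions,
                          data.frame(subject_id = sid, reason = reason,
                                     stringsAsFactors = FALSE))
    } else segments[[sid]] <- res
  }
  kept <- manifest[manifest$subject_id %in% names(segments), ]

  # --- stage 3: features ---
  pmf_list <- lapply(names(segments), function(sid)
    phonationFeatures(segments[[sid]], sid))
  names(pmf_list) <- names(segments)
  # spectral blocks (in configured order) then the phonation block
  feat_mat <- do.call(rbind, lapply(names(segments), function(sid) {
    row <- numeric(0)
    for (kind in cfg$features$spectral_kinds) {
      track <- spectralCoefficients(segments[[sid]], kind = kind)
      ss <- summarizeCoefficients(track, subject_id = sid, kind = kind)
      v <- if (cfg$features$stat == "var") ss@var_vec else ss@mean_vec
      names(v) <- paste0(kind, "_", cfg$features$stat, seq_along(v))
      row <- c(row, v)
    }
    c(row, pmf_list[[sid]][phonationFeatureNames()])
  }))
  if (is.null(feat_mat))
    feat_mat <- matrix(numeric(0), nrow = 0, ncol = 0)
  else rownames(feat_mat) <- names(segments)
  complete <- if (nrow(feat_mat)) stats::complete.cases(feat_mat) else logical(0)
  if (any(!complete))
    exclusions <- rbind(exclusions,
      data.frame(subject_id = rownames(feat_mat)[!complete],
                 reason = "incomplete-features", stringsAsFactors = FALSE))
  feat_mat <- feat_mat[complete, , drop = FALSE]
  kept <- kept[kept$subject_id %in% rownames(feat_mat), ]

  # --- stage 4: spectrograms ---
  spectrograms <- list()
  for (scale in cfg$spectrograms$scales) {
    mats <- lapply(kept$subject_id, function(sid)
      (if (scale == "mel") melSpectrogram else linearSpectrogram)(
        centerClip(segments[[sid]], cfg$clip_s)))
    names(mats) <- kept$subject_id
    spectrograms[[scale]] <- mats
  }

  # --- stage 5: evaluation ---
  labels <- kept$label[match(rownames(feat_mat), kept$subject_id)]
  spec <- switch(cfg$model,
    random_forest = modelSpec("random_forest", n_trees = cfg$rf$n_trees,
      vars_per_split = cfg$rf$vars_per_split, min_node = cfg$rf$min_node),
    stepwise_lr = modelSpec("stepwise_lr"),
    cnn_head = modelSpec("cnn_head", epochs = cfg$cnn$epochs,
      batch_size = cfg$cnn$batch_size, dropout = cfg$cnn$dropout,
      lr = cfg$cnn$lr))
  eval_seed <- stageSeed(cfg$seed, "holdout")
  if (cfg$model == "cnn_head") {
    scale <- cfg$spectrograms$scales[1L]
    ds <- imageDataset(spectrograms[[scale]], labels,
                       subject_ids = kept$subject_id,
                       size = cfg$spectrograms$image_size)
  } else {
    ds <- featureDataset(feat_mat, labels)
  }
  eval_res <- tryCatch(
    repeatedHoldout(ds, spec, n_iter = cfg$n_iter,
                    train_frac = cfg$train_frac, seed = eval_seed,
                    keep_last = TRUE),
    error = function(e) e)
  eval_failed <- inherits(eval_res, "error")
  importance <- if (!eval_failed && cfg$model == "random_forest")
    attr(eval_res, "last_model")$importance else NULL

  report <- list(
    config = unclass(cfg),
    counts = list(recordings_in = nrow(manifest),
                  recordings_kept = nrow(feat_mat),
                  excluded = nrow(exclusions)),
    exclusions = exclusions,
    auc = if (eval_failed) numeric(0) else eval_res@auc,
    auc_summary = if (eval_failed) NULL else summary(eval_res),
    error = if (eval_failed)
      paste("evaluation failed:", conditionMessage(eval_res)) else NULL,
    importance = importance,
    version = as.character(utils::packageVersion("pdvoice")))
  if (eval_failed) eval_res <- NULL

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report[setdiff(names(report), "importance")],
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(data.frame(iteration = seq_along(report$auc),
                                auc = report$auc),
                     file.path(cfg$out_dir, "auc.csv"), row.names = FALSE)
    utils::write.csv(cbind(subject_id = rownames(feat_mat),
                           as.data.frame(feat_mat)),
                     file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(importance))
      utils::write.csv(importance, file.path(cfg$out_dir, "importance.csv"),
                       row.names = FALSE)
  }
  report$eval <- eval_res
  report$features <- feat_mat
  report$spectrograms <- spectrograms
  report$segments <- segments
  report$manifest <- manifest
  report
}

#' Summarize evaluation reports as a comparison table
#'
#' One row per report (feature set / representation), mean AUC formatted
#' to two decimals per classifier; when exactly two reports are given a
#' Wilcoxon rank-sum comparison column of their AUC samples is included.
#'
#' @param reports named list of run reports (from [runPipeline()]) or
#'   [EvalResult-class] objects.
#' @return data.frame comparison table.
#' @export
summarizeResults <- function(reports) {
  if (!length(reports)) stop("need at least one report")
  if (is.null(names(reports))) names(reports) <- paste0("run", seq_along(reports))
  getEval <- function(r) if (is(r, "EvalResult")) r else r$eval
  rows <- lapply(names(reports), function(nm) {
    ev <- getEval(reports[[nm]])
    data.frame(representation = nm, classifier = ev@model,
               mean_auc = sprintf("%.2f", mean(ev@auc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(reports) == 2L) {
    cmp <- compareAucDistributions(getEval(reports[[1L]]),
                                   getEval(reports[[2L]]))
    out$wilcoxon_p <- c(sprintf("%.3g", cmp$p_value), "")
  }
  out
}
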