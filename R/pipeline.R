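# End-to-end orchestration: simulate -> cohort -> eventlog -> discover ->
# tss -> train -> evaluate (-> baselines -> shapley), with per-stage
# artifacts, manifests (input hashes + seed) and idempotent re-runs.

#' Pipeline configuration
#'
#' Single nested configuration covering every stage; serializable to YAML
#' via [write_pipeline_config()].
#'
#' @param synthetic a [synthetic_config()].
#' @param cohort a [cohort_spec()].
#' @param split_ratios train/validation/test ratios.
#' @param frequency_threshold discovery directly-follows threshold.
#' @param art_k artificial-event cluster count.
#' @param normalize_tss min-max normalize TSS features.
#' @param tss_components TSS state components to include.
#' @param nn an [nn_config()].
#' @param baselines_mode baseline input mode (`"tabular"` or `"tss"`), or
#'   `NULL` to skip baselines.
#' @param threshold classification threshold on the positive-class score.
#' @param seed global seed; stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            cohort = cohort_spec(),
                            split_ratios = c(0.731, 0.129, 0.140),
                            frequency_threshold = 1,
                            art_k = 30,
                            normalize_tss = TRUE,
                            tss_components = c("decay", "count", "marking"),
                            nn = nn_config(),
                            baselines_mode = "tabular",
                            threshold = 0.5,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `pipeline_config`.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  # yaml drops names of atomic vectors; keep the named maps as maps
  plain$synthetic$comorbidity_prevalences <-
    as.list(config$synthetic$comorbidity_prevalences)
  plain$synthetic$code_vocab_sizes <- as.list(config$synthetic$code_vocab_sizes)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$synthetic$lab_panel <- as.data.frame(y$synthetic$lab_panel)
  y$synthetic$comorbidity_prevalences <- unlist(y$synthetic$comorbidity_prevalences)
  y$synthetic$code_vocab_sizes <- unlist(y$synthetic$code_vocab_sizes)
  syn <- do.call(synthetic_config, y$synthetic)
  coh <- do.call(cohort_spec, y$cohort)
  nn <- do.call(nn_config, y$nn[setdiff(names(y$nn), character(0))])
  pipeline_config(synthetic = syn, cohort = coh,
                  split_ratios = unlist(y$split_ratios),
                  frequency_threshold = y$frequency_threshold,
                  art_k = y$art_k, normalize_tss = y$normalize_tss,
                  tss_components = unlist(y$tss_components), nn = nn,
                  baselines_mode = y$baselines_mode,
                  threshold = y$threshold, seed = y$seed)
}

stage_manifest <- function(outdir, stage, files, meta = list()) {
  manifest <- list(stage = stage, created = format(Sys.time(), tz = "UTC"),
                   meta = meta,
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

stage_done <- function(outdir, stage)
  file.exists(file.path(outdir, paste0(stage, ".manifest.json")))

#' Run the pipeline
#'
#' Executes the requested stages in order, writing artifacts and manifests
#' under `outdir`. Stages whose manifest already exists are not rewritten
#' unless `force = TRUE` (logged as up-to-date).
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory.
#' @param stages `"all"` or a subset of
#'   `c("simulate","cohort","eventlog","discover","tss","train","evaluate",
#'   "baselines","shapley")`.
#' @param force rewrite artifacts even when up to date.
#' @param quiet suppress progress messages.
#' @return Invisible list with the in-memory objects of the executed
#'   stages (tables, split, net, alphas, bundles, model, metrics,
#'   baselines, shapley).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = "dreamhf-run",
                         stages = "all", force = FALSE, quiet = FALSE) {
  all_stages <- c("simulate", "cohort", "eventlog", "discover", "tss",
                  "train", "evaluate", "baselines", "shapley")
  if (identical(stages, "all"))
    stages <- setdiff(all_stages, if (is.null(config$baselines_mode)) "baselines")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_config("unknown stage '%s'", bad[1L])
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(stage, writer, files) {
    if (stage_done(outdir, stage) && !force) {
      say("[%s] up-to-date", stage)
    } else {
      writer()
      stage_manifest(outdir, stage, files, meta = list(seed = config$seed))
      say("[%s] written", stage)
    }
  }
  st <- list()

  # stage computations are deterministic in the config, so later stages can
  # recompute upstream objects in memory even when artifacts are up to date
  st$tables <- generate_ehr(config$synthetic)
  if ("simulate" %in% stages) {
    ehr_dir <- file.path(outdir, "ehr")
    emit("simulate", function() write_ehr_tables(st$tables, ehr_dir),
         file.path(ehr_dir, ehr_file_names))
  }

  members <- select_cohort(st$tables, config$cohort)
  st$split <- split_cohort(members, config$split_ratios, seed = config$seed)
  if ("cohort" %in% stages) {
    f <- file.path(outdir, "cohort.csv")
    emit("cohort", function() {
      rows <- do.call(rbind, lapply(names(st$split), function(p) {
        m <- st$split[[p]]
        data.frame(patient_id = m$patient_id,
                   index_admission_id = m$index_admission_id,
                   label = m$label,
                   discharge_time = num_to_iso(m$discharge_time), split = p)
      }))
      utils::write.csv(rows, f, row.names = FALSE)
    }, f)
  }

  st$art_model <- fit_artificial_events(st$tables, st$split$train,
                                        k = config$art_k, seed = config$seed)
  logs <- lapply(st$split, function(m)
    build_event_log(st$tables, m, st$art_model))
  if ("eventlog" %in% stages) {
    fs <- file.path(outdir, paste0("eventlog_", names(logs), ".xes"))
    emit("eventlog", function()
      for (i in seq_along(logs)) write_xes(logs[[i]], fs[i]), fs)
  }

  st$net <- discover_petri_net(logs$train, config$frequency_threshold)
  st$alphas <- estimate_decay_rates(st$net, logs$train)
  if ("discover" %in% stages) {
    f <- file.path(outdir, "model.pnml")
    emit("discover", function() write_pnml(st$net, f, alphas = st$alphas), f)
  }

  st$bundles <- assemble_features(st$tables, st$split, st$net, st$alphas,
                                  st$art_model,
                                  normalize_tss = config$normalize_tss,
                                  tss_components = config$tss_components)
  if ("tss" %in% stages) {
    fs <- file.path(outdir, paste0("tss_", names(st$bundles), ".csv"))
    emit("tss", function()
      for (i in seq_along(st$bundles))
        utils::write.csv(st$bundles[[i]]$tss, fs[i]), fs)
  }

  if (any(c("train", "evaluate", "baselines", "shapley") %in% stages)) {
    b <- st$bundles
    cfg <- config$nn
    cfg$seed <- config$seed
    st$model <- build_network(ncol(b$train$tss), ncol(b$train$demographics),
                              ncol(b$train$severity), cfg)
    st$model <- train_network(st$model, b$train, b$validation)
    if ("train" %in% stages) {
      f <- file.path(outdir, "training_history.csv")
      emit("train", function()
        utils::write.csv(st$model$history, f, row.names = FALSE), f)
    }
  }

  if ("evaluate" %in% stages) {
    st$metrics <- classification_metrics(predict(st$model, st$bundles$test),
                                         st$bundles$test$label,
                                         threshold = config$threshold)
    f <- file.path(outdir, "metrics_test.json")
    emit("evaluate", function()
      jsonlite::write_json(unclass(st$metrics), f, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA), f)
  }

  if ("baselines" %in% stages && !is.null(config$baselines_mode)) {
    st$baselines <- fit_baselines(st$bundles$train, st$bundles$validation,
                                  mode = config$baselines_mode,
                                  seed = config$seed)
    f <- file.path(outdir, "baselines.json")
    emit("baselines", function() {
      rows <- lapply(st$baselines, function(bl) list(
        params = bl$params, val_auroc = bl$val_auroc,
        test_auroc = auc_rank(
          predict(bl, st$bundles$test, mode = config$baselines_mode),
          st$bundles$test$label)))
      jsonlite::write_json(rows, f, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
    }, f)
  }

  if ("shapley" %in% stages) {
    st$shapley <- model_shapley(st$model, st$net, st$bundles$train,
                                st$bundles$test, seed = config$seed)
    f <- file.path(outdir, "shapley.csv")
    emit("shapley", function()
      utils::write.csv(st$shapley, f, row.names = FALSE), f)
  }

  invisible(st)
}
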