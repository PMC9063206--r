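# Variable and layer ablation drivers: re-run conversion -> discovery ->
# TSS -> training with one variable family removed from the event logs (or
# one branch input zeroed, or a layer variant), several repeats, and
# report the AUROC per variant. Discharge events are never removed: they
# carry the TSS marker.

EVENT_DROP_PATTERNS <- c(
  admission_insurance = "^(Admission_|Insurance_)",
  artificial = "^Artificial_",
  comorbidity = "^Elix_",
  lab = "_(mean|std)$")

filter_event_log <- function(log, pattern) {
  keep <- !grepl(pattern, log$events$name)
  ev <- log$events[keep, , drop = FALSE]
  rownames(ev) <- NULL
  n_by_case <- table(factor(ev$case_id, levels = log$cases$case_id))
  cases <- log$cases
  cases$tss_index <- as.integer(n_by_case)
  structure(list(events = ev, cases = cases), class = "hf_event_log")
}

# one full pipeline pass (shared by ablation_run and the orchestrator)
run_core <- function(tables, split, drop = "none",
                     nn_cfg = nn_config(), frequency_threshold = 1,
                     art_k = 30, seed = 1, normalize_tss = TRUE,
                     tss_components = c("decay", "count", "marking")) {
  art <- if (drop != "artificial")
    fit_artificial_events(tables, split$train, k = art_k, seed = seed)
  drop_pattern <- EVENT_DROP_PATTERNS[drop]
  build <- function(members, art_model) {
    log <- build_event_log(tables, members, art_model)
    if (!is.na(drop_pattern)) log <- filter_event_log(log, drop_pattern)
    log
  }
  log_tr <- build(split$train, art)
  net <- discover_petri_net(log_tr, frequency_threshold)
  alphas <- estimate_decay_rates(net, log_tr)
  bundles <- list()
  norm <- NULL; age_center <- NULL; impute <- NULL
  for (part in c("train", "validation", "test")) {
    members <- split[[part]]
    log <- if (part == "train") log_tr else build(members, art)
    tss <- tss_matrix(log, net, alphas, normalize = normalize_tss,
                      norm = norm, components = tss_components)
    demo <- demographics_matrix(tables, members, age_center)
    sev <- severity_matrix(tables, members)
    tab <- tabular_matrix(tables, members, demo, sev, impute)
    if (part == "train") {
      norm <- attr(tss, "norm")
      age_center <- attr(demo, "age_center")
      impute <- attr(tab, "impute")
    }
    if (drop == "severity") sev <- matrix(0, nrow(sev), 1,
                                          dimnames = list(rownames(sev), "zero"))
    if (drop == "demographics") demo <- matrix(0, nrow(demo), 1,
                                               dimnames = list(rownames(demo), "zero"))
    bundles[[part]] <- structure(
      list(tss = tss, demographics = demo, severity = sev, tabular = tab,
           label = members$label, case_id = members$patient_id),
      class = "feature_bundle")
  }
  list(net = net, alphas = alphas, art_model = art, bundles = bundles,
       nn_cfg = nn_cfg)
}

ablation_variants <- function() {
  c("none", "severity", "demographics", "admission_insurance", "artificial",
    "comorbidity", "lab", "layers_1", "layers_2", "layers_3", "layers_4",
    "no_post_concat")
}

#' Variable and layer ablation study
#'
#' Re-executes the full conversion/discovery/TSS/training pipeline with
#' one component removed and reports the test AUROC over `repeats`
#' retrainings (different network seeds, identical data). Variants:
#' `"none"` (base pipeline), the variable families `"severity"`,
#' `"demographics"`, `"admission_insurance"`, `"artificial"`,
#' `"comorbidity"`, `"lab"`, and the layer variants `"layers_1"` ..
#' `"layers_4"` (branch depth) and `"no_post_concat"`. Requesting removal
#' of discharge events is refused: they anchor the TSS marker.
#'
#' @param tables an `ehr_tables` object.
#' @param split named train/validation/test cohort list.
#' @param drop variant name (see above).
#' @param repeats number of retrainings per variant (default 10).
#' @param nn_cfg base [nn_config()].
#' @param frequency_threshold,art_k,seed pipeline parameters.
#' @return Data frame with `variant`, `rep`, `auroc` and attribute
#'   `"mean_auroc"`.
#' @export
ablation_run <- function(tables, split, drop = "none", repeats = 10,
                         nn_cfg = nn_config(), frequency_threshold = 1,
                         art_k = 30, seed = 1) {
  if (drop %in% c("discharge", "Discharge"))
    stop_config("discharge events are never removed: they mark the TSS state")
  if (!drop %in% ablation_variants())
    stop_config("unknown ablation variant '%s'", drop)
  layer_widths <- c(128, 64, 32, 16)
  core_drop <- if (drop %in% names(EVENT_DROP_PATTERNS) ||
                   drop %in% c("severity", "demographics")) drop else "none"
  if (startsWith(drop, "layers_")) {
    L <- as.integer(sub("layers_", "", drop))
    nn_cfg$branch_hidden <- layer_widths[seq_len(L)]
  }
  if (drop == "no_post_concat") nn_cfg$post_concat <- 0
  core <- run_core(tables, split, drop = core_drop, nn_cfg = nn_cfg,
                   frequency_threshold = frequency_threshold,
                   art_k = art_k, seed = seed)
  b <- core$bundles
  res <- lapply(seq_len(repeats), function(r) {
    cfg <- nn_cfg
    cfg$seed <- seed + r
    model <- build_network(ncol(b$train$tss), ncol(b$train$demographics),
                           ncol(b$train$severity), cfg)
    model <- train_network(model, b$train, b$validation)
    data.frame(variant = drop, rep = r,
               auroc = auc_rank(predict(model, b$test), b$test$label))
  })
  out <- do.call(rbind, res)
  attr(out, "mean_auroc") <- mean(out$auroc)
  out
}
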