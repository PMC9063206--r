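# Feature assembly: the three NN input vectors (TSS, demographics,
# severity) plus the tabular representation used by the baseline models'
# first input mode. All fitting of normalization parameters happens on the
# training split only.

ETHNICITY_LEVELS <- c("African American", "Hispanic", "Others non-Hispanic",
                      "White", "Asian")
ADMISSION_TYPES <- c("ELECTIVE", "EMERGENCY", "URGENT", "NEWBORN")
INSURANCE_LEVELS <- c("Medicare", "Medicaid", "Private", "Government", "Self-pay")

one_hot <- function(x, levels, prefix) {
  m <- vapply(levels, function(l) as.numeric(x == l), numeric(length(x)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(x))
  colnames(m) <- paste0(prefix, gsub("[^A-Za-z0-9]", "", levels))
  m
}

# age (years, standardized with train parameters), gender, ethnicity
demographics_matrix <- function(tables, members, age_center = NULL) {
  pat <- tables$patients
  i <- match(members$patient_id, pat$SUBJECT_ID)
  adm <- tables$admissions
  j <- match(members$index_admission_id, adm$HADM_ID)
  age <- (adm$ADMITTIME[j] - pat$DOB[i]) / (365.25 * DAY_S)
  if (is.null(age_center)) {
    age_center <- list(mean = mean(age), sd = max(stats::sd(age), 1e-9))
  }
  X <- cbind(age = (age - age_center$mean) / age_center$sd,
             one_hot(pat$GENDER[i], c("F", "M"), "gender_"),
             one_hot(pat$ETHNICITY[i], ETHNICITY_LEVELS, "eth_"))
  rownames(X) <- as.character(members$patient_id)
  attr(X, "age_center") <- age_center
  X
}

severity_matrix <- function(tables, members, elixhauser_scheme = "count") {
  rows <- t(vapply(seq_len(nrow(members)), function(i) {
    s <- scores_at_discharge(members[i, , drop = FALSE], tables,
                             elixhauser_scheme)
    c(charlson = s$charlson, elixhauser = s$elixhauser)
  }, numeric(2)))
  rownames(rows) <- as.character(members$patient_id)
  rows
}

# baseline tabular mode: the model's variables in the original flat
# per-admission format -- index admission type + insurance, the index
# admission's lab mean/std per analyte and Elixhauser group indicators,
# demographics and severity scores. Prior-visit history enters only
# through the severity scores; the multi-admission record is what the
# event-log representation adds on top of this format.
tabular_matrix <- function(tables, members, demo, sev, impute = NULL) {
  adm <- tables$admissions
  j <- match(members$index_admission_id, adm$HADM_ID)
  upto_ids <- as.list(members$index_admission_id)
  le <- tables$labevents
  le$label <- tables$d_labitems$LABEL[match(le$ITEMID, tables$d_labitems$ITEMID)]
  labs <- sort(unique(tables$d_labitems$LABEL))
  lab_block <- t(vapply(upto_ids, function(ids) {
    sub <- le[le$HADM_ID %in% ids, ]
    unlist(lapply(labs, function(l) {
      v <- sub$VALUENUM[sub$label == l]
      c(mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else if (length(v)) 0 else NA_real_)
    }))
  }, numeric(2 * length(labs))))
  colnames(lab_block) <- paste0(rep(labs, each = 2), c("_mean", "_sd"))
  d <- tables$diagnoses_icd
  groups <- elixhauser_group_names()
  elix_block <- t(vapply(upto_ids, function(ids) {
    as.numeric(groups %in% elixhauser_groups(d$ICD9_CODE[d$HADM_ID %in% ids]))
  }, numeric(length(groups))))
  colnames(elix_block) <- paste0("elix_", groups)
  X <- cbind(one_hot(adm$ADMISSION_TYPE[j], ADMISSION_TYPES, "admtype_"),
             one_hot(adm$INSURANCE[j], INSURANCE_LEVELS, "ins_"),
             lab_block, elix_block, demo, sev)
  if (is.null(impute)) {
    impute <- colMeans(X, na.rm = TRUE)
    impute[is.nan(impute)] <- 0
  }
  for (k in which(colSums(is.na(X)) > 0)) X[is.na(X[, k]), k] <- impute[k]
  rownames(X) <- as.character(members$patient_id)
  attr(X, "impute") <- impute
  X
}

#' Assemble train/validation/test feature bundles
#'
#' Builds, for each split, the three NN input matrices (`tss`,
#' `demographics`, `severity`), the baseline `tabular` matrix and the
#' `label` vector. TSS min-max normalization, age standardization and
#' tabular imputation are all fitted on the training split and applied to
#' the others.
#'
#' @param tables an `ehr_tables` object.
#' @param split named list `train`/`validation`/`test` from
#'   [split_cohort()].
#' @param net,alphas discovered net and decay rates (training data only).
#' @param art_model fitted [fit_artificial_events()] model (or `NULL`).
#' @param normalize_tss min-max normalize TSS columns (fit on train).
#' @param tss_components passed to [tss_matrix()].
#' @return Named list of three `feature_bundle` lists.
#' @export
assemble_features <- function(tables, split, net, alphas, art_model = NULL,
                              normalize_tss = TRUE,
                              tss_components = c("decay", "count", "marking")) {
  out <- list()
  norm <- NULL; age_center <- NULL; impute <- NULL
  for (part in c("train", "validation", "test")) {
    members <- split[[part]]
    log <- build_event_log(tables, members, art_model)
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
    out[[part]] <- structure(
      list(tss = tss, demographics = demo, severity = sev, tabular = tab,
           label = members$label, case_id = members$patient_id),
      class = "feature_bundle")
  }
  out
}
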