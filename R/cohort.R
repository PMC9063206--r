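# Heart-failure study cohort: inclusion/exclusion, 30-day unplanned
# readmission label, train/validation/test split.

#' Cohort selection rules
#'
#' @param hf_exact_codes ICD-9 codes matched exactly (after decimal
#'   normalization) to identify an HF diagnosis.
#' @param hf_prefix_codes ICD-9 prefixes matched as code families
#'   (default `"428"`, covering 428.xx).
#' @param window_days readmission window in days (> 0, boundary inclusive).
#' @param unplanned_types admission types counted as unplanned.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(hf_exact_codes = c("39891", "40201", "40211", "40291",
                                           "40401", "40403", "40411", "40413",
                                           "40491", "40493"),
                        hf_prefix_codes = "428",
                        window_days = 30,
                        unplanned_types = c("EMERGENCY", "URGENT")) {
  if (window_days <= 0) stop_config("window_days must be > 0")
  if (length(hf_exact_codes) + length(hf_prefix_codes) == 0)
    stop_config("HF code set must be non-empty")
  structure(list(hf_exact_codes = normalize_icd9(hf_exact_codes),
                 hf_prefix_codes = normalize_icd9(hf_prefix_codes),
                 window_days = window_days,
                 unplanned_types = unplanned_types),
            class = "cohort_spec")
}

is_hf_code <- function(codes, spec) {
  codes <- normalize_icd9(codes)
  hit <- codes %in% spec$hf_exact_codes
  for (p in spec$hf_prefix_codes) hit <- hit | startsWith(codes, p)
  hit
}

#' Select the heart-failure study cohort
#'
#' A patient is included when: the index admission (the most recent
#' admission that still has at least one subsequent admission) carries at
#' least one HF ICD-9 code; at least one admission precedes the index
#' admission; at least one admission follows it; and the patient is not
#' flagged deceased. Patients whose HF codes appear only in earlier
#' admissions are excluded.
#'
#' @param tables an `ehr_tables` object.
#' @param spec a [cohort_spec()].
#' @return A `hf_cohort` data frame sorted by `patient_id`, with columns
#'   `patient_id`, `index_admission_id`, `discharge_time`, `label` and a
#'   list column `prior_admission_ids` (ordered by admission time).
#' @export
select_cohort <- function(tables, spec = cohort_spec()) {
  adm <- tables$admissions
  if (nrow(adm) == 0L) {
    warning("empty admissions table: returning empty cohort")
    return(empty_cohort())
  }
  o <- order(adm$SUBJECT_ID, adm$ADMITTIME)
  adm <- adm[o, ]
  n_by_pat <- stats::ave(rep(1L, nrow(adm)), adm$SUBJECT_ID, FUN = cumsum)
  tot <- stats::ave(rep(1L, nrow(adm)), adm$SUBJECT_ID, FUN = length)
  # index = penultimate admission; requires >= 3 admissions so that a prior
  # and a subsequent admission both exist
  is_index <- tot >= 3L & n_by_pat == tot - 1L
  cand <- adm[is_index, ]

  dead <- tables$patients$SUBJECT_ID[tables$patients$EXPIRE_FLAG == 1L]
  cand <- cand[!(cand$SUBJECT_ID %in% dead), ]
  if (nrow(cand) == 0L) return(empty_cohort())

  d <- tables$diagnoses_icd
  hf_adm <- unique(d$HADM_ID[is_hf_code(d$ICD9_CODE, spec)])
  cand <- cand[cand$HADM_ID %in% hf_adm, ]
  if (nrow(cand) == 0L) return(empty_cohort())

  cand <- cand[order(cand$SUBJECT_ID), ]
  # adm is sorted by (patient, admit time); the index admission is the
  # penultimate one, so priors are everything before it
  by_pat <- split(adm$HADM_ID, adm$SUBJECT_ID)
  priors <- lapply(as.character(cand$SUBJECT_ID), function(p) {
    ids <- by_pat[[p]]
    ids[seq_len(length(ids) - 2L)]
  })
  members <- data.frame(
    patient_id = cand$SUBJECT_ID,
    index_admission_id = cand$HADM_ID,
    discharge_time = cand$DISCHTIME,
    stringsAsFactors = FALSE)
  members$prior_admission_ids <- priors
  members$label <- assign_label_vec(members, tables, spec)
  class(members) <- c("hf_cohort", "data.frame")
  members
}

empty_cohort <- function() {
  m <- data.frame(patient_id = numeric(0), index_admission_id = numeric(0),
                  discharge_time = numeric(0))
  m$prior_admission_ids <- list()
  m$label <- logical(0)
  class(m) <- c("hf_cohort", "data.frame")
  m
}

assign_label_vec <- function(members, tables, spec) {
  adm <- tables$admissions
  o <- order(adm$SUBJECT_ID, adm$ADMITTIME)
  by_admit <- split(adm$ADMITTIME[o], adm$SUBJECT_ID[o])
  by_type <- split(adm$ADMISSION_TYPE[o], adm$SUBJECT_ID[o])
  vapply(seq_len(nrow(members)), function(i) {
    p <- as.character(members$patient_id[i])
    at <- by_admit[[p]]
    j <- which(at > members$discharge_time[i])
    if (length(j) == 0L)
      stop_invariant("member %s has no subsequent admission",
                     members$patient_id[i])
    j <- j[1L]
    gap_days <- (at[j] - members$discharge_time[i]) / DAY_S
    (by_type[[p]][j] %in% spec$unplanned_types) && gap_days <= spec$window_days
  }, logical(1))
}

#' Assign the unplanned 30-day readmission label
#'
#' `TRUE` iff the first admission after the index discharge is of an
#' unplanned type and its admit time lies within `window_days` of the index
#' discharge (boundary inclusive). Reads nothing from the index admission
#' except its discharge time, and nothing beyond the next admission's admit
#' record.
#'
#' @param member a single-row cohort member (from [select_cohort()]).
#' @param tables an `ehr_tables` object.
#' @param spec a [cohort_spec()].
#' @return Logical scalar.
#' @export
assign_label <- function(member, tables, spec = cohort_spec()) {
  assign_label_vec(member, tables, spec)[1L]
}

#' Split a cohort into train, validation and test sets
#'
#' Random partition with largest-remainder rounding, so the three sizes
#' always sum to the cohort size; deterministic given `seed`.
#'
#' @param members a `hf_cohort` data frame.
#' @param ratios length-3 positive vector summing to 1 (default the study's
#'   73.1/12.9/14.0 split).
#' @param seed RNG seed.
#' @return Named list `train`, `validation`, `test` of cohort data frames.
#' @export
split_cohort <- function(members, ratios = c(0.731, 0.129, 0.140), seed = 1) {
  if (abs(sum(ratios) - 1) > 1e-9) stop_config("ratios must sum to 1")
  n <- nrow(members)
  if (n < 3L) stop_config("need at least 3 members to split (got %d)", n)
  sizes <- largest_remainder(n, ratios)
  idx <- with_seed(seed, sample.int(n))
  cut <- cumsum(sizes)
  parts <- list(train = idx[seq_len(cut[1L])],
                validation = idx[(cut[1L] + 1L):cut[2L]],
                test = idx[(cut[2L] + 1L):cut[3L]])
  lapply(parts, function(i) {
    m <- members[sort(i), , drop = FALSE]
    class(m) <- c("hf_cohort", "data.frame")
    m
  })
}

largest_remainder <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' @export
print.hf_cohort <- function(x, ...) {
  cat(sprintf("<hf_cohort> %d members, %d (%.1f%%) readmitted unplanned\n",
              nrow(x), sum(x$label),
              if (nrow(x)) 100 * mean(x$label) else 0))
  invisible(x)
}
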