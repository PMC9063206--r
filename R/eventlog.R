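# EHR -> event-log conversion: the 13 event types with their millisecond
# timestamp rules. For every admission of every cohort member (all prior
# admissions plus the index admission):
#
#   1. admission-type event at the admit time
#   2. insurance event 1 ms later
#   3. per lab analyte: a Mean event at the first measurement time and a
#      Std event 1 ms later (single measurement) or at the last
#      measurement time (repeated measurements)
#   4. one event per Elixhauser group scored for the admission, placed
#      just before discharge with successive +1 ms offsets
#   5. one artificial event from the admission's procedure/CPT code
#      sequence, 1 ms after the first code observation, clipped to 0.5 ms
#      before discharge
#   6. a discharge event at the discharge time
#
# The TSS-collection marker sits on the index admission's discharge event;
# nothing after it contributes to features.

EV_PRIO <- c(admission = 0L, insurance = 1L, lab_mean = 2L, lab_std = 3L,
             artificial = 4L, comorbidity = 5L, discharge = 6L)

#' Convert cohort EHR histories into an event log
#'
#' @param tables an `ehr_tables` object.
#' @param cohort a `hf_cohort` data frame (any subset of members).
#' @param art_model an `artificial_event_model` fitted on the training
#'   cohort via [fit_artificial_events()], or `NULL` to omit artificial
#'   events.
#' @return A `hf_event_log`: list with `events` (data frame `case_id`,
#'   `name`, `timestamp`, ordered by case and time, strictly increasing
#'   within a case) and `cases` (data frame `case_id`, `label`,
#'   `tss_index`, where `tss_index` is the position of the index
#'   admission's discharge event within the case).
#' @export
build_event_log <- function(tables, cohort, art_model = NULL) {
  if (nrow(cohort) == 0L) stop_config("empty cohort")
  cohort <- cohort[order(cohort$patient_id), , drop = FALSE]
  adm <- tables$admissions
  hadm <- unlist(lapply(seq_len(nrow(cohort)), function(i)
    c(cohort$prior_admission_ids[[i]], cohort$index_admission_id[i])))
  case_of <- rep(cohort$patient_id,
                 vapply(cohort$prior_admission_ids, length, integer(1)) + 1L)
  ai <- match(hadm, adm$HADM_ID)
  if (anyNA(ai)) stop_format("cohort references unknown admission id")
  A <- data.frame(case_id = case_of, hadm = hadm,
                  admit = adm$ADMITTIME[ai], disch = adm$DISCHTIME[ai],
                  type = adm$ADMISSION_TYPE[ai], ins = adm$INSURANCE[ai],
                  stringsAsFactors = FALSE)

  ev <- list(
    data.frame(case_id = A$case_id, hadm = A$hadm,
               name = paste0("Admission_", A$type),
               timestamp = A$admit, prio = EV_PRIO[["admission"]]),
    data.frame(case_id = A$case_id, hadm = A$hadm,
               name = paste0("Insurance_", A$ins),
               timestamp = ms_round(A$admit + MS), prio = EV_PRIO[["insurance"]]),
    data.frame(case_id = A$case_id, hadm = A$hadm, name = "Discharge",
               timestamp = A$disch, prio = EV_PRIO[["discharge"]]))

  ev <- c(ev, lab_events(tables, A), comorbidity_events(tables, A))
  if (!is.null(art_model)) ev <- c(ev, artificial_events(tables, A, art_model))
  events <- do.call(rbind, ev)
  events <- events[order(events$case_id, events$timestamp, events$prio), ]
  events$timestamp <- enforce_strict_order(events$case_id, events$timestamp)
  rownames(events) <- NULL

  n_by_case <- table(factor(events$case_id, levels = cohort$patient_id))
  cases <- data.frame(case_id = cohort$patient_id,
                      label = cohort$label,
                      tss_index = as.integer(n_by_case))
  last_idx <- cumsum(cases$tss_index)
  if (!all(events$name[last_idx] == "Discharge"))
    stop_invariant("TSS marker does not sit on a discharge event")
  structure(list(events = events[, c("case_id", "name", "timestamp")],
                 cases = cases),
            class = "hf_event_log")
}

lab_events <- function(tables, A) {
  le <- tables$labevents
  le <- le[le$HADM_ID %in% A$hadm & !is.na(le$VALUENUM), ]
  if (nrow(le) == 0L) return(list())
  le$label <- tables$d_labitems$LABEL[match(le$ITEMID, tables$d_labitems$ITEMID)]
  key <- paste(le$HADM_ID, le$label)
  first <- tapply(le$CHARTTIME, key, min)
  last <- tapply(le$CHARTTIME, key, max)
  cnt <- tapply(le$CHARTTIME, key, length)
  ks <- strsplit(names(first), " ", fixed = TRUE)
  hadm_k <- as.numeric(vapply(ks, `[`, "", 1L))
  lab_k <- vapply(ks, `[`, "", 2L)
  i <- match(hadm_k, A$hadm)
  mean_t <- as.numeric(first)
  std_t <- ifelse(cnt == 1L, ms_round(mean_t + MS), as.numeric(last))
  std_t <- ifelse(std_t <= mean_t, ms_round(mean_t + MS), std_t)
  list(
    data.frame(case_id = A$case_id[i], hadm = hadm_k,
               name = paste0(lab_k, "_mean"), timestamp = mean_t,
               prio = EV_PRIO[["lab_mean"]]),
    data.frame(case_id = A$case_id[i], hadm = hadm_k,
               name = paste0(lab_k, "_std"), timestamp = std_t,
               prio = EV_PRIO[["lab_std"]]))
}

comorbidity_events <- function(tables, A) {
  d <- tables$diagnoses_icd
  d <- d[d$HADM_ID %in% A$hadm, ]
  if (nrow(d) == 0L) return(list())
  groups <- elixhauser_group_names()
  # memoized unique-code -> group expansion keeps this linear in the log
  uc <- unique(normalize_icd9(d$ICD9_CODE))
  g_of <- lapply(uc, function(cc) match(elixhauser_groups(cc), groups))
  names(g_of) <- uc
  gl <- g_of[normalize_icd9(d$ICD9_CODE)]
  reps <- lengths(gl)
  pairs <- unique(data.frame(hadm = rep(d$HADM_ID, reps), g = unlist(gl)))
  if (nrow(pairs) == 0L) return(list())
  pairs <- pairs[order(pairs$hadm, pairs$g), ]
  m <- stats::ave(pairs$g, pairs$hadm, FUN = length)
  i_in_adm <- stats::ave(pairs$g, pairs$hadm, FUN = seq_along)
  ai <- match(pairs$hadm, A$hadm)
  list(data.frame(
    case_id = A$case_id[ai], hadm = pairs$hadm,
    name = paste0("Elix_", groups[pairs$g]),
    timestamp = ms_round(A$disch[ai] - (m - i_in_adm + 1) * MS),
    prio = EV_PRIO[["comorbidity"]]))
}

artificial_events <- function(tables, A, art_model) {
  seqs <- admission_code_seqs(tables, A$hadm)
  cl <- predict_artificial_clusters(art_model, seqs)
  keep <- !is.na(cl)
  if (!any(keep)) return(list())
  # anchor: procedures are observed at admission; otherwise the first CPT
  # chart time
  cp <- tables$cptevents
  cp <- cp[cp$HADM_ID %in% A$hadm, ]
  first_cpt <- tapply(cp$CHARTTIME, cp$HADM_ID, min)
  pr_hadm <- unique(tables$procedures_icd$HADM_ID)
  anchor <- ifelse(A$hadm %in% pr_hadm, A$admit,
                   as.numeric(first_cpt[as.character(A$hadm)]))
  # clipped to 1 ms before discharge; ties with comorbidity events resolve
  # deterministically through the priority-ordered bump pass
  t <- ms_round(pmin(anchor + MS, A$disch - MS))
  list(data.frame(
    case_id = A$case_id[keep], hadm = A$hadm[keep],
    name = paste0("Artificial_", cl[keep]),
    timestamp = t[keep], prio = EV_PRIO[["artificial"]]))
}

# single forward pass bumping equal/decreasing timestamps by 1 ms within a
# case; input must already be sorted by (case, timestamp, priority)
enforce_strict_order <- function(case_id, ts) {
  n <- length(ts)
  if (n < 2L) return(ts)
  for (i in 2:n) {
    if (case_id[i] == case_id[i - 1L] && ts[i] <= ts[i - 1L])
      ts[i] <- ms_round(ts[i - 1L] + MS)
  }
  ts
}

#' @export
print.hf_event_log <- function(x, ...) {
  cat(sprintf("<hf_event_log> %d cases, %d events, %d event names\n",
              nrow(x$cases), nrow(x$events), length(unique(x$events$name))))
  invisible(x)
}

# per-case views used by replay: list of (names, timestamps, tss_index, label)
log_traces <- function(log) {
  ev_by <- split(seq_len(nrow(log$events)), log$events$case_id)
  lapply(seq_len(nrow(log$cases)), function(i) {
    idx <- ev_by[[as.character(log$cases$case_id[i])]]
    list(case_id = log$cases$case_id[i],
         names = log$events$name[idx],
         timestamps = log$events$timestamp[idx],
         tss_index = log$cases$tss_index[i],
         label = log$cases$label[i])
  })
}
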