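# Hand-built micro EHR fixtures for exercising the conversion rules, and
# shared cached objects for the heavier property tests.

DAY <- 86400
T0 <- as.numeric(as.POSIXct("2101-06-01 00:00:00", tz = "UTC"))

# a minimal ehr_tables object built column by column. Admissions are given
# as a list of lists: list(hadm, admit, disch, type, ins, pid)
tiny_tables <- function(admissions, patients, labevents = NULL,
                        diagnoses = NULL, procedures = NULL, cpt = NULL) {
  adf <- do.call(rbind, lapply(admissions, function(a)
    data.frame(SUBJECT_ID = a$pid, HADM_ID = a$hadm, ADMITTIME = a$admit,
               DISCHTIME = a$disch,
               ADMISSION_TYPE = a$type %||% "EMERGENCY",
               INSURANCE = a$ins %||% "Medicare")))
  pdf <- do.call(rbind, lapply(patients, function(p)
    data.frame(SUBJECT_ID = p$pid, GENDER = p$gender %||% "F",
               DOB = p$dob %||% (T0 - 70 * 365.25 * DAY),
               ETHNICITY = p$eth %||% "White",
               EXPIRE_FLAG = p$dead %||% 0L)))
  le <- if (is.null(labevents))
    data.frame(HADM_ID = numeric(0), ITEMID = integer(0),
               CHARTTIME = numeric(0), VALUENUM = numeric(0))
  else labevents
  dg <- if (is.null(diagnoses))
    data.frame(HADM_ID = numeric(0), SEQ_NUM = integer(0),
               ICD9_CODE = character(0))
  else diagnoses
  pr <- if (is.null(procedures))
    data.frame(HADM_ID = numeric(0), SEQ_NUM = integer(0),
               ICD9_CODE = character(0))
  else procedures
  cp <- if (is.null(cpt))
    data.frame(HADM_ID = numeric(0), CHARTTIME = numeric(0),
               CPT_CD = character(0))
  else cpt
  structure(list(
    patients = pdf, admissions = adf, labevents = le,
    d_labitems = data.frame(ITEMID = 50001:50004,
                            LABEL = c("BUN", "SerumCreatinine", "Sodium",
                                      "NTproBNP")),
    diagnoses_icd = dg, procedures_icd = pr, cptevents = cp),
    class = "ehr_tables")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three-admission patient (prior, index with HF code, future) usable as a
# one-member cohort
tiny_member_tables <- function(future_gap_days = 10,
                               future_type = "EMERGENCY",
                               index_codes = c("4280"),
                               prior_codes = character(0),
                               labevents = NULL, procedures = NULL,
                               cpt = NULL) {
  admit1 <- T0; disch1 <- T0 + 5 * DAY
  admit2 <- T0 + 40 * DAY; disch2 <- T0 + 47 * DAY
  admit3 <- disch2 + future_gap_days * DAY
  tabs <- tiny_tables(
    admissions = list(
      list(pid = 1, hadm = 101, admit = admit1, disch = disch1,
           type = "ELECTIVE", ins = "Private"),
      list(pid = 1, hadm = 102, admit = admit2, disch = disch2,
           type = "EMERGENCY", ins = "Medicare"),
      list(pid = 1, hadm = 103, admit = admit3, disch = admit3 + 2 * DAY,
           type = future_type)),
    patients = list(list(pid = 1)),
    labevents = labevents,
    diagnoses = {
      rows <- data.frame(HADM_ID = numeric(0), SEQ_NUM = integer(0),
                         ICD9_CODE = character(0))
      if (length(prior_codes))
        rows <- rbind(rows, data.frame(HADM_ID = 101,
                                       SEQ_NUM = seq_along(prior_codes),
                                       ICD9_CODE = prior_codes))
      if (length(index_codes))
        rows <- rbind(rows, data.frame(HADM_ID = 102,
                                       SEQ_NUM = seq_along(index_codes),
                                       ICD9_CODE = index_codes))
      rows
    },
    procedures = procedures, cpt = cpt)
  tabs
}

# cached expensive shared objects ---------------------------------------
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small end-to-end pipeline shared by several test files
small_pipeline <- function() {
  cached("small_pipeline", {
    cfg <- synthetic_config(n_patients = 250, seed = 42, signal_strength = 2)
    tab <- generate_ehr(cfg)
    split <- split_cohort(select_cohort(tab), seed = 42)
    art <- suppressWarnings(fit_artificial_events(tab, split$train, seed = 1))
    log <- build_event_log(tab, split$train, art)
    net <- discover_petri_net(log)
    alphas <- estimate_decay_rates(net, log)
    list(tables = tab, split = split, art = art, log = log, net = net,
         alphas = alphas)
  })
}
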