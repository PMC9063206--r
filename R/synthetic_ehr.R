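# Synthetic MIMIC-III-shaped EHR generator with a latent readmission
# mechanism. Every downstream stage (cohort, event log, discovery, decay
# replay, models) is exercised on these tables; column names follow the
# MIMIC-III source tables.

#' Default HF lab panel and comorbidity prevalences
#'
#' The four HF-relevant analytes (BUN, serum creatinine, sodium,
#' NT-proBNP) with their cohort means/sds and per-analyte severity shift,
#' and the default prevalence of each Elixhauser group in the simulated
#' population.
#'
#' @return `default_lab_panel()`: a data frame;
#'   `default_comorbidity_prevalences()`: a named probability vector.
#' @export
default_lab_panel <- function() {
  data.frame(
    label = c("BUN", "SerumCreatinine", "Sodium", "NTproBNP"),
    item_id = 50001:50004,
    mean = c(34.4, 0.002, 138.6, 0.187),
    sd = c(24.0, 0.0496, 4.58, 0.380),
    # lab-mean shift per sd of latent severity, in units of the single-
    # measurement sd (sodium carries no severity signal). Pooling over the
    # ~10 repeated measurements of a patient history divides the noise sd
    # by ~sqrt(10), so 0.1 keeps the lab family informative but the least
    # important one, matching the intended importance ordering
    severity_shift = c(0.1, 0.1, 0, 0.1),
    stringsAsFactors = FALSE)
}

#' @rdname default_lab_panel
#' @export
default_comorbidity_prevalences <- function() {
  p <- c(
    CongestiveHeartFailure = 0.85, CardiacArrhythmias = 0.35,
    ValvularDisease = 0.15, PulmonaryCirculation = 0.08,
    PeripheralVascular = 0.12, HypertensionUncomplicated = 0.35,
    HypertensionComplicated = 0.15, Paralysis = 0.03,
    OtherNeurological = 0.08, ChronicPulmonary = 0.25,
    DiabetesUncomplicated = 0.25, DiabetesComplicated = 0.12,
    Hypothyroidism = 0.12, RenalFailure = 0.25, LiverDisease = 0.05,
    PepticUlcer = 0.03, AIDSHIV = 0.01, Lymphoma = 0.02,
    MetastaticCancer = 0.03, SolidTumor = 0.05, RheumatoidArthritis = 0.03,
    Coagulopathy = 0.08, Obesity = 0.10, WeightLoss = 0.05,
    FluidElectrolyte = 0.30, BloodLossAnemia = 0.02,
    DeficiencyAnemia = 0.15, AlcoholAbuse = 0.05, DrugAbuse = 0.04,
    Psychoses = 0.04, Depression = 0.10)
  p
}

hf_code_pool <- function() {
  c("4280", "4281", "42820", "42822", "42830", "42832", "42840",
    "39891", "40291", "40491")
}

#' Configuration for the synthetic EHR generator
#'
#' Defines the study conditions the generator emulates: cohort size, the
#' latent-severity readmission mechanism, lab panel, comorbidity
#' prevalences and code vocabularies.
#'
#' @param n_patients number of patients (>= 10).
#' @param seed integer RNG seed; identical configs produce byte-identical
#'   tables.
#' @param signal_strength log-odds weight linking standardized latent
#'   severity to unplanned 30-day readmission (>= 0; 0 = pure noise).
#' @param readmit_base_rate marginal unplanned 30-day readmission
#'   probability at zero signal, in (0,1).
#' @param mean_admissions_per_patient mean admissions per eligible patient
#'   (>= 2; eligible patients always receive at least 3 so that a prior, an
#'   index and a future admission exist).
#' @param lab_panel data frame with columns `label`, `item_id`, `mean`,
#'   `sd`, `severity_shift` for the four HF-relevant analytes.
#' @param comorbidity_prevalences named probability vector over the 31
#'   Elixhauser groups.
#' @param code_vocab_sizes named integer vector with entries `diagnosis`
#'   (extra unmapped noise codes; 0 disables), `procedure`, `cpt`.
#' @param eligible_fraction fraction of patients guaranteed the structural
#'   inclusion criteria (>= 1 prior admission, >= 1 future admission, an HF
#'   ICD-9 code in the index admission).
#' @param death_rate fraction of patients flagged deceased (exercises the
#'   exclusion rule).
#' @param prevalence_shift additive comorbidity-prevalence shift per sd of
#'   latent severity (clipped to probabilities).
#' @param acuity_intercept,acuity_slope log-odds intercept/slope of the
#'   probability that a non-outcome admission is emergency/urgent.
#' @param age_mean,age_sd,age_shift age distribution (years) and its latent
#'   shift in sd units.
#' @param calendar_start ISO date anchoring the synthetic calendar.
#' @return A `synthetic_config` object (validated list).
#' @export
synthetic_config <- function(n_patients = 1000,
                             seed = 1,
                             signal_strength = 2,
                             readmit_base_rate = 0.235,
                             mean_admissions_per_patient = 3.5,
                             lab_panel = default_lab_panel(),
                             comorbidity_prevalences = default_comorbidity_prevalences(),
                             code_vocab_sizes = c(diagnosis = 0, procedure = 30, cpt = 40),
                             eligible_fraction = 0.9,
                             death_rate = 0.10,
                             prevalence_shift = 0.15,
                             acuity_intercept = 0.4,
                             acuity_slope = 0.8,
                             age_mean = 69.9,
                             age_sd = 14.3,
                             age_shift = 0.2,
                             calendar_start = "2100-01-01") {
  cfg <- as.list(environment())
  if (!is.numeric(n_patients) || n_patients < 10)
    stop_config("n_patients must be >= 10 (got %s)", format(n_patients))
  if (!(readmit_base_rate > 0 && readmit_base_rate < 1))
    stop_config("readmit_base_rate must be in (0,1)")
  if (signal_strength < 0) stop_config("signal_strength must be >= 0")
  if (mean_admissions_per_patient < 2)
    stop_config("mean_admissions_per_patient must be >= 2")
  if (any(comorbidity_prevalences < 0 | comorbidity_prevalences > 1))
    stop_config("comorbidity prevalences must lie in [0,1]")
  missing_g <- setdiff(elixhauser_group_names(), names(comorbidity_prevalences))
  if (length(missing_g))
    stop_config("comorbidity_prevalences lacks groups: %s",
                paste(missing_g, collapse = ", "))
  if (!(eligible_fraction >= 0 && eligible_fraction <= 1))
    stop_config("eligible_fraction must be in [0,1]")
  structure(cfg, class = "synthetic_config")
}

# representative ICD-9 code per Elixhauser group (first prefix of the Quan
# list, zero-padded to a concrete code)
elix_representative_codes <- function() {
  m <- elix_map()
  first <- m[!duplicated(m$group), ]
  code <- first$icd9_prefix
  pad <- !startsWith(code, "V") & nchar(code) == 3
  code[pad] <- paste0(code[pad], "0")
  stats::setNames(code, first$group)
}

#' Generate synthetic EHR tables
#'
#' Draws a standard-normal latent severity per patient; severity shifts
#' comorbidity prevalences, HF lab means and admission acuity, and sets the
#' probability that the admission following the index discharge is an
#' unplanned admission within 30 days to
#' `plogis(qlogis(readmit_base_rate) + signal_strength * severity)`.
#'
#' @param config a [synthetic_config()] object.
#' @return An `ehr_tables` object: list of data frames `patients`,
#'   `admissions`, `labevents`, `d_labitems`, `diagnoses_icd`,
#'   `procedures_icd`, `cptevents` with MIMIC-III column names; timestamps
#'   are numeric seconds since epoch (UTC). The latent truth (severity,
#'   readmission indicator) is attached as attribute `"latent"` for
#'   verification purposes and is never written by [write_ehr_tables()].
#' @export
generate_ehr <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_config("config must be created by synthetic_config()")
  with_seed(config$seed, generate_ehr_impl(config))
}

generate_ehr_impl <- function(cfg) {
  n <- as.integer(cfg$n_patients)
  pid <- 10000L + seq_len(n)
  z <- stats::rnorm(n)
  death <- stats::runif(n) < cfg$death_rate
  elig <- stats::runif(n) < cfg$eligible_fraction
  viol <- rep("none", n)
  viol[!elig] <- sample(c("no_prior", "no_future", "no_hf"),
                        sum(!elig), replace = TRUE)

  lam <- max(0, cfg$mean_admissions_per_patient - 3)
  n_adm <- 3L + stats::rpois(n, lam)
  n_adm <- pmin(n_adm, 12L)
  n_adm[viol == "no_prior"] <- 2L
  n_adm[viol == "no_future"] <- 2L + stats::rpois(sum(viol == "no_future"), lam)
  n_adm <- pmin(n_adm, 12L)
  has_future <- viol %in% c("none", "no_prior", "no_hf")
  index_pos <- ifelse(has_future, n_adm - 1L, n_adm)

  p_readmit <- stats::plogis(stats::qlogis(cfg$readmit_base_rate) +
                               cfg$signal_strength * z)
  readmit <- stats::rbinom(n, 1L, p_readmit) == 1L

  insurance_p <- c(Medicare = 0.55, Medicaid = 0.08, Private = 0.30,
                   Government = 0.04, `Self-pay` = 0.03)
  insurance <- sample(names(insurance_p), n, replace = TRUE, prob = insurance_p)
  eth_p <- c(`African American` = 0.12, Hispanic = 0.031,
             `Others non-Hispanic` = 0.07, White = 0.758, Asian = 0.021)
  ethnicity <- sample(names(eth_p), n, replace = TRUE, prob = eth_p / sum(eth_p))
  gender <- ifelse(stats::runif(n) < 0.476, "F", "M")
  age <- cfg$age_mean + cfg$age_sd *
    (cfg$age_shift * z + sqrt(1 - cfg$age_shift^2) * stats::rnorm(n))
  age <- pmin(pmax(age, 30), 95)
  hf_code <- sample(hf_code_pool(), n, replace = TRUE)
  start0 <- iso_to_num(paste0(cfg$calendar_start, "T00:00:00"))
  start <- start0 + round(stats::runif(n, 0, 3000) * DAY_S)

  # ---- admission-level frame ------------------------------------------
  N <- sum(n_adm)
  a_pid <- rep(pid, n_adm)
  a_row <- rep(seq_len(n), n_adm)
  a_pos <- sequence(n_adm)
  a_index <- a_pos == index_pos[a_row]
  a_outcome <- has_future[a_row] & a_pos == index_pos[a_row] + 1L

  los <- stats::runif(N, 2, 15)                       # days
  # gap (days) between previous discharge and this admission
  gap <- numeric(N)
  pre <- a_pos > 1L & !a_outcome
  short <- stats::runif(N) < 0.3
  gap[pre] <- ifelse(short[pre], stats::runif(sum(pre), 2, 25),
                     stats::runif(sum(pre), 35, 300))
  oc <- which(a_outcome)
  oc_re <- readmit[a_row[oc]]
  u <- stats::runif(length(oc))
  late_unplanned <- !oc_re & u < 0.5
  gap[oc[oc_re]] <- stats::runif(sum(oc_re), 0.5, 30)
  gap[oc[late_unplanned]] <- stats::runif(sum(late_unplanned), 30.5, 300)
  gap[oc[!oc_re & !late_unplanned]] <-
    stats::runif(sum(!oc_re & !late_unplanned), 1, 300)

  step <- gap * DAY_S
  prev_los <- c(0, los[-N] * DAY_S)
  prev_los[a_pos == 1L] <- 0
  step[a_pos == 1L] <- 0
  admit <- start[a_row] + round(ave(step + prev_los, a_pid, FUN = cumsum))
  discharge <- admit + round(los * DAY_S)

  a_type <- character(N)
  emer <- stats::runif(N) <
    stats::plogis(cfg$acuity_intercept + cfg$acuity_slope * z[a_row])
  a_type[!emer] <- "ELECTIVE"
  a_type[emer] <- sample(c("EMERGENCY", "URGENT"), sum(emer),
                         replace = TRUE, prob = c(0.8, 0.2))
  # the outcome admission's type comes from the label mechanism
  a_type[oc[oc_re | late_unplanned]] <-
    sample(c("EMERGENCY", "URGENT"), sum(oc_re | late_unplanned),
           replace = TRUE, prob = c(0.8, 0.2))
  a_type[oc[!oc_re & !late_unplanned]] <- "ELECTIVE"

  hadm <- a_pid * 100L + a_pos
  admissions <- data.frame(
    SUBJECT_ID = a_pid, HADM_ID = hadm,
    ADMITTIME = admit, DISCHTIME = discharge,
    ADMISSION_TYPE = a_type, INSURANCE = insurance[a_row],
    stringsAsFactors = FALSE)

  # ---- patients --------------------------------------------------------
  idx_admit <- admit[a_index][order(a_row[a_index])]
  dob <- round(idx_admit - age * 365.25 * DAY_S)
  patients <- data.frame(
    SUBJECT_ID = pid, GENDER = gender, DOB = dob,
    ETHNICITY = ethnicity, EXPIRE_FLAG = as.integer(death),
    stringsAsFactors = FALSE)

  # ---- labevents -------------------------------------------------------
  panel <- cfg$lab_panel
  K <- nrow(panel)
  g_adm <- rep(seq_len(N), each = K)
  g_item <- rep(seq_len(K), times = N)
  nm <- ifelse(stats::runif(N * K) < 0.1, 0L, sample(1:4, N * K, replace = TRUE))
  le_adm <- rep(g_adm, nm)
  le_item <- rep(g_item, nm)
  n_le <- length(le_adm)
  los_s <- (discharge - admit)[le_adm]
  ct <- admit[le_adm] + round(3600 + stats::runif(n_le) * (los_s - 7200))
  o <- order(le_adm, le_item, ct)
  le_adm <- le_adm[o]; le_item <- le_item[o]; ct <- ct[o]
  # strictly increasing within (admission, item)
  grp <- paste(le_adm, le_item)
  ct <- ct + (stats::ave(seq_len(n_le), grp, FUN = seq_along) - 1L)
  val <- stats::rnorm(n_le,
    mean = panel$mean[le_item] +
      panel$severity_shift[le_item] * panel$sd[le_item] * z[a_row[le_adm]],
    sd = panel$sd[le_item])
  labevents <- data.frame(
    HADM_ID = hadm[le_adm], ITEMID = panel$item_id[le_item],
    CHARTTIME = ct, VALUENUM = val, stringsAsFactors = FALSE)

  d_labitems <- data.frame(ITEMID = panel$item_id, LABEL = panel$label,
                           stringsAsFactors = FALSE)

  # ---- diagnoses -------------------------------------------------------
  groups <- elixhauser_group_names()
  prev <- cfg$comorbidity_prevalences[groups]
  G <- length(groups)
  pmat <- pmin(0.98, pmax(0, outer(z * cfg$prevalence_shift, rep(1, G)) +
                               matrix(prev, n, G, byrow = TRUE)))
  pmat[prev == 0] <- 0          # zero prevalence means the group never occurs
  chronic <- matrix(stats::rbinom(n * G, 1L, pmat), n, G) == 1L
  chronic[viol == "no_hf", which(groups == "CongestiveHeartFailure")] <- FALSE
  adm_mask <- matrix(stats::runif(N * G) < 0.8, N, G) & chronic[a_row, , drop = FALSE]
  rep_codes <- elix_representative_codes()[groups]
  di <- which(adm_mask, arr.ind = TRUE)
  di <- di[order(di[, 1L], di[, 2L]), , drop = FALSE]
  diag_adm <- di[, 1L]
  diag_code <- rep_codes[di[, 2L]]

  inject <- viol %in% c("none", "no_prior", "no_future")
  inj_adm <- which(a_index & inject[a_row])
  d_adm <- c(inj_adm, diag_adm)
  d_code <- c(hf_code[a_row[inj_adm]], diag_code)
  o <- order(d_adm, c(rep(0L, length(inj_adm)), di[, 2L]))
  d_adm <- d_adm[o]; d_code <- d_code[o]
  if (cfg$code_vocab_sizes[["diagnosis"]] > 0) {
    pool <- paste0("V7", sprintf("%03d", seq_len(cfg$code_vocab_sizes[["diagnosis"]])))
    n_noise <- stats::rpois(N, 0.5)
    nz_adm <- rep(seq_len(N), n_noise)
    d_adm <- c(d_adm, nz_adm)
    d_code <- c(d_code, sample(pool, length(nz_adm), replace = TRUE))
    o <- order(d_adm)
    d_adm <- d_adm[o]; d_code <- d_code[o]
  }
  diagnoses_icd <- data.frame(
    HADM_ID = hadm[d_adm],
    SEQ_NUM = stats::ave(seq_along(d_adm), d_adm, FUN = seq_along),
    ICD9_CODE = unname(d_code), stringsAsFactors = FALSE)

  # ---- procedures and CPT ---------------------------------------------
  proc_pool <- sprintf("%04d", 3500 + seq_len(cfg$code_vocab_sizes[["procedure"]]))
  n_proc <- stats::rpois(N, 1.5)
  pr_adm <- rep(seq_len(N), n_proc)
  procedures_icd <- data.frame(
    HADM_ID = hadm[pr_adm],
    SEQ_NUM = stats::ave(seq_along(pr_adm), pr_adm, FUN = seq_along),
    ICD9_CODE = sample(proc_pool, length(pr_adm), replace = TRUE),
    stringsAsFactors = FALSE)

  cpt_pool <- sprintf("9%04d", 2000 + seq_len(cfg$code_vocab_sizes[["cpt"]]))
  n_cpt <- stats::rpois(N, 2)
  cp_adm <- rep(seq_len(N), n_cpt)
  cp_ct <- admit[cp_adm] +
    round(1800 + stats::runif(length(cp_adm)) * ((discharge - admit)[cp_adm] - 3600))
  o <- order(cp_adm, cp_ct)
  cp_adm <- cp_adm[o]; cp_ct <- cp_ct[o]
  cp_ct <- cp_ct + (stats::ave(seq_along(cp_adm), cp_adm, FUN = seq_along) - 1L)
  cptevents <- data.frame(
    HADM_ID = hadm[cp_adm], CHARTTIME = cp_ct,
    CPT_CD = sample(cpt_pool, length(cp_adm), replace = TRUE),
    stringsAsFactors = FALSE)

  tables <- structure(
    list(patients = patients, admissions = admissions, labevents = labevents,
         d_labitems = d_labitems, diagnoses_icd = diagnoses_icd,
         procedures_icd = procedures_icd, cptevents = cptevents),
    class = "ehr_tables")
  attr(tables, "latent") <- data.frame(
    SUBJECT_ID = pid, severity = z, readmit = readmit & has_future,
    eligible = elig, death = death)
  validate_ehr_tables(tables)
  tables
}

#' Validate EHR table invariants
#'
#' Checks discharge after admit, non-overlapping admissions per patient,
#' lab chart times inside their admission interval, and resolvable foreign
#' keys. Errors name the offending table and row.
#'
#' @param tables an `ehr_tables` object.
#' @return `tables`, invisibly.
#' @export
validate_ehr_tables <- function(tables) {
  adm <- tables$admissions
  bad <- which(adm$DISCHTIME <= adm$ADMITTIME)
  if (length(bad))
    stop_invariant("admissions row %d: discharge_time <= admit_time", bad[1L])
  o <- order(adm$SUBJECT_ID, adm$ADMITTIME)
  s <- adm[o, ]
  same <- s$SUBJECT_ID[-1L] == s$SUBJECT_ID[-nrow(s)]
  ovl <- which(same & s$ADMITTIME[-1L] < s$DISCHTIME[-nrow(s)])
  if (length(ovl))
    stop_invariant("overlapping admissions for patient %s", s$SUBJECT_ID[ovl[1L] + 1L])
  for (tb in c("labevents", "diagnoses_icd", "procedures_icd", "cptevents")) {
    dangling <- !(tables[[tb]]$HADM_ID %in% adm$HADM_ID)
    if (any(dangling))
      stop_format("%s row %d: dangling HADM_ID %s", tb, which(dangling)[1L],
                  tables[[tb]]$HADM_ID[which(dangling)[1L]])
  }
  if (any(!(tables$labevents$ITEMID %in% tables$d_labitems$ITEMID)))
    stop_format("labevents: ITEMID missing from d_labitems")
  if (nrow(tables$labevents)) {
    i <- match(tables$labevents$HADM_ID, adm$HADM_ID)
    out <- which(tables$labevents$CHARTTIME < adm$ADMITTIME[i] |
                 tables$labevents$CHARTTIME > adm$DISCHTIME[i])
    if (length(out))
      stop_invariant("labevents row %d: charttime outside admission", out[1L])
  }
  invisible(tables)
}
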