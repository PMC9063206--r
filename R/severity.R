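# Charlson and Elixhauser comorbidity scoring from ICD-9-CM diagnosis codes,
# using the Quan et al. (2005) coding maps shipped as package data.

elix_map <- function() {
  if (is.null(.dhf$elix_map)) {
    f <- system.file("extdata", "elixhauser_quan_icd9.csv", package = "dreamHF")
    m <- utils::read.csv(f, colClasses = c("integer", "character", "character"))
    .dhf$elix_map <- m
  }
  .dhf$elix_map
}

charlson_map <- function() {
  if (is.null(.dhf$charlson_map)) {
    f <- system.file("extdata", "charlson_quan_icd9.csv", package = "dreamHF")
    .dhf$charlson_map <- utils::read.csv(
      f, colClasses = c("character", "integer", "character"))
  }
  .dhf$charlson_map
}

#' Canonical Elixhauser group names
#'
#' The 31 Elixhauser comorbidity groups in canonical order (the order used
#' for comorbidity event placement and feature columns).
#'
#' @return Character vector of length 31.
#' @export
elixhauser_group_names <- function() {
  m <- elix_map()
  m$group[!duplicated(m$group)]
}

#' Normalize ICD-9 codes
#'
#' Upper-cases and strips the decimal point, e.g. `"428.0"` becomes
#' `"4280"`. All scoring functions match on normalized codes.
#'
#' @param codes character vector of ICD-9-CM codes.
#' @return Normalized character vector.
#' @export
normalize_icd9 <- function(codes) {
  gsub(".", "", toupper(trimws(as.character(codes))), fixed = TRUE)
}

# map a vector of normalized codes to the set of groups/categories whose
# prefix lists they hit; memoized on unique codes for speed
match_prefix_groups <- function(codes, map, group_col) {
  codes <- unique(codes[!is.na(codes) & nzchar(codes)])
  if (length(codes) == 0L) return(character(0))
  groups <- unique(map[[group_col]])
  hit <- vapply(groups, function(g) {
    prefs <- map$icd9_prefix[map[[group_col]] == g]
    any(vapply(prefs, function(p) any(startsWith(codes, p)), logical(1)))
  }, logical(1))
  groups[hit]
}

#' Elixhauser comorbidity groups present in a code list
#'
#' Returns every Elixhauser group (Quan ICD-9 mapping) whose code set
#' intersects the input. Matching is prefix-based on normalized codes, so
#' `"4280"` and `"42822"` both hit the congestive heart failure group.
#' Duplicated codes are idempotent; unrecognized codes are ignored.
#'
#' @param icd9_codes character vector of ICD-9 diagnosis codes (dotted or
#'   normalized).
#' @return Character vector of group names (subset of
#'   [elixhauser_group_names()]), in canonical order.
#' @examples
#' elixhauser_groups(c("428.0", "250.42", "V45.81"))
#' @export
elixhauser_groups <- function(icd9_codes) {
  codes <- normalize_icd9(icd9_codes)
  g <- match_prefix_groups(codes, elix_map(), "group")
  intersect(elixhauser_group_names(), g)
}

# van Walraven (2009) weights, keyed by canonical group name
vw_weights <- c(
  CongestiveHeartFailure = 7, CardiacArrhythmias = 5, ValvularDisease = -1,
  PulmonaryCirculation = 4, PeripheralVascular = 2,
  HypertensionUncomplicated = 0, HypertensionComplicated = 0, Paralysis = 7,
  OtherNeurological = 6, ChronicPulmonary = 3, DiabetesUncomplicated = 0,
  DiabetesComplicated = 0, Hypothyroidism = 0, RenalFailure = 5,
  LiverDisease = 11, PepticUlcer = 0, AIDSHIV = 0, Lymphoma = 9,
  MetastaticCancer = 12, SolidTumor = 4, RheumatoidArthritis = 0,
  Coagulopathy = 3, Obesity = -4, WeightLoss = 6, FluidElectrolyte = 5,
  BloodLossAnemia = -2, DeficiencyAnemia = -2, AlcoholAbuse = 0,
  DrugAbuse = -7, Psychoses = 0, Depression = -3)

#' Elixhauser score
#'
#' Default scheme is the unweighted count of groups present; the
#' `"vanwalraven"` scheme sums van Walraven (2009) weights instead.
#'
#' @inheritParams elixhauser_groups
#' @param scheme `"count"` (default) or `"vanwalraven"`.
#' @return Integer score.
#' @export
elixhauser_score <- function(icd9_codes, scheme = c("count", "vanwalraven")) {
  scheme <- match.arg(scheme)
  g <- elixhauser_groups(icd9_codes)
  if (scheme == "count") length(g) else sum(vw_weights[g])
}

#' Charlson comorbidity index
#'
#' Weighted sum over Charlson categories present (Quan ICD-9 mapping,
#' original weights 1/2/3/6), each category counted once regardless of code
#' multiplicity. The three canonical hierarchy rules apply: complicated
#' diabetes supersedes uncomplicated, moderate/severe liver disease
#' supersedes mild, and metastatic tumor supersedes (non-metastatic)
#' malignancy.
#'
#' @inheritParams elixhauser_groups
#' @return Non-negative integer score.
#' @examples
#' charlson_score("428.0")      # CHF, weight 1
#' charlson_score(c("585", "042"))  # renal (2) + HIV (6) = 8
#' @export
charlson_score <- function(icd9_codes) {
  codes <- normalize_icd9(icd9_codes)
  m <- charlson_map()
  cats <- match_prefix_groups(codes, m, "category")
  if ("DiabetesComplication" %in% cats)
    cats <- setdiff(cats, "DiabetesNoComplication")
  if ("ModerateSevereLiver" %in% cats)
    cats <- setdiff(cats, "MildLiver")
  if ("MetastaticTumor" %in% cats)
    cats <- setdiff(cats, "Malignancy")
  w <- m$weight[!duplicated(m$category)]
  names(w) <- m$category[!duplicated(m$category)]
  as.integer(sum(w[cats]))
}

#' Severity scores at the index discharge
#'
#' Pools ICD-9 diagnosis codes from all of a cohort member's admissions up
#' to and including the index admission (union semantics) and computes the
#' Charlson and Elixhauser scores. Admissions after the index admission
#' never contribute, so no post-discharge information leaks into the
#' scores.
#'
#' @param member one row of a cohort data frame from [select_cohort()].
#' @param tables an `ehr_tables` object.
#' @param elixhauser_scheme passed to [elixhauser_score()].
#' @return A list with `charlson`, `elixhauser` and `groups_present`.
#' @export
scores_at_discharge <- function(member, tables, elixhauser_scheme = "count") {
  adm_ids <- c(unlist(member$prior_admission_ids), member$index_admission_id)
  d <- tables$diagnoses_icd
  codes <- d$ICD9_CODE[d$HADM_ID %in% adm_ids]
  g <- elixhauser_groups(codes)
  list(
    charlson = charlson_score(codes),
    elixhauser = if (elixhauser_scheme == "count") length(g)
                 else sum(vw_weights[g]),
    groups_present = g)
}
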