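# CSV round trip for the seven EHR tables (MIMIC-III column names,
# ISO-8601 timestamps)

ehr_file_names <- c(
  patients = "PATIENTS.csv", admissions = "ADMISSIONS.csv",
  labevents = "LABEVENTS.csv", d_labitems = "D_LABITEMS.csv",
  diagnoses_icd = "DIAGNOSES_ICD.csv", procedures_icd = "PROCEDURES_ICD.csv",
  cptevents = "CPTEVENTS.csv")

ehr_time_cols <- list(
  patients = "DOB", admissions = c("ADMITTIME", "DISCHTIME"),
  labevents = "CHARTTIME", cptevents = "CHARTTIME")

ehr_char_cols <- list(
  diagnoses_icd = "ICD9_CODE", procedures_icd = "ICD9_CODE",
  cptevents = "CPT_CD")

#' Write EHR tables to a directory of CSV files
#'
#' One CSV per table (`PATIENTS.csv`, `ADMISSIONS.csv`, ...) with
#' MIMIC-III column names and ISO-8601 timestamps.
#'
#' @param tables an `ehr_tables` object.
#' @param directory target directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_ehr_tables <- function(tables, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (nm in names(ehr_file_names)) {
    df <- tables[[nm]]
    for (cc in ehr_time_cols[[nm]]) df[[cc]] <- num_to_iso(df[[cc]])
    utils::write.csv(df, file.path(directory, ehr_file_names[[nm]]),
                     row.names = FALSE)
  }
  invisible(directory)
}

#' Read EHR tables from a directory of CSV files
#'
#' Inverse of [write_ehr_tables()]; validates timestamps, foreign keys and
#' admission-interval invariants, raising a format error that names the
#' offending file and row.
#'
#' @param directory directory containing the seven CSV files.
#' @return An `ehr_tables` object.
#' @export
read_ehr_tables <- function(directory) {
  out <- list()
  for (nm in names(ehr_file_names)) {
    f <- file.path(directory, ehr_file_names[[nm]])
    if (!file.exists(f))
      stop_format("missing table file: %s", ehr_file_names[[nm]])
    df <- utils::read.csv(f, stringsAsFactors = FALSE,
                          colClasses = stats::setNames(
                            rep("character", length(ehr_char_cols[[nm]])),
                            ehr_char_cols[[nm]]))
    for (cc in ehr_time_cols[[nm]]) {
      v <- iso_to_num(df[[cc]])
      if (anyNA(v) && !all(is.na(df[[cc]]))) {
        row <- which(is.na(v) & !is.na(df[[cc]]))[1L]
        stop_format("%s row %d: unparsable timestamp '%s'",
                    ehr_file_names[[nm]], row, df[[cc]][row])
      }
      df[[cc]] <- v
    }
    out[[nm]] <- df
  }
  tables <- structure(out, class = "ehr_tables")
  validate_ehr_tables(tables)
  tables
}

#' @export
print.ehr_tables <- function(x, ...) {
  cat("<ehr_tables>\n")
  for (nm in names(ehr_file_names))
    cat(sprintf("  %-15s %7d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}
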