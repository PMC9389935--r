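patient_csv_columns <- c(
  "hospital_id", "patient_id", "onset_known", "onset_precise",
  "out_of_hospital_onset", "t_oa", "t_as", "t_sn", "age_80plus", "nihss",
  "ischemic", "prestroke_mrs", "anticoagulant", "arrival_by_ambulance",
  "thrombolysis"
)

#' Read and write the patient-level CSV
#'
#' One row per admission with a fixed header.  Times are integer minutes;
#' flags are 0/1; a missing value (onset-to-arrival when onset is unknown,
#' arrival-to-scan when never scanned, scan-to-needle when untreated) is an
#' empty field, never 0.
#'
#' @param patients a patient table as produced by [generate_patients()].
#' @param path file path.
#' @return `read_patients()` returns a tibble; `write_patients()` returns
#'   `path` invisibly.
#' @export
write_patients <- function(patients, path) {
  missing_cols <- setdiff(patient_csv_columns, names(patients))
  if (length(missing_cols)) {
    stop("patient table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(patients[patient_csv_columns], path, na = "")
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  spec <- readr::cols(
    hospital_id = readr::col_character(),
    patient_id = readr::col_character(),
    .default = readr::col_double()
  )
  out <- readr::read_csv(path, col_types = spec, na = "")
  missing_cols <- setdiff(patient_csv_columns, names(out))
  if (length(missing_cols)) {
    stop("patient CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out[patient_csv_columns]
}
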