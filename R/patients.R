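# The six-case clinical table shipped with the package. The values are
# embedded as code-level constants so the fixture cannot drift; a checksum
# test pins them.

PATIENT_TABLE <- data.frame(
  id = 1:6,
  category = c("incus", "incus", "stapes", "stapes", "adhesion",
               "adhesion_abnormal_EAC"),
  age = c(24, 47, 9, 50, 56, 18),
  sex = c("M", "M", "F", "M", "M", "F"),
  pta4_db_hl = c(31.7, 43.3, 23.3, 70.0, 23.3, 65.0),
  ab_gap_db_hl = c(27.5, 25.0, 18.8, 30.0, 28.8, 60.0),
  tympanogram = c("Ad", "Ad", "A", "A", "A", "A"),
  diagnosis = c(
    "Incus long process, complete loss",
    "Incus long process, incomplete loss",
    "Monopodal stapes",
    "Monopodal stapes; adhesion to the petrosus",
    "Adhesion of the malleus to the tympanic cavity; fixation of stapes",
    "Narrow EAC; adhesion of malleus and incus"
  ),
  surgery = c(
    "Tympanoplasty IIIiM",
    "Tympanoplasty III",
    "Tympanoplasty IVi",
    "Tympanoplasty I",
    "Tympanoplasty + stapedotomy",
    "Tympanoplasty IIIc"
  ),
  stringsAsFactors = FALSE
)

#' Load the shipped clinical case table
#'
#' Six surgically confirmed ossicular-malformation cases: incudostapedial
#' discontinuity (cases 1-2), monopodal stapes (cases 3-4) and attic adhesion
#' (cases 5-6), with their preoperative four-frequency pure-tone averages and
#' mean air-bone gaps in dB HL.
#'
#' @return A 6-row `data.frame` with columns `id`, `category`, `age`, `sex`,
#'   `pta4_db_hl`, `ab_gap_db_hl`, `tympanogram`, `diagnosis`, `surgery`.
#' @export
#' @examples
#' load_patient_table()
load_patient_table <- function() {
  PATIENT_TABLE
}

#' Summarise the clinical cohort
#'
#' @param records A patient table as returned by [load_patient_table()].
#' @return List with `n`, `mean_age`, `sd_age` (sample, n-1, `NA` for a single
#'   record), `sex_counts`, `mean_pta4`, `mean_ab_gap`. Values are kept at
#'   full precision; the print method rounds to one decimal.
#' @export
#' @examples
#' summarize_cohort(load_patient_table())
summarize_cohort <- function(records = load_patient_table()) {
  if (!is.data.frame(records) || !nrow(records)) {
    abort_data("'records' must be a non-empty patient table")
  }
  needed <- c("age", "sex", "pta4_db_hl", "ab_gap_db_hl")
  if (!all(needed %in% names(records))) {
    abort_data(sprintf("'records' must have columns: %s",
                       paste(needed, collapse = ", ")))
  }
  structure(
    list(n = nrow(records),
         mean_age = mean(records$age),
         sd_age = if (nrow(records) > 1L) stats::sd(records$age) else NA_real_,
         sex_counts = table(records$sex),
         mean_pta4 = mean(records$pta4_db_hl),
         mean_ab_gap = mean(records$ab_gap_db_hl)),
    class = "ear_cohort_summary"
  )
}

#' @export
print.ear_cohort_summary <- function(x, ...) {
  sd_disp <- if (is.na(x$sd_age)) "not available (n = 1)" else sprintf("%.1f", x$sd_age)
  cat(sprintf("Cohort of %d patient(s)\n", x$n))
  cat(sprintf("  age: %.1f +/- %s years (mean +/- sample SD)\n", x$mean_age, sd_disp))
  cat("  sex:", paste(names(x$sex_counts), as.integer(x$sex_counts),
                      sep = "=", collapse = ", "), "\n")
  cat(sprintf("  mean PTA4: %.1f dB HL; mean AB gap: %.1f dB HL\n",
              x$mean_pta4, x$mean_ab_gap))
  invisible(x)
}
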