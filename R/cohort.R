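#' @title Cohort data model and I/O
#' @name cohort-io
#'
#' @description
#' A cohort is a plain `data.frame` with one row per preoperative evaluation
#' and a companion long-format events table. The wide patient table uses the
#' following column dictionary:
#'
#' \describe{
#'   \item{patient_id}{opaque character id}
#'   \item{visit_date, surgery_date}{`Date`; `surgery_date >= visit_date`}
#'   \item{age}{integer years, >= 18}
#'   \item{sex}{"male"/"female"}
#'   \item{race}{"Asian", "African American", "White", "American Indian", "Others"}
#'   \item{hispanic}{logical}
#'   \item{afib, cad, chf, cva_tia, ckd, diabetes}{logical comorbidity flags}
#'   \item{mets_lt4}{logical, functional capacity below 4 METS}
#'   \item{asa_class}{integer 1-4}
#'   \item{rcri_*}{six logical RCRI components, see [rcri_score()]}
#'   \item{mica_risk_pct}{numeric percent in \[0, 100\]}
#'   \item{surgical_risk}{"low"/"moderate"/"high"}
#'   \item{active_cardiac_condition, cardiac_disease_unclear_status,
#'         ischemia_concern, ecg_flag, testing_may_change_management}{logical
#'         algorithm gate flags}
#' }
#'
#' The events table has columns `patient_id`, `event_type` (one of
#' "consult", "echo", "stress", "cath", "mi", "revasc", "chf_acute",
#' "death", "icu", "ed_visit", "readmission") and `date`.
NULL

RCRI_COLS <- c(
  "rcri_high_risk_surgery", "rcri_ischemic_heart_disease", "rcri_chf_history",
  "rcri_cerebrovascular_disease", "rcri_insulin_diabetes",
  "rcri_creatinine_gt2"
)

SERVICE_TYPES <- c("consult", "echo", "stress", "cath")
OUTCOME_TYPES <- c("mi", "revasc", "chf_acute", "death", "icu", "ed_visit",
                   "readmission")
MACE_COMPONENTS <- c("mi", "revasc", "chf_acute", "death")

# Columns whose absence means "missing preoperative risk scores"
RISK_SCORE_COLS <- c(RCRI_COLS, "mica_risk_pct", "mets_lt4", "asa_class")

#' Read / write cohort tables
#'
#' Round-trippable CSV I/O for the wide patient table and the long events
#' table. Dates are written as ISO-8601 and parsed back to `Date`; logical
#' columns survive the round trip.
#'
#' @param patients_file path to the wide patient CSV.
#' @param events_file optional path to the long events CSV.
#' @return `read_cohort()`: a list with elements `patients` (data.frame) and
#'   `events` (data.frame or `NULL`).
#' @export
read_cohort <- function(patients_file, events_file = NULL) {
  patients <- utils::read.csv(patients_file, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
  for (col in intersect(c("visit_date", "surgery_date"), names(patients)))
    patients[[col]] <- as.Date(patients[[col]])
  logicals <- intersect(
    c("hispanic", "afib", "cad", "chf", "cva_tia", "ckd", "diabetes",
      "mets_lt4", RCRI_COLS, "active_cardiac_condition",
      "cardiac_disease_unclear_status", "ischemia_concern", "ecg_flag",
      "testing_may_change_management"),
    names(patients)
  )
  for (col in logicals) patients[[col]] <- as.logical(patients[[col]])
  events <- NULL
  if (!is.null(events_file)) {
    events <- utils::read.csv(events_file, stringsAsFactors = FALSE)
    events$date <- as.Date(events$date)
  }
  list(patients = patients, events = events)
}

#' @rdname read_cohort
#' @param cohort list as returned by [read_cohort()] (element `events` may be
#'   `NULL`).
#' @export
write_cohort <- function(cohort, patients_file, events_file = NULL) {
  utils::write.csv(cohort$patients, patients_file, row.names = FALSE)
  if (!is.null(events_file) && !is.null(cohort$events))
    utils::write.csv(cohort$events, events_file, row.names = FALSE)
  invisible(c(patients_file, events_file))
}

#' Remove duplicate visits and records with missing risk scores
#'
#' Screens the raw evaluation table the way the study cohort was assembled:
#' repeated rows for the same `(patient_id, surgery_date)` are collapsed to
#' the chronologically first visit, and any record missing one of the
#' preoperative risk-tool fields (the six RCRI components, MICA risk percent,
#' METS class, or ASA class) is dropped.
#'
#' @param patients wide patient data.frame (may be empty).
#' @return list with `cohort` (the retained rows) and `accounting`, a one-row
#'   data.frame with `n_screened`, `n_duplicates`, `n_missing_scores`,
#'   `n_final` satisfying `n_final = n_screened - n_duplicates -
#'   n_missing_scores`.
#' @export
apply_exclusions <- function(patients) {
  n_screened <- nrow(patients)
  if (n_screened == 0L) {
    acct <- data.frame(n_screened = 0L, n_duplicates = 0L,
                       n_missing_scores = 0L, n_final = 0L)
    return(list(cohort = patients, accounting = acct))
  }
  stopifnot(all(c("patient_id", "surgery_date", "visit_date") %in%
                  names(patients)))
  # first visit per (patient_id, surgery_date); ties broken by row order
  ord <- order(patients$patient_id, patients$surgery_date,
               patients$visit_date)
  sorted <- patients[ord, , drop = FALSE]
  key <- paste(sorted$patient_id, sorted$surgery_date, sep = "\r")
  keep_sorted <- !duplicated(key)
  kept <- sorted[keep_sorted, , drop = FALSE]
  n_duplicates <- n_screened - nrow(kept)

  present <- intersect(RISK_SCORE_COLS, names(kept))
  absent_cols <- setdiff(RISK_SCORE_COLS, names(kept))
  miss <- if (length(present))
    Reduce(`|`, lapply(kept[present], is.na))
  else
    rep(FALSE, nrow(kept))
  if (length(absent_cols)) miss <- rep(TRUE, nrow(kept))
  n_missing <- sum(miss)
  final <- kept[!miss, , drop = FALSE]
  final <- final[order(match(rownames(final), rownames(patients))), ,
                 drop = FALSE]
  rownames(final) <- NULL
  acct <- data.frame(
    n_screened = n_screened, n_duplicates = n_duplicates,
    n_missing_scores = n_missing, n_final = nrow(final)
  )
  stopifnot(acct$n_final ==
              acct$n_screened - acct$n_duplicates - acct$n_missing_scores)
  list(cohort = final, accounting = acct)
}

#' Assign study period from the evaluation date
#'
#' Dichotomizes evaluations at the intervention cutover date: "pre" strictly
#' before the cutover, "post" on or after it. Visits outside the configured
#' study window get `NA` and are meant to be excluded from analysis.
#'
#' @param visit_date `Date` vector.
#' @param cutover_date cutover `Date` (default 2022-07-01).
#' @param study_start,study_end inclusive study window bounds; `NULL` disables
#'   the window check.
#' @return character vector in `{"pre", "post", NA}`.
#' @export
assign_period <- function(visit_date,
                          cutover_date = as.Date("2022-07-01"),
                          study_start = as.Date("2021-07-01"),
                          study_end = as.Date("2023-06-30")) {
  visit_date <- as.Date(visit_date)
  out <- ifelse(visit_date < as.Date(cutover_date), "pre", "post")
  if (!is.null(study_start))
    out[visit_date < as.Date(study_start)] <- NA_character_
  if (!is.null(study_end))
    out[visit_date > as.Date(study_end)] <- NA_character_
  out
}

#' Flag preoperative services completed within the lookback window
#'
#' A service (consultation, echocardiogram, stress test, catheterization)
#' counts as preoperative when it occurred within `window_days` before
#' surgery, inclusive at both ends: `0 <= surgery_date - event_date <=
#' window_days`. Events after surgery never set a preoperative flag, and
#' repeated events of one type collapse to a single flag.
#'
#' @param patients wide patient table with `patient_id` and `surgery_date`.
#' @param events long events table (`patient_id`, `event_type`, `date`); rows
#'   with non-service `event_type` are ignored.
#' @param window_days lookback in days (default 60).
#' @return `patients` with one logical column per service type.
#' @export
link_preop_services <- function(patients, events, window_days = 60) {
  flags <- matrix(FALSE, nrow = nrow(patients), ncol = length(SERVICE_TYPES),
                  dimnames = list(NULL, SERVICE_TYPES))
  if (!is.null(events) && nrow(events) && nrow(patients)) {
    ev <- events[events$event_type %in% SERVICE_TYPES, , drop = FALSE]
    if (nrow(ev)) {
      row_of <- match(ev$patient_id, patients$patient_id)
      ok <- !is.na(row_of)
      ev <- ev[ok, , drop = FALSE]; row_of <- row_of[ok]
      lag <- as.numeric(patients$surgery_date[row_of] - as.Date(ev$date))
      in_win <- lag >= 0 & lag <= window_days
      for (svc in SERVICE_TYPES) {
        hit <- row_of[in_win & ev$event_type == svc]
        flags[unique(hit), svc] <- TRUE
      }
    }
  }
  for (svc in SERVICE_TYPES) patients[[svc]] <- unname(flags[, svc])
  patients
}

#' Construct 30-day postoperative outcome flags and the MACE composite
#'
#' An outcome is flagged when an event of its type occurred in the 30 days
#' after surgery, exclusive of the day of surgery: `0 < event_date -
#' surgery_date <= window_days`. MACE is the set union (never the sum) of
#' acute MI, cardiac revascularization, acute CHF and all-cause death, so a
#' patient with several component events contributes one MACE.
#'
#' @inheritParams link_preop_services
#' @param window_days follow-up in days (default 30).
#' @return `patients` with one logical column per outcome plus `mace`.
#' @export
compute_30d_outcomes <- function(patients, events, window_days = 30) {
  flags <- matrix(FALSE, nrow = nrow(patients), ncol = length(OUTCOME_TYPES),
                  dimnames = list(NULL, OUTCOME_TYPES))
  if (!is.null(events) && nrow(events) && nrow(patients)) {
    ev <- events[events$event_type %in% OUTCOME_TYPES, , drop = FALSE]
    if (nrow(ev)) {
      row_of <- match(ev$patient_id, patients$patient_id)
      ok <- !is.na(row_of)
      ev <- ev[ok, , drop = FALSE]; row_of <- row_of[ok]
      lead <- as.numeric(as.Date(ev$date) - patients$surgery_date[row_of])
      in_win <- lead > 0 & lead <= window_days
      for (oc in OUTCOME_TYPES) {
        hit <- row_of[in_win & ev$event_type == oc]
        flags[unique(hit), oc] <- TRUE
      }
    }
  }
  for (oc in OUTCOME_TYPES) patients[[oc]] <- unname(flags[, oc])
  patients$mace <- Reduce(`|`, lapply(MACE_COMPONENTS, function(oc)
    patients[[oc]]), rep(FALSE, nrow(patients)))
  patients
}
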