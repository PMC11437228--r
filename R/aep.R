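#' Algorithm end point table
#'
#' The nine terminal nodes of the preoperative cardiac risk algorithm. The
#' gate logic is fixed; the numbering of the "proceed" branches is isolated
#' here so an institution renumbering its end points cannot change the
#' classification logic.
#'
#' @format data.frame with `aep_id`, `gate` (internal key), `label`,
#'   `recommendation`.
#' @export
aep_table <- function() {
  data.frame(
    aep_id = 1:9,
    gate = c("active_cardiac_condition", "cardiac_disease_unclear_status",
             "ischemia_concern", "ecg_flag", "low_risk_surgery",
             "rcri_gate", "mica_low", "mets_adequate", "testing_helpful"),
    label = c(
      "Active cardiac condition",
      "Known cardiac disease with unclear status",
      "Concern for myocardial ischemia",
      "New ECG changes or abnormal ECG without prior workup",
      "Low-risk surgery",
      "RCRI score 0 and age under 65",
      "Estimated MACE risk below 1%",
      "Elevated MACE risk with adequate functional capacity",
      "Elevated MACE risk, poor capacity, testing may change management"
    ),
    recommendation = c(
      "cardiology_before_surgery", "consider_cardiology",
      "consider_cardiology", "consider_cardiology",
      "proceed_to_surgery", "proceed_to_surgery", "proceed_to_surgery",
      "proceed_to_surgery", "consider_cardiology"
    ),
    stringsAsFactors = FALSE
  )
}

POSSIBLE_INDICATION_AEPS <- c(1L, 2L, 3L, 4L, 9L)

#' Consultation indication class of an end point
#'
#' End points 1-4 and 9 are "possible indications" for cardiology
#' consultation; every other end point is "no clear indication".
#'
#' @param aep_id integer vector of end point ids (1..9).
#' @return character vector, "possible_indication" or "no_clear_indication".
#' @export
aep_indication_class <- function(aep_id) {
  if (anyNA(aep_id) || !all(aep_id %in% 1:9))
    stop("aep_id must be in 1..9")
  ifelse(aep_id %in% POSSIBLE_INDICATION_AEPS,
         "possible_indication", "no_clear_indication")
}

#' Classify patients to algorithm end points
#'
#' Walks each record through the preoperative cardiac risk algorithm and
#' stops at the first gate that fires:
#'
#' 1. active cardiac condition -> AEP 1, cardiology before surgery;
#' 2. known cardiac disease with unclear status -> AEP 2, consider cardiology;
#' 3. concern for myocardial ischemia (nonacute symptoms) -> AEP 3;
#' 4. new/unevaluated abnormal ECG -> AEP 4;
#' 5. low-risk surgery -> AEP 5, proceed;
#' 6. RCRI score 0 and age < 65 -> AEP 6, proceed;
#' 7. estimated MACE risk < 1% (MICA, or supplied NSQIP percent) -> AEP 7;
#' 8. elevated risk but 4+ METS -> AEP 8, proceed;
#' 9. elevated risk, < 4 METS, testing may change management -> AEP 9,
#'    consider cardiology.
#'
#' A patient with elevated risk and poor functional capacity for whom further
#' testing would *not* change management proceeds to surgery; this
#' fallthrough shares end point 8 and is distinguishable in the trace.
#'
#' Each record reaches exactly one end point, so end-point counts always
#' partition the cohort.
#'
#' @param patients wide patient table (see [cohort-io]). When an
#'   `nsqip_risk_pct` column is present and non-missing it overrides
#'   `mica_risk_pct` for gate 7.
#' @param mica_threshold_pct strict low-risk threshold for gate 7 (default 1).
#' @param trace if `TRUE`, include a JSON-encoded decision trace per record
#'   (ordered `step`/`predicate`/`value` triples ending at the gate that
#'   fired).
#' @return data.frame with `aep_id`, `label`, `recommendation`,
#'   `indication_class` and (optionally) `trace`, one row per input record.
#' @export
aep_classify <- function(patients, mica_threshold_pct = 1, trace = FALSE) {
  n <- nrow(patients)
  need <- c("active_cardiac_condition", "cardiac_disease_unclear_status",
            "ischemia_concern", "ecg_flag", "surgical_risk", "age",
            "mets_lt4", "testing_may_change_management", "mica_risk_pct",
            RCRI_COLS)
  missing_cols <- setdiff(need, names(patients))
  if (length(missing_cols))
    stop("cannot evaluate algorithm, missing column(s): ",
         paste(missing_cols, collapse = ", "))

  score <- rcri_score(patients)
  risk_pct <- patients$mica_risk_pct
  if ("nsqip_risk_pct" %in% names(patients)) {
    ext <- patients$nsqip_risk_pct
    risk_pct <- ifelse(!is.na(ext), ext, risk_pct)
  }

  # gate predicates in firing order; each is a logical vector over records
  gates <- list(
    active_cardiac_condition = patients$active_cardiac_condition,
    cardiac_disease_unclear_status = patients$cardiac_disease_unclear_status,
    ischemia_concern = patients$ischemia_concern,
    ecg_flag = patients$ecg_flag,
    low_risk_surgery = patients$surgical_risk == "low",
    rcri_gate = rcri_low_risk_gate(score, patients$age),
    mica_low = mica_low_risk(risk_pct, mica_threshold_pct),
    mets_adequate = !patients$mets_lt4,
    testing_helpful = patients$testing_may_change_management
  )
  tab <- aep_table()

  aep <- rep(NA_integer_, n)
  fired_step <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  for (step in seq_along(gates)) {
    g <- gates[[step]]
    bad <- remaining & is.na(g)
    if (any(bad))
      stop("gate ", step, " (", names(gates)[step], ") unevaluable: ",
           "missing value in record(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    fire <- remaining & g
    aep[fire] <- tab$aep_id[tab$gate == names(gates)[step]]
    fired_step[fire] <- step
    remaining <- remaining & !fire
  }
  # fallthrough: elevated risk, poor capacity, testing would not change
  # management -> proceed, shares end point 8
  aep[remaining] <- 8L
  fired_step[remaining] <- length(gates) + 1L

  out <- data.frame(
    aep_id = aep,
    label = tab$label[match(aep, tab$aep_id)],
    recommendation = tab$recommendation[match(aep, tab$aep_id)],
    indication_class = if (n) aep_indication_class(aep) else character(0),
    stringsAsFactors = FALSE
  )
  out$label[fired_step == length(gates) + 1L] <-
    "Elevated MACE risk, poor capacity, testing would not change management"
  if (trace && n) {
    gate_names <- names(gates)
    gmat <- do.call(cbind, gates)
    out$trace <- vapply(seq_len(n), function(i) {
      k <- min(fired_step[i], length(gates))
      steps <- seq_len(k)
      paste0("[", paste0(
        '{"step":', steps,
        ',"predicate":"', gate_names[steps],
        '","value":', tolower(as.character(gmat[i, steps])), "}",
        collapse = ","), "]")
    }, character(1))
  }
  out
}

#' Per-end-point MACE table
#'
#' Tabulates cohort size, MACE count and MACE percent for each algorithm end
#' point. End points with no patients report a null percent rather than 0.
#'
#' @param aep_id integer vector of end point ids.
#' @param mace logical MACE flags, same length.
#' @return data.frame with one row per end point 1..9 plus a total row.
#' @export
aep_outcome_table <- function(aep_id, mace) {
  stopifnot(length(aep_id) == length(mace))
  tab <- aep_table()
  n <- vapply(tab$aep_id, function(k) sum(aep_id == k), integer(1))
  ev <- vapply(tab$aep_id, function(k) sum(mace[aep_id == k]), integer(1))
  pct <- ifelse(n > 0, 100 * ev / n, NA_real_)
  out <- data.frame(aep_id = tab$aep_id, label = tab$label, n = n,
                    mace = ev, mace_pct = pct, stringsAsFactors = FALSE)
  stopifnot(sum(out$n) == length(aep_id))
  out
}
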