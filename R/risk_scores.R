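#' Revised Cardiac Risk Index score
#'
#' Counts positive RCRI components. The six components are high-risk
#' (suprainguinal vascular, intrathoracic or intraperitoneal) surgery,
#' ischemic heart disease, history of congestive heart failure,
#' cerebrovascular disease, insulin-treated diabetes, and serum creatinine
#' above 2 mg/dL.
#'
#' @param components either a logical vector/matrix of the six components, or
#'   a data.frame carrying the `rcri_*` columns (see [cohort-io]).
#' @return integer score(s) in 0..6.
#' @export
rcri_score <- function(components) {
  if (is.data.frame(components)) {
    missing_cols <- setdiff(RCRI_COLS, names(components))
    if (length(missing_cols))
      stop("missing RCRI component column(s): ",
           paste(missing_cols, collapse = ", "))
    components <- as.matrix(components[RCRI_COLS])
  }
  if (is.null(dim(components))) {
    if (length(components) != 6L)
      stop("expected 6 RCRI components, got ", length(components))
    components <- matrix(components, nrow = 1L)
  }
  if (ncol(components) != 6L)
    stop("expected 6 RCRI components per record")
  if (anyNA(components))
    stop("RCRI components contain missing values; ",
         "such records should have been excluded upstream")
  as.integer(rowSums(components))
}

#' RCRI low-risk gate
#'
#' A patient is gated low risk on RCRI grounds only with a score of exactly
#' zero *and* age under 65 years; older patients carry elevated MACE risk
#' even without other risk factors, so age 65 and over always fails the gate.
#'
#' @param score RCRI score(s), 0..6.
#' @param age age(s) in years.
#' @return logical.
#' @export
rcri_low_risk_gate <- function(score, age) {
  stopifnot(all(score >= 0 & score <= 6, na.rm = TRUE))
  score == 0L & age < 65
}

#' MICA-style logistic perioperative risk
#'
#' Evaluates a logistic model of perioperative myocardial infarction or
#' cardiac arrest risk: `risk_pct = 100 * plogis(intercept + sum(coef *
#' feature))`. The coefficient set is supplied, not built in (the published
#' MICA coefficients can be transcribed into a model file; see
#' [read_mica_model()]); any synthetic coefficient set works identically.
#'
#' @param features named numeric vector or single-row list of feature values.
#' @param model list with numeric `intercept` and named numeric
#'   `coefficients`. Every feature name must have a coefficient.
#' @return risk in percent (0..100).
#' @export
mica_risk <- function(features, model) {
  stopifnot(is.numeric(model$intercept), length(model$intercept) == 1L)
  features <- unlist(features)
  unknown <- setdiff(names(features), names(model$coefficients))
  if (length(unknown))
    stop("unknown MICA feature(s): ", paste(unknown, collapse = ", "))
  lp <- model$intercept +
    sum(model$coefficients[names(features)] * features)
  100 * stats::plogis(lp)
}

#' @rdname mica_risk
#' @param risk_pct risk percent.
#' @param threshold_pct low-risk threshold, strict (default 1).
#' @return `mica_low_risk()`: logical, `TRUE` iff `risk_pct < threshold_pct`.
#' @export
mica_low_risk <- function(risk_pct, threshold_pct = 1) {
  risk_pct < threshold_pct
}

#' Read a MICA coefficient file
#'
#' YAML with keys `intercept` and `coefficients` (a map feature -> value).
#'
#' @param file path to YAML model file.
#' @export
read_mica_model <- function(file) {
  m <- yaml::read_yaml(file)
  m$coefficients <- unlist(m$coefficients)
  stopifnot(is.numeric(m$intercept), is.numeric(m$coefficients))
  m
}

#' Functional capacity class
#'
#' @param mets metabolic equivalents achieved (> 0).
#' @return "poor" when `mets < 4`, else "adequate".
#' @export
functional_capacity_class <- function(mets) {
  stopifnot(all(mets > 0, na.rm = TRUE))
  ifelse(mets < 4, "poor", "adequate")
}

#' Surgical risk level lookup
#'
#' Maps a procedure descriptor to its institutional risk level. The shipped
#' example map (`system.file("extdata", "surgical_risk_map.csv", package =
#' "preopcard")`) is illustrative, following conventional procedure classes;
#' institutions substitute their own.
#'
#' @param procedure character vector of procedure descriptors.
#' @param map data.frame with columns `procedure` and `level` (one of
#'   "low", "moderate", "high").
#' @return character vector of levels; unmapped procedures are an error so
#'   that the mapping must be configured explicitly.
#' @export
surgical_risk_level <- function(procedure, map) {
  stopifnot(is.data.frame(map), all(c("procedure", "level") %in% names(map)))
  if (!all(map$level %in% c("low", "moderate", "high")))
    stop("risk map levels must be low/moderate/high")
  idx <- match(procedure, map$procedure)
  if (anyNA(idx))
    stop("unmapped procedure(s): ",
         paste(unique(procedure[is.na(idx)]), collapse = ", "))
  map$level[idx]
}

#' @rdname surgical_risk_level
#' @param file CSV path with columns `procedure`, `level`.
#' @export
read_risk_map <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
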