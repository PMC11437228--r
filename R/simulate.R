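#' Specification for a synthetic two-period preoperative cohort
#'
#' Describes the marginal structure of a preoperative clinic population split
#' into a pre- and a post-intervention period: arm sizes, covariate
#' prevalences, confounding between covariates and period assignment,
#' per-period service-utilization and 30-day outcome rates, and the date
#' windows. Defaults encode the matched-cohort marginals of the motivating
#' two-year study population (~23k evaluations, ~36% cardiac comorbidity
#' burden, 23%/18% per-period consultation rates) with mild confounding of
#' the size seen in its unmatched arms.
#'
#' `confounding_strength` is a named vector of log-odds shifts toward the
#' *pre* period per unit covariate (positive values make the covariate more
#' prevalent pre-intervention, mimicking secular case-mix drift). Arm sizes
#' are exact: period labels are drawn by weighted sampling without
#' replacement, so `confounding_strength = 0` gives a uniformly random split.
#'
#' @param n_pre,n_post arm sizes.
#' @param covariates named list of prevalences: `sex_male`, `hispanic`, the
#'   six comorbidities, `mets_lt4`, `asa_3or4`, `rcri_component` (per-RCRI
#'   component Bernoulli rate), `mica_elevated`, plus probability vectors
#'   `race` and `surgical_risk`.
#' @param flags prevalences of the algorithm gate flags.
#' @param confounding_strength named numeric, see above. Recognised names:
#'   any binary covariate name plus `surgical_risk_high` and `race_White`.
#' @param service_rates named list, each element `c(pre=, post=)` completion
#'   probability of that preoperative service within the 60-day window.
#' @param outcome_rates named list, each element `c(pre=, post=)` 30-day
#'   outcome probability.
#' @param age list with `mean`, `sd`, `min`, `max` for the truncated-normal
#'   age draw.
#' @param noise list: `service_out_of_window` and `outcome_late` are rates of
#'   decoy events falling outside the 60-/30-day windows (they must never
#'   set a flag).
#' @param n_duplicates,n_missing_scores extra screened rows appended to
#'   exercise the exclusion filter: exact duplicate visits and records with a
#'   missing risk-tool field.
#' @param cutover,study_start,study_end study calendar (ISO dates).
#' @param seed default seed used by [simulate_cohort()] when none is given.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_pre = 13365, n_post = 12119,
    covariates = list(
      sex_male = 0.438, hispanic = 0.119,
      afib = 0.081, cad = 0.104, chf = 0.033, cva_tia = 0.040,
      ckd = 0.102, diabetes = 0.201,
      mets_lt4 = 0.146, asa_3or4 = 0.350,
      rcri_component = 0.067, mica_elevated = 0.050,
      race = c("Asian" = 0.012, "African American" = 0.079,
               "White" = 0.792, "American Indian" = 0.004,
               "Others" = 0.113),
      surgical_risk = c(low = 0.232, moderate = 0.558, high = 0.210)
    ),
    flags = list(
      active_cardiac_condition = 0.005,
      cardiac_disease_unclear_status = 0.020,
      ischemia_concern = 0.020, ecg_flag = 0.030,
      testing_may_change_management = 0.500
    ),
    confounding_strength = c(
      sex_male = 0.05, race_White = 0.10, afib = 0.09, cad = 0.10,
      ckd = 0.13, mets_lt4 = 0.14, surgical_risk_high = 0.12
    ),
    service_rates = list(
      consult = c(pre = 0.232, post = 0.179),
      echo = c(pre = 0.069, post = 0.051),
      stress = c(pre = 0.0170, post = 0.0155),
      cath = c(pre = 0.0045, post = 0.0038)
    ),
    outcome_rates = list(
      mi = c(pre = 0.0012, post = 0.0012),
      revasc = c(pre = 0.0002, post = 0.0004),
      chf_acute = c(pre = 0.0019, post = 0.0021),
      death = c(pre = 0.0014, post = 0.0014),
      icu = c(pre = 0.0145, post = 0.0157),
      ed_visit = c(pre = 0.058, post = 0.054),
      readmission = c(pre = 0.064, post = 0.065)
    ),
    age = list(mean = 63.5, sd = 13.5, min = 18, max = 95),
    noise = list(service_out_of_window = 0.01, outcome_late = 0.005),
    n_duplicates = 0, n_missing_scores = 0,
    cutover = "2022-07-01", study_start = "2021-07-01",
    study_end = "2023-06-30",
    seed = 1L) {
  spec <- list(
    n_pre = n_pre, n_post = n_post, covariates = covariates, flags = flags,
    confounding_strength = confounding_strength,
    service_rates = service_rates, outcome_rates = outcome_rates,
    age = age, noise = noise, n_duplicates = n_duplicates,
    n_missing_scores = n_missing_scores, cutover = cutover,
    study_start = study_start, study_end = study_end, seed = seed
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_pre >= 0, spec$n_post >= 0,
            spec$n_duplicates >= 0, spec$n_missing_scores >= 0)
  probs <- c(
    unlist(spec$covariates), unlist(spec$flags),
    unlist(spec$service_rates), unlist(spec$outcome_rates),
    unlist(spec$noise)
  )
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("all prevalences and rates must be probabilities in [0, 1]")
  for (nm in c("race", "surgical_risk"))
    if (abs(sum(spec$covariates[[nm]]) - 1) > 1e-8)
      stop("'", nm, "' probabilities must sum to 1")
  invisible(spec)
}

#' Read a cohort spec from YAML
#'
#' Fields absent from the file keep the [cohort_spec()] defaults. The shipped
#' `system.file("extdata", "table1_matched.yaml", package = "preopcard")`
#' encodes the study-population margins used throughout the test suite.
#'
#' @param file YAML path.
#' @export
read_cohort_spec <- function(file) {
  raw <- yaml::read_yaml(file)
  for (nm in c("confounding_strength"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  for (nm in c("service_rates", "outcome_rates"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- lapply(raw[[nm]], unlist)
  if (!is.null(raw$covariates))
    for (nm in c("race", "surgical_risk"))
      if (!is.null(raw$covariates[[nm]]))
        raw$covariates[[nm]] <- unlist(raw$covariates[[nm]])
  defaults <- formals(cohort_spec)
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown cohort_spec field(s): ", paste(unknown, collapse = ", "))
  # merge nested lists shallowly onto defaults
  args <- raw
  for (nm in c("covariates", "flags", "service_rates", "outcome_rates",
               "age", "noise")) {
    if (!is.null(raw[[nm]])) {
      base <- eval(defaults[[nm]])
      base[names(raw[[nm]])] <- raw[[nm]]
      args[[nm]] <- base
    }
  }
  do.call(cohort_spec, args)
}

#' Multiply the post-period odds of a service or outcome
#'
#' Creates a known ground-truth effect for pipeline-recovery experiments:
#' the post-period probability `p` becomes `q/(1+q)` with `q = relative_odds
#' * p/(1-p)`, everything else unchanged. With no confounding the marginal
#' pre-vs-post odds ratio of the modified event equals `1/relative_odds`.
#'
#' @param spec a [cohort_spec()].
#' @param service name of a configured service (or outcome).
#' @param relative_odds positive multiplier on the post-period odds.
#' @export
inject_effect <- function(spec, service, relative_odds) {
  if (!is.numeric(relative_odds) || relative_odds <= 0)
    stop("relative_odds must be > 0")
  where <- if (service %in% names(spec$service_rates)) "service_rates"
  else if (service %in% names(spec$outcome_rates)) "outcome_rates"
  else stop("service '", service, "' is not configured")
  p <- spec[[where]][[service]][["post"]]
  q <- relative_odds * p / (1 - p)
  spec[[where]][[service]][["post"]] <- q / (1 + q)
  validate_cohort_spec(spec)
  spec
}

r_days <- function(n, from, to) sample(seq.int(from, to), n, replace = TRUE)

#' Generate a synthetic cohort
#'
#' Draws a patient table and long events table from a [cohort_spec()]:
#' covariates are sampled independently at their configured prevalences,
#' period labels are assigned by confounding-tilted weighted sampling to the
#' exact arm sizes, and service/outcome events are placed uniformly inside
#' (or, for decoy events, outside) the 60-day preoperative and 30-day
#' postoperative windows. Output is reproducible: the same seed and spec give
#' identical tables.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list with `patients`, `events` (see [cohort-io]); `patients` has
#'   a `period` column consistent with [assign_period()].
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_pre + spec$n_post
  cv <- spec$covariates
  if (n == 0L) {
    patients <- empty_patients()
    return(list(patients = patients,
                events = data.frame(patient_id = character(0),
                                    event_type = character(0),
                                    date = as.Date(character(0)))))
  }

  rb <- function(p) stats::runif(n) < p
  age <- round(stats::qnorm(
    stats::runif(n, stats::pnorm(spec$age$min, spec$age$mean, spec$age$sd),
                 stats::pnorm(spec$age$max, spec$age$mean, spec$age$sd)),
    spec$age$mean, spec$age$sd))
  patients <- data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    age = pmin(pmax(age, spec$age$min), spec$age$max),
    sex = ifelse(rb(cv$sex_male), "male", "female"),
    race = sample(names(cv$race), n, replace = TRUE, prob = cv$race),
    hispanic = rb(cv$hispanic),
    afib = rb(cv$afib), cad = rb(cv$cad), chf = rb(cv$chf),
    cva_tia = rb(cv$cva_tia), ckd = rb(cv$ckd), diabetes = rb(cv$diabetes),
    mets_lt4 = rb(cv$mets_lt4),
    asa_class = ifelse(rb(cv$asa_3or4), sample(3:4, n, replace = TRUE),
                       sample(1:2, n, replace = TRUE)),
    surgical_risk = sample(names(cv$surgical_risk), n, replace = TRUE,
                           prob = cv$surgical_risk),
    mica_risk_pct = ifelse(rb(cv$mica_elevated),
                           stats::runif(n, 1, 8),
                           stats::runif(n, 0.05, 0.999)),
    stringsAsFactors = FALSE
  )
  for (col in RCRI_COLS) patients[[col]] <- rb(cv$rcri_component)
  for (fl in names(spec$flags)) patients[[fl]] <- rb(spec$flags[[fl]])

  # period assignment: weights tilted toward "pre" by the confounding shifts
  conf <- spec$confounding_strength
  lp <- rep(0, n)
  for (nm in names(conf)) {
    x <- switch(nm,
                sex_male = patients$sex == "male",
                race_White = patients$race == "White",
                surgical_risk_high = patients$surgical_risk == "high",
                asa_3or4 = patients$asa_class >= 3,
                patients[[nm]])
    if (is.null(x)) stop("unknown confounding covariate: ", nm)
    lp <- lp + conf[[nm]] * x
  }
  # P(pre) proportional to exp(lp); exact arm sizes via weighted sampling
  # without replacement (exponential-key trick, O(n log n))
  keys <- stats::rexp(n) / exp(lp)
  pre_idx <- if (spec$n_pre > 0)
    order(keys)[seq_len(spec$n_pre)] else integer(0)
  patients$period <- "post"
  patients$period[pre_idx] <- "pre"

  cutover <- as.Date(spec$cutover)
  pre_days <- as.integer(cutover - as.Date(spec$study_start))   # days before
  post_days <- as.integer(as.Date(spec$study_end) - cutover) + 1L
  is_pre <- patients$period == "pre"
  visit <- as.Date(rep(NA, n))
  visit[is_pre] <- cutover - r_days(sum(is_pre), 1L, pre_days)
  visit[!is_pre] <- cutover + r_days(sum(!is_pre), 0L, post_days - 1L)
  patients$visit_date <- visit
  patients$surgery_date <- visit + r_days(n, 7L, 45L)

  # events
  ev_pid <- character(0); ev_type <- character(0); ev_off <- integer(0)
  per <- patients$period
  add_events <- function(type, offs, who) {
    ev_pid <<- c(ev_pid, patients$patient_id[who])
    ev_type <<- c(ev_type, rep(type, length(who)))
    ev_off <<- c(ev_off, offs)
  }
  for (svc in names(spec$service_rates)) {
    p <- spec$service_rates[[svc]]
    hit <- which(stats::runif(n) < ifelse(per == "pre", p[["pre"]],
                                          p[["post"]]))
    add_events(svc, -r_days(length(hit), 0L, 60L), hit)
    decoy <- which(stats::runif(n) < spec$noise$service_out_of_window)
    add_events(svc, -r_days(length(decoy), 61L, 120L), decoy)
  }
  for (oc in names(spec$outcome_rates)) {
    p <- spec$outcome_rates[[oc]]
    hit <- which(stats::runif(n) < ifelse(per == "pre", p[["pre"]],
                                          p[["post"]]))
    add_events(oc, r_days(length(hit), 1L, 30L), hit)
    decoy <- which(stats::runif(n) < spec$noise$outcome_late)
    add_events(oc, r_days(length(decoy), 31L, 60L), decoy)
  }
  events <- data.frame(patient_id = ev_pid, event_type = ev_type,
                       stringsAsFactors = FALSE)
  events$date <- patients$surgery_date[match(ev_pid, patients$patient_id)] +
    ev_off
  events <- events[order(events$patient_id, events$event_type,
                         events$date), , drop = FALSE]
  rownames(events) <- NULL

  # planted exclusion material: exact duplicate visits (same patient and
  # surgery date, later visit) and extra screened rows with a missing score
  if (spec$n_duplicates > 0) {
    src <- patients[sample.int(n, spec$n_duplicates, replace = TRUE), ,
                    drop = FALSE]
    src$visit_date <- pmin(src$visit_date + 1L, src$surgery_date)
    patients <- rbind(patients, src)
  }
  if (spec$n_missing_scores > 0) {
    m <- spec$n_missing_scores
    src <- patients[sample.int(n, m, replace = TRUE), , drop = FALSE]
    src$patient_id <- sprintf("M%07d", seq_len(m))
    drop_col <- sample(c("mica_risk_pct", "asa_class", "mets_lt4",
                         RCRI_COLS[1]), m, replace = TRUE)
    for (j in seq_len(m)) src[[drop_col[j]]][j] <- NA
    patients <- rbind(patients, src)
  }
  rownames(patients) <- NULL
  list(patients = patients, events = events)
}

empty_patients <- function() {
  p <- data.frame(
    patient_id = character(0), age = integer(0), sex = character(0),
    race = character(0), hispanic = logical(0), afib = logical(0),
    cad = logical(0), chf = logical(0), cva_tia = logical(0),
    ckd = logical(0), diabetes = logical(0), mets_lt4 = logical(0),
    asa_class = integer(0), surgical_risk = character(0),
    mica_risk_pct = numeric(0), stringsAsFactors = FALSE
  )
  for (col in RCRI_COLS) p[[col]] <- logical(0)
  for (fl in c("active_cardiac_condition", "cardiac_disease_unclear_status",
               "ischemia_concern", "ecg_flag",
               "testing_may_change_management")) p[[fl]] <- logical(0)
  p$period <- character(0)
  p$visit_date <- as.Date(character(0))
  p$surgery_date <- as.Date(character(0))
  p
}
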