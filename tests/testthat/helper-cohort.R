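# fixture builders used across the suite

# one or more benign patient rows; override any field by name
make_patients <- function(n = 1, ...) {
  if (n == 0) return(make_patients(1)[0, , drop = FALSE])
  p <- data.frame(
    patient_id = sprintf("T%04d", seq_len(n)),
    visit_date = as.Date("2022-08-01"),
    surgery_date = as.Date("2022-09-01"),
    age = 50L,
    sex = "female",
    race = "White",
    hispanic = FALSE,
    afib = FALSE, cad = FALSE, chf = FALSE, cva_tia = FALSE,
    ckd = FALSE, diabetes = FALSE,
    mets_lt4 = FALSE,
    asa_class = 2L,
    surgical_risk = "moderate",
    mica_risk_pct = 0.5,
    rcri_high_risk_surgery = FALSE, rcri_ischemic_heart_disease = FALSE,
    rcri_chf_history = FALSE, rcri_cerebrovascular_disease = FALSE,
    rcri_insulin_diabetes = FALSE, rcri_creatinine_gt2 = FALSE,
    active_cardiac_condition = FALSE,
    cardiac_disease_unclear_status = FALSE,
    ischemia_concern = FALSE, ecg_flag = FALSE,
    testing_may_change_management = FALSE,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# Table 2 matched-cohort service counts (flagged/total per arm)
table2_counts <- function() {
  list(
    consult = c(pre = 2698, post = 2088),
    echo = c(pre = 808, post = 591),
    stress = c(pre = 198, post = 181),
    cath = c(pre = 52, post = 44),
    n_arm = 11645
  )
}

table2_2x2 <- function(service) {
  k <- table2_counts()
  n <- k$n_arm
  rbind(pre = c(yes = k[[service]][["pre"]], no = n - k[[service]][["pre"]]),
        post = c(yes = k[[service]][["post"]], no = n - k[[service]][["post"]]))
}

# a small flat cohort with exact per-arm flag counts, for report fixtures
flag_cohort <- function(counts, n_arm) {
  df <- data.frame(period = rep(c("pre", "post"), each = n_arm),
                   stringsAsFactors = FALSE)
  for (svc in names(counts)) {
    v <- logical(2 * n_arm)
    v[seq_len(counts[[svc]][["pre"]])] <- TRUE
    v[n_arm + seq_len(counts[[svc]][["post"]])] <- TRUE
    df[[svc]] <- v
  }
  df
}

# null spec for simulation experiments: no confounding, symmetric rates
null_spec <- function(n_arm = 1000) {
  spec <- cohort_spec(n_pre = n_arm, n_post = n_arm)
  spec$confounding_strength[] <- 0
  for (svc in names(spec$service_rates))
    spec$service_rates[[svc]][["post"]] <- spec$service_rates[[svc]][["pre"]]
  for (oc in names(spec$outcome_rates))
    spec$outcome_rates[[oc]][["post"]] <- spec$outcome_rates[[oc]][["pre"]]
  spec
}

# independent single-record transliteration of the algorithm, used as the
# truth-table oracle for the vectorized engine
aep_oracle <- function(rec) {
  if (rec$active_cardiac_condition) return(1L)
  if (rec$cardiac_disease_unclear_status) return(2L)
  if (rec$ischemia_concern) return(3L)
  if (rec$ecg_flag) return(4L)
  if (rec$surgical_risk == "low") return(5L)
  score <- sum(c(rec$rcri_high_risk_surgery, rec$rcri_ischemic_heart_disease,
                 rec$rcri_chf_history, rec$rcri_cerebrovascular_disease,
                 rec$rcri_insulin_diabetes, rec$rcri_creatinine_gt2))
  if (score == 0 && rec$age < 65) return(6L)
  if (rec$mica_risk_pct < 1) return(7L)
  if (!rec$mets_lt4) return(8L)
  if (rec$testing_may_change_management) return(9L)
  8L  # testing would not change management: proceed
}
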