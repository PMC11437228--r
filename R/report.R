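#' Percent formatting rule used in all report tables
#'
#' `100 * count / total`, rounded half away from zero to `digits` decimals
#' (one by default, matching clinical-table convention). Returns `NA` for an
#' empty denominator rather than 0.
#'
#' @param count,total numerator and denominator counts.
#' @param digits decimals kept (default 1).
#' @export
format_pct <- function(count, total, digits = 1) {
  ifelse(total > 0,
         round_half_up(100 * count / total, digits),
         NA_real_)
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' 30-day outcome comparison between periods
#'
#' Per-outcome totals, per-period counts and percents, and the pre-vs-post
#' test, for the postoperative outcomes including the MACE composite.
#'
#' @param x a `preop_match` or data.frame with `period` and outcome flag
#'   columns (see [compute_30d_outcomes()]).
#' @param outcomes outcome column names.
#' @inheritParams utilization_report
#' @export
outcome_report <- function(x, outcomes = c(OUTCOME_TYPES, "mace"),
                           fisher_threshold = 5) {
  df <- if (inherits(x, "preop_match")) x$data else x
  stopifnot("period" %in% names(df))
  two_period_report(df, outcomes, evalues = FALSE,
                    fisher_threshold = fisher_threshold)
}

#' MACE by consultation indication and consultation completion
#'
#' Post-period subanalysis: within each consultation indication class
#' ("possible indication" vs "no clear indication"), compares 30-day MACE
#' between patients with and without a completed preoperative cardiology
#' consultation.
#'
#' @param df post-period patient table with `indication_class`, `consult`
#'   and `mace` columns.
#' @return data.frame, one row per indication class: group sizes, MACE
#'   counts and percents with and without consultation, and the p-value.
#' @export
indication_mace_table <- function(df) {
  stopifnot(all(c("indication_class", "consult", "mace") %in% names(df)))
  classes <- c("no_clear_indication", "possible_indication")
  rows <- lapply(classes, function(cl) {
    sub <- df[df$indication_class == cl, , drop = FALSE]
    no <- sub[!sub$consult, , drop = FALSE]
    yes <- sub[sub$consult, , drop = FALSE]
    tab <- rbind(no_consult = c(mace = sum(no$mace),
                                none = nrow(no) - sum(no$mace)),
                 consult = c(mace = sum(yes$mace),
                             none = nrow(yes) - sum(yes$mace)))
    p <- NA_real_
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      p <- contingency_test(tab)$p_value
    data.frame(
      indication_class = cl, n = nrow(sub),
      n_no_consult = nrow(no),
      pct_no_consult = format_pct(nrow(no), nrow(sub)),
      n_consult = nrow(yes),
      pct_consult = format_pct(nrow(yes), nrow(sub)),
      mace_no_consult = sum(no$mace),
      mace_pct_no_consult = format_pct(sum(no$mace), nrow(no)),
      mace_consult = sum(yes$mace),
      mace_pct_consult = format_pct(sum(yes$mace), nrow(yes)),
      p_value = p
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monthly utilization series around the cutover
#'
#' Per-calendar-month count of evaluations and service completion percent,
#' with month 0 the cutover month; months with no evaluations are emitted
#' with `n = 0` and a null rate. Spans the whole configured study window.
#'
#' @param patients cohort table with `visit_date` and the service flag.
#' @param service service flag column name (e.g. "consult").
#' @param cutover_date,study_start,study_end study calendar.
#' @return data.frame with `month` (index relative to cutover), `n`,
#'   `rate_pct`.
#' @export
monthly_series <- function(patients, service,
                           cutover_date = as.Date("2022-07-01"),
                           study_start = as.Date("2021-07-01"),
                           study_end = as.Date("2023-06-30")) {
  stopifnot(service %in% names(patients))
  month_index <- function(d) {
    d <- as.POSIXlt(d)
    c0 <- as.POSIXlt(as.Date(cutover_date))
    12L * (d$year - c0$year) + (d$mon - c0$mon)
  }
  idx <- month_index(patients$visit_date)
  rng <- month_index(c(as.Date(study_start), as.Date(study_end)))
  months <- seq.int(rng[1], rng[2])
  n <- vapply(months, function(m) sum(idx == m, na.rm = TRUE), integer(1))
  hits <- vapply(months, function(m)
    sum(patients[[service]][idx == m], na.rm = TRUE), integer(1))
  data.frame(month = months, n = n, rate_pct = format_pct(hits, n))
}

#' Run the full retrospective evaluation pipeline
#'
#' Composes every stage end to end: exclusions, period assignment, service
#' and outcome linkage, algorithm end-point classification, propensity
#' matching, balance diagnostics, the utilization and outcome comparisons
#' with E-values, the indication-stratified MACE subanalysis, the per-end-
#' point MACE table, and the monthly utilization series. Input is either a
#' cohort (list of `patients` + `events`) or a [cohort_spec()], in which
#' case the cohort is simulated first.
#'
#' @param input a [cohort_spec()] or a list with `patients` and `events`.
#' @param seed seed for simulation and matching order.
#' @param cutover_date,study_start,study_end study calendar.
#' @param service_window_days,outcome_window_days linkage windows.
#' @param covariates propensity covariates.
#' @param caliper_sd_logit matching caliper.
#' @param common_prevalence_cutoff E-value conversion cutoff.
#' @return object of class `preop_study`: stage outputs (`accounting`,
#'   `cohort`, `fit`, `match`, `balance`, `utilization`, `outcomes`,
#'   `indication_mace`, `aep_mace`, `monthly_consult`) and a `manifest`
#'   recording seed, parameters and per-stage record counts.
#' @export
preop_study <- function(input, seed = 1L,
                        cutover_date = as.Date("2022-07-01"),
                        study_start = as.Date("2021-07-01"),
                        study_end = as.Date("2023-06-30"),
                        service_window_days = 60,
                        outcome_window_days = 30,
                        covariates = preop_covariates(),
                        caliper_sd_logit = 0.2,
                        common_prevalence_cutoff = 0.15) {
  if (inherits(input, "cohort_spec")) {
    cutover_date <- as.Date(input$cutover)
    study_start <- as.Date(input$study_start)
    study_end <- as.Date(input$study_end)
    input <- simulate_cohort(input, seed = seed)
  }
  stopifnot(is.list(input), !is.null(input$patients))
  counts <- list(screened = nrow(input$patients))

  excl <- apply_exclusions(input$patients)
  cohort <- excl$cohort
  counts$after_exclusions <- nrow(cohort)

  cohort$period <- assign_period(cohort$visit_date, cutover_date,
                                 study_start, study_end)
  cohort <- cohort[!is.na(cohort$period), , drop = FALSE]
  counts$in_window <- nrow(cohort)

  cohort <- link_preop_services(cohort, input$events,
                                window_days = service_window_days)
  cohort <- compute_30d_outcomes(cohort, input$events,
                                 window_days = outcome_window_days)
  aep <- aep_classify(cohort)
  cohort$aep_id <- aep$aep_id
  cohort$recommendation <- aep$recommendation
  cohort$indication_class <- aep$indication_class
  stopifnot(nrow(cohort) == counts$in_window)  # stage conservation

  fit <- fit_propensity(cohort, covariates)
  match <- match_pairs(fit, caliper_sd_logit = caliper_sd_logit, seed = seed)
  counts$matched <- 2L * match$n_pairs

  balance <- list(before = balance_table(cohort, covariates),
                  after = balance_table(match, covariates))
  util <- utilization_report(match,
                             common_prevalence_cutoff =
                               common_prevalence_cutoff)
  outc <- outcome_report(match)
  post_matched <- match$data[match$data$period == "post", , drop = FALSE]
  ind_mace <- indication_mace_table(post_matched)
  aep_mace <- aep_outcome_table(post_matched$aep_id, post_matched$mace)
  monthly <- monthly_series(cohort, "consult", cutover_date,
                            study_start, study_end)

  params <- list(
    cutover_date = as.character(cutover_date),
    study_start = as.character(study_start),
    study_end = as.character(study_end),
    service_window_days = service_window_days,
    outcome_window_days = outcome_window_days,
    covariates = covariates, caliper_sd_logit = caliper_sd_logit,
    common_prevalence_cutoff = common_prevalence_cutoff
  )
  manifest <- list(
    seed = seed, params = params, counts = counts,
    config_hash = config_hash(params),
    package_version = as.character(utils::packageVersion("preopcard")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(list(
    accounting = excl$accounting, cohort = cohort, fit = fit,
    match = match, balance = balance, utilization = util,
    outcomes = outc, indication_mace = ind_mace, aep_mace = aep_mace,
    monthly_consult = monthly, manifest = manifest
  ), class = "preop_study")
}

config_hash <- function(params) {
  json <- jsonlite::toJSON(params, auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a study report bundle to disk
#'
#' CSV analogues of the balance, utilization, outcome, indication-MACE,
#' per-end-point MACE and monthly tables, plus the JSON manifest.
#'
#' @param study a [preop_study()] result.
#' @param dir output directory (created if absent).
#' @export
write_report <- function(study, dir) {
  stopifnot(inherits(study, "preop_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(study$accounting, "exclusions.csv")
  w(study$balance$before, "balance_before.csv")
  w(study$balance$after, "balance_after.csv")
  w(study$utilization, "utilization.csv")
  w(study$outcomes, "outcomes.csv")
  w(study$indication_mace, "indication_mace.csv")
  w(study$aep_mace, "aep_mace.csv")
  w(study$monthly_consult, "monthly_consult.csv")
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.preop_study <- function(x, ...) {
  a <- x$accounting
  cat("Preoperative cardiac risk study pipeline\n")
  cat(sprintf("  screened %d; excluded %d duplicates, %d missing scores; final %d\n",
              a$n_screened, a$n_duplicates, a$n_missing_scores, a$n_final))
  cat(sprintf("  matched pairs: %d (%.1f%% of cohort retained)\n",
              x$match$n_pairs,
              100 * 2 * x$match$n_pairs / x$manifest$counts$in_window))
  u <- x$utilization[x$utilization$variable == "consult", ]
  if (nrow(u))
    cat(sprintf("  consultation: pre %.1f%% vs post %.1f%% (p = %.3g, E-value %.2f)\n",
                u$pct_pre, u$pct_post, u$p_value, u$evalue))
  invisible(x)
}

#' @export
summary.preop_study <- function(object, ...) {
  cat("== Exclusions ==\n"); print(object$accounting)
  cat("\n== Balance (max |SMD| before / after matching) ==\n")
  cat(sprintf("  %.3f / %.3f\n", max(object$balance$before$smd),
              max(object$balance$after$smd)))
  cat("\n== Utilization (matched) ==\n")
  print(object$utilization, row.names = FALSE)
  cat("\n== 30-day outcomes (matched) ==\n")
  print(object$outcomes, row.names = FALSE)
  cat("\n== MACE by consultation indication (post period) ==\n")
  print(object$indication_mace, row.names = FALSE)
  invisible(object)
}
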