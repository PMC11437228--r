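test_that("exclusion filter removes duplicates and missing-score rows with a consistent accounting", {
  base <- make_patients(100)
  base$patient_id <- sprintf("T%04d", 1:100)
  # plant 5 duplicate visits (same patient and surgery date, later visit)
  dup <- base[1:5, ]
  dup$visit_date <- dup$visit_date + 3
  # plant 3 rows with a missing risk-tool field
  mis <- make_patients(3, patient_id = sprintf("M%02d", 1:3))
  mis$mica_risk_pct[1] <- NA
  mis$asa_class[2] <- NA
  mis$rcri_chf_history[3] <- NA
  raw <- rbind(base, dup, mis)

  res <- apply_exclusions(raw)
  expect_equal(res$accounting$n_screened, 108)
  expect_equal(res$accounting$n_duplicates, 5)
  expect_equal(res$accounting$n_missing_scores, 3)
  expect_equal(res$accounting$n_final, 92 + 8)  # 100 unique complete rows
  # independent set-based recount: unique keys, then complete rows
  keys <- paste(raw$patient_id, raw$surgery_date)
  first <- !duplicated(keys)
  complete <- stats::complete.cases(
    raw[, c("mica_risk_pct", "asa_class", "mets_lt4",
            grep("^rcri_", names(raw), value = TRUE))])
  expect_equal(res$accounting$n_final, sum(first & complete))
  # the chronologically first visit is the one retained
  expect_true(all(res$cohort$visit_date[1:5] == base$visit_date[1:5]))

  # accounting identity holds on random planted inputs
  set.seed(7)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    p <- make_patients(n)
    p$patient_id <- sample(sprintf("R%02d", 1:15), n, replace = TRUE)
    p$mica_risk_pct[sample(n, sample(0:3, 1))] <- NA
    a <- apply_exclusions(p)$accounting
    expect_equal(a$n_final, a$n_screened - a$n_duplicates - a$n_missing_scores)
  }
})

test_that("exclusion filter accepts empty input", {
  res <- apply_exclusions(make_patients(0))
  expect_equal(unlist(res$accounting), c(n_screened = 0, n_duplicates = 0,
                                         n_missing_scores = 0, n_final = 0))
})

test_that("period assignment splits strictly at the cutover and flags out-of-window visits", {
  expect_equal(assign_period(as.Date("2022-06-30")), "pre")
  expect_equal(assign_period(as.Date("2022-07-01")), "post")
  # minimal representable cutover: everything is post
  expect_equal(
    assign_period(as.Date(c("2021-07-02", "2023-01-01")),
                  cutover_date = as.Date("0001-01-01"),
                  study_start = NULL, study_end = NULL),
    c("post", "post"))
  # visits outside the study window are flagged NA
  expect_true(is.na(assign_period(as.Date("2021-06-30"))))
  expect_true(is.na(assign_period(as.Date("2023-07-01"))))
})

test_that("service linkage honours the 60-day inclusive window and ignores postoperative events", {
  p <- make_patients(1, surgery_date = as.Date("2022-09-01"))
  ev <- function(type, offset)
    data.frame(patient_id = "T0001", event_type = type,
               date = as.Date("2022-09-01") + offset)
  expect_true(link_preop_services(p, ev("consult", -59))$consult)
  expect_true(link_preop_services(p, ev("echo", 0))$echo)    # day-0 inclusive
  expect_true(link_preop_services(p, ev("stress", -60))$stress)
  expect_false(link_preop_services(p, ev("stress", -61))$stress)
  expect_false(link_preop_services(p, ev("cath", 5))$cath)   # postoperative
  # several events of one type collapse to one flag
  two <- rbind(ev("consult", -10), ev("consult", -20))
  expect_equal(link_preop_services(p, two)$consult, TRUE)
})

test_that("service flags match a brute-force oracle and are order-invariant", {
  set.seed(11)
  n <- 200
  p <- make_patients(n)
  p$surgery_date <- as.Date("2022-09-01") + sample(0:100, n, replace = TRUE)
  ev <- data.frame(
    patient_id = sample(p$patient_id, 600, replace = TRUE),
    event_type = sample(c("consult", "echo", "stress", "cath"), 600,
                        replace = TRUE),
    stringsAsFactors = FALSE
  )
  ev$date <- p$surgery_date[match(ev$patient_id, p$patient_id)] +
    sample(-120:30, 600, replace = TRUE)
  got <- link_preop_services(p, ev)
  # oracle: per record, filter-and-count
  for (i in sample(n, 40)) {
    for (svc in c("consult", "echo", "stress", "cath")) {
      sub <- ev[ev$patient_id == p$patient_id[i] & ev$event_type == svc, ]
      lag <- as.numeric(p$surgery_date[i] - sub$date)
      expect_identical(got[[svc]][i], any(lag >= 0 & lag <= 60))
    }
  }
  shuffled <- ev[sample(nrow(ev)), ]
  got2 <- link_preop_services(p, shuffled)
  expect_identical(got, got2)
})

test_that("30-day outcomes use a (0, 30] window and MACE is a union, not a sum", {
  p <- make_patients(1, surgery_date = as.Date("2022-09-01"))
  ev <- function(type, offset)
    data.frame(patient_id = "T0001", event_type = type,
               date = as.Date("2022-09-01") + offset)
  expect_false(compute_30d_outcomes(p, ev("mi", 0))$mi)   # day of surgery
  expect_true(compute_30d_outcomes(p, ev("mi", 1))$mi)
  expect_true(compute_30d_outcomes(p, ev("death", 30))$death)
  expect_false(compute_30d_outcomes(p, ev("death", 31))$death)
  # MI and death on day 10: one MACE
  both <- rbind(ev("mi", 10), ev("death", 10))
  got <- compute_30d_outcomes(p, both)
  expect_true(got$mi && got$death)
  expect_equal(sum(got$mace), 1)
  # no events: all flags false
  none <- compute_30d_outcomes(p, NULL)
  expect_false(any(unlist(none[c("mi", "revasc", "chf_acute", "death",
                                 "mace")])))
})

test_that("MACE composite count never exceeds the sum of its components", {
  set.seed(3)
  n <- 150
  p <- make_patients(n)
  ev <- data.frame(
    patient_id = sample(p$patient_id, 300, replace = TRUE),
    event_type = sample(c("mi", "revasc", "chf_acute", "death"), 300,
                        replace = TRUE),
    stringsAsFactors = FALSE
  )
  ev$date <- p$surgery_date[match(ev$patient_id, p$patient_id)] +
    sample(1:40, 300, replace = TRUE)
  got <- compute_30d_outcomes(p, ev)
  comp_sum <- sum(got$mi) + sum(got$revasc) + sum(got$chf_acute) +
    sum(got$death)
  expect_lte(sum(got$mace), comp_sum)
  # equality iff no patient has more than one component
  multi <- got$mi + got$revasc + got$chf_acute + got$death > 1
  expect_equal(sum(got$mace) == comp_sum, !any(multi))
})

test_that("cohort tables round-trip through CSV", {
  sim <- simulate_cohort(cohort_spec(n_pre = 40, n_post = 40), seed = 5)
  pf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write_cohort(sim, pf, ef)
  back <- read_cohort(pf, ef)
  expect_equal(back$patients, sim$patients)
  expect_equal(back$events, sim$events)
  unlink(c(pf, ef))
})
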