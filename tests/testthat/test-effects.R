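test_that("chi-square matches the textbook formula and degenerates correctly", {
  # identical rows: statistic 0, p = 1
  even <- rbind(c(50, 50), c(50, 50))
  res <- contingency_test(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$test_used, "pearson_chi2")
  expect_error(contingency_test(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(contingency_test(rbind(c(1.5, 2), c(3, 4))), "integer")

  # independent direct formula on random tables
  set.seed(17)
  for (i in 1:200) {
    tab <- matrix(sample(5:80, 4), 2)
    res <- contingency_test(tab, fisher_threshold = 0)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    expect_equal(res$statistic, stat, tolerance = 1e-10)
    expect_equal(res$p_value, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("small expected cells trigger the Fisher exact test for 2x2 tables", {
  small <- rbind(c(2, 30), c(1, 28))
  res <- contingency_test(small)
  expect_equal(res$test_used, "fisher_exact")
  expect_equal(res$p_value, stats::fisher.test(small)$p.value)
  # raising the data above the threshold switches back to Pearson
  big <- small * 20
  expect_equal(contingency_test(big)$test_used, "pearson_chi2")
})

test_that("Bonferroni post hoc fires only when the omnibus test licenses it", {
  # 3 classes with a real difference in the third row
  sig <- rbind(a = c(50, 50), b = c(52, 48), c = c(90, 10))
  res <- contingency_test(sig)
  expect_lt(res$p_value, 0.05)
  expect_false(is.null(res$posthoc))
  expect_equal(res$posthoc$p_bonferroni,
               pmin(1, res$posthoc$p_raw * 3))
  # the a-vs-b contrast is not significant even though the omnibus is
  ab <- res$posthoc[res$posthoc$row_a == 1 & res$posthoc$row_b == 2, ]
  expect_gt(ab$p_bonferroni, 0.05)

  null3 <- rbind(c(50, 50), c(51, 49), c(49, 51))
  expect_null(contingency_test(null3)$posthoc)
})

test_that("odds ratio follows the 2x2 definition with zero-cell correction", {
  expect_equal(as.numeric(odds_ratio(rbind(c(7, 7), c(7, 7)))), 1)
  # matched echocardiogram counts: OR about 1.39
  or_echo <- odds_ratio(table2_2x2("echo"))
  expect_equal(as.numeric(or_echo), (808 * 11054) / (10837 * 591),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(or_echo), 2), 1.39)
  # transposing exposure rows inverts the OR
  tab <- rbind(c(12, 34), c(9, 41))
  expect_equal(as.numeric(odds_ratio(tab[2:1, ])),
               1 / as.numeric(odds_ratio(tab)), tolerance = 1e-12)
  zero <- rbind(c(0, 20), c(5, 15))
  expect_true(attr(odds_ratio(zero), "corrected"))
  expect_equal(as.numeric(odds_ratio(zero)), (0.5 * 15.5) / (20.5 * 5.5))
})

test_that("the E-value has its documented null, monotonicity and direction invariance", {
  expect_equal(evalue(1)$evalue, 1)
  expect_equal(evalue(1, outcome_common = TRUE)$evalue, 1)
  expect_error(evalue(0), "positive")
  expect_error(evalue(-2), "positive")
  rr <- seq(1, 6, by = 0.05)
  ev <- vapply(rr, function(r) evalue(r)$evalue, numeric(1))
  expect_true(all(diff(ev) >= 0))
  expect_true(all(ev >= 1))
  set.seed(5)
  for (or in exp(runif(25, -2, 2))) {
    expect_equal(evalue(or)$evalue, evalue(1 / or)$evalue, tolerance = 1e-12)
    expect_equal(evalue(or, TRUE)$evalue, evalue(1 / or, TRUE)$evalue,
                 tolerance = 1e-12)
    # sqrt conversion never exceeds the direct one away from the null
    expect_lte(evalue(or, TRUE)$evalue, evalue(or, FALSE)$evalue + 1e-12)
  }
})

test_that("Mann-Whitney handles degenerate and separated samples", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_lt(mann_whitney(1:20, 101:120)$p_value, 0.001)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney agrees with exhaustive permutation enumeration for small samples", {
  perm_p <- function(x, y) {
    n1 <- length(x); N <- n1 + length(y)
    pooled <- c(x, y)
    obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    center <- n1 * length(y) / 2
    sets <- utils::combn(N, n1)
    u <- apply(sets, 2, function(ix) {
      r <- rank(pooled)
      sum(r[ix]) - n1 * (n1 + 1) / 2
    })
    mean(abs(u - center) >= abs(obs - center) - 1e-12)
  }
  set.seed(33)
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- runif(n1); y <- runif(n2)  # continuous, no ties
    got <- mann_whitney(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, perm_p(x, y), tolerance = 1e-9)
  }
})

test_that("the utilization report reproduces a known table and handles empty services", {
  k <- table2_counts()
  df <- flag_cohort(k[c("consult", "echo", "stress", "cath")], k$n_arm)
  rep <- utilization_report(df)
  expect_equal(rep$variable, c("consult", "echo", "stress", "cath"))
  expect_equal(rep$pct_pre, c(23.2, 6.9, 1.7, 0.4))
  expect_equal(rep$pct_post, c(17.9, 5.1, 1.6, 0.4))
  expect_equal(round(rep$evalue, 2), c(1.63, 2.14, 1.42, 1.65))
  expect_equal(rep$outcome_common, c(TRUE, FALSE, FALSE, FALSE))

  none <- df
  none$consult <- FALSE
  rep0 <- utilization_report(none, services = "consult")
  expect_equal(rep0$pct_pre, 0)
  expect_true(is.na(rep0$p_value))
  expect_true(is.na(rep0$evalue))
})

test_that("the matched pipeline recovers an injected utilization effect", {
  spec <- inject_effect(null_spec(1500), "consult", 0.6)
  p <- simulate_cohort(spec, seed = 77)
  cohort <- link_preop_services(p$patients, p$events)
  m <- match_pairs(fit_propensity(cohort), seed = 77)
  rep <- utilization_report(m, services = "consult")
  true_or <- 1 / 0.6
  # recovered OR within a simulation 95% CI of the truth
  tab <- rbind(c(rep$n_pre, sum(m$data$period == "pre") - rep$n_pre),
               c(rep$n_post, sum(m$data$period == "post") - rep$n_post))
  se <- sqrt(sum(1 / tab))
  ci <- exp(log(rep$odds_ratio) + c(-1.96, 1.96) * se)
  expect_gt(true_or, ci[1])
  expect_lt(true_or, ci[2])
})
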