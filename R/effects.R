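#' Contingency-table comparison with small-sample fallback and post hoc
#'
#' Pearson chi-square without continuity correction by default; for a 2x2
#' table whose smallest expected cell falls below `fisher_threshold` the
#' Fisher exact test is used instead. For an r x c table with more than two
#' row classes and an overall p below `posthoc_alpha`, Bonferroni-adjusted
#' pairwise row comparisons are appended; pairwise significance is never
#' reported unless the omnibus test licenses it.
#'
#' @param table matrix of non-negative integer counts, at least 2x2.
#' @param fisher_threshold expected-cell threshold for the Fisher fallback
#'   (default 5).
#' @param posthoc_alpha omnibus significance level gating the post hoc
#'   (default 0.05).
#' @return object of class `contingency_result`: `table`, `test_used`
#'   ("pearson_chi2" or "fisher_exact"), `statistic`, `p_value`, `posthoc`
#'   (data.frame or `NULL`).
#' @export
contingency_test <- function(table, fisher_threshold = 5,
                             posthoc_alpha = 0.05) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has an all-zero margin")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(dim(table) == 2L) && any(expected < fisher_threshold)) {
    ft <- stats::fisher.test(table)
    res <- list(table = table, test_used = "fisher_exact",
                statistic = NA_real_, p_value = ft$p.value, posthoc = NULL)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    res <- list(table = table, test_used = "pearson_chi2",
                statistic = unname(ct$statistic),
                p_value = ct$p.value, posthoc = NULL)
  }
  if (nrow(table) > 2L && res$p_value < posthoc_alpha) {
    pairs <- utils::combn(nrow(table), 2L)
    raw <- apply(pairs, 2L, function(ij) {
      sub <- table[ij, , drop = FALSE]
      keep <- colSums(sub) > 0
      suppressWarnings(stats::chisq.test(sub[, keep, drop = FALSE],
                                         correct = FALSE)$p.value)
    })
    res$posthoc <- data.frame(
      row_a = pairs[1L, ], row_b = pairs[2L, ], p_raw = raw,
      p_bonferroni = stats::p.adjust(raw, method = "bonferroni")
    )
  }
  structure(res, class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.4g\n", x$test_used,
              ifelse(is.na(x$statistic), "-", sprintf("%.4f", x$statistic)),
              x$p_value))
  if (!is.null(x$posthoc)) {
    cat("Bonferroni post hoc (pairwise rows):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' Rows are exposure periods (pre, post), columns outcome (yes, no); the
#' returned value is `(a*d)/(b*c)`, the odds of the outcome pre relative to
#' post. When any cell is zero the Haldane-Anscombe 0.5 correction is
#' applied to every cell (recorded in the `"corrected"` attribute).
#'
#' @param table 2x2 count matrix.
#' @return positive numeric with attribute `corrected`.
#' @export
odds_ratio <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  corrected <- any(table == 0)
  if (corrected) table <- table + 0.5
  out <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  attr(out, "corrected") <- corrected
  out
}

#' E-value for unmeasured confounding
#'
#' Converts an observed odds ratio to an approximate risk ratio — direct
#' substitution when the outcome is rare, the square-root conversion when it
#' is common — takes the reciprocal when the approximate RR is below 1 (the
#' E-value is direction-invariant), and applies
#' `E = RR + sqrt(RR * (RR - 1))`. An E-value of 1 (its minimum, reached
#' exactly at RR = 1) means no unmeasured confounding is needed to explain
#' the association; larger values mean a stronger confounder would be
#' required.
#'
#' @param or_value observed odds ratio, > 0.
#' @param outcome_common `TRUE` to use the square-root OR-to-RR conversion.
#' @return object of class `effect_sensitivity` with `or_value`,
#'   `rr_approx` (>= 1 after the reciprocal rule), `evalue`,
#'   `outcome_common`.
#' @export
evalue <- function(or_value, outcome_common = FALSE) {
  or_value <- as.numeric(or_value)
  if (!is.finite(or_value) || or_value <= 0)
    stop("or_value must be a positive number")
  rr <- if (outcome_common) sqrt(or_value) else or_value
  if (rr < 1) rr <- 1 / rr
  e <- rr + sqrt(rr * (rr - 1))
  structure(list(or_value = or_value, rr_approx = rr, evalue = e,
                 outcome_common = outcome_common),
            class = "effect_sensitivity")
}

#' @export
print.effect_sensitivity <- function(x, ...) {
  cat(sprintf("OR = %.3f, approx RR = %.3f (%s outcome), E-value = %.2f\n",
              x$or_value, x$rr_approx,
              if (x$outcome_common) "common" else "rare", x$evalue))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two independent samples. Without ties (and at
#' most 50 observations per group) the exact null distribution of U is used,
#' which reproduces full permutation enumeration; with ties, the normal
#' approximation with tie-corrected variance and no continuity correction.
#' Degenerate data with zero variance give p = 1.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `statistic` (U for the first sample), `p_value`,
#'   `method`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= 50 && n2 <= 50) {
    p_less <- stats::pwilcox(U, n1, n2)
    p_greater <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_less, p_greater))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  list(statistic = unname(U), p_value = p, method = method)
}

#' Service-utilization comparison with sensitivity analysis
#'
#' For each preoperative service, tabulates totals and per-period counts and
#' percents, tests the pre-vs-post difference (Pearson chi-square, Fisher
#' fallback), and attaches the odds ratio and its E-value. The OR-to-RR
#' conversion is chosen automatically: square-root (common outcome) when the
#' pooled prevalence is at least `common_prevalence_cutoff`, direct
#' otherwise. Services never used give null p and E-values.
#'
#' @param x a `preop_match` or a data.frame with `period` and one logical
#'   column per service.
#' @param services service column names (default consult, echo, stress,
#'   cath).
#' @param common_prevalence_cutoff pooled-prevalence cutoff for the
#'   common-outcome conversion (default 0.15).
#' @param fisher_threshold passed to [contingency_test()].
#' @return data.frame, one row per service: counts, percents, `test`, `p_value`,
#'   `odds_ratio`, `outcome_common`, `evalue`.
#' @export
utilization_report <- function(x, services = SERVICE_TYPES,
                               common_prevalence_cutoff = 0.15,
                               fisher_threshold = 5) {
  df <- if (inherits(x, "preop_match")) x$data else x
  stopifnot("period" %in% names(df))
  two_period_report(df, services, evalues = TRUE,
                    common_prevalence_cutoff = common_prevalence_cutoff,
                    fisher_threshold = fisher_threshold)
}

two_period_report <- function(df, vars, evalues,
                              common_prevalence_cutoff = 0.15,
                              fisher_threshold = 5) {
  pre <- df$period == "pre"; post <- df$period == "post"
  n_pre <- sum(pre); n_post <- sum(post); n_tot <- n_pre + n_post
  rows <- lapply(vars, function(v) {
    a <- sum(df[[v]][pre]); b <- sum(df[[v]][post])
    tab <- rbind(pre = c(yes = a, no = n_pre - a),
                 post = c(yes = b, no = n_post - b))
    out <- data.frame(
      variable = v, n_total = a + b,
      pct_total = format_pct(a + b, n_tot),
      n_pre = a, pct_pre = format_pct(a, n_pre),
      n_post = b, pct_post = format_pct(b, n_post),
      test = NA_character_, p_value = NA_real_
    )
    if (a + b > 0 && a + b < n_tot) {
      ct <- contingency_test(tab, fisher_threshold = fisher_threshold)
      out$test <- ct$test_used
      out$p_value <- ct$p_value
    }
    if (evalues) {
      out$odds_ratio <- NA_real_
      out$outcome_common <- NA
      out$evalue <- NA_real_
      if (a + b > 0 && a + b < n_tot) {
        or <- odds_ratio(tab)
        common <- (a + b) / n_tot >= common_prevalence_cutoff
        out$odds_ratio <- as.numeric(or)
        out$outcome_common <- common
        out$evalue <- evalue(or, outcome_common = common)$evalue
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
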