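#' Default propensity-model covariate set
#'
#' The baseline characteristics used to model period membership:
#' demographics (age, sex, race, ethnicity), the six comorbidities, and the
#' perioperative risk-tool classes (METS below 4, ASA 3-4, RCRI 2 or more,
#' MICA elevated, surgical risk level).
#'
#' @export
preop_covariates <- function() {
  c("age", "sex", "race", "hispanic", "afib", "cad", "chf", "cva_tia",
    "ckd", "diabetes", "mets_lt4", "asa_34", "rcri_2plus", "mica_elevated",
    "surgical_risk")
}

# adds the derived risk-class columns the covariate set refers to
ps_frame <- function(patients) {
  if (!"asa_34" %in% names(patients) && "asa_class" %in% names(patients))
    patients$asa_34 <- patients$asa_class >= 3
  if (!"rcri_2plus" %in% names(patients) &&
      all(RCRI_COLS %in% names(patients)))
    patients$rcri_2plus <- rcri_score(patients) >= 2
  if (!"mica_elevated" %in% names(patients) &&
      "mica_risk_pct" %in% names(patients))
    patients$mica_elevated <- !mica_low_risk(patients$mica_risk_pct)
  patients
}

#' Fit a propensity model for period membership
#'
#' Logistic regression of the post-period indicator on the baseline
#' covariates, giving each record its predicted probability of belonging to
#' the post-intervention cohort. With an empty covariate set the model is
#' intercept-only and every score equals the empirical post proportion.
#'
#' @param patients cohort table with a `period` column ("pre"/"post"); both
#'   periods must be represented.
#' @param covariates character vector of column names (factors and logicals
#'   handled as usual); defaults to [preop_covariates()].
#' @return object of class `propensity_fit`: the `glm` fit, per-record
#'   `score` in (0, 1) and its logit, and the data used.
#' @export
fit_propensity <- function(patients, covariates = preop_covariates()) {
  stopifnot("period" %in% names(patients))
  patients <- ps_frame(patients)
  if (!all(patients$period %in% c("pre", "post")))
    stop("period must be 'pre'/'post' with no missing values")
  if (length(unique(patients$period)) < 2L)
    stop("both periods must be non-empty")
  missing_cols <- setdiff(covariates, names(patients))
  if (length(missing_cols))
    stop("covariate column(s) not found: ",
         paste(missing_cols, collapse = ", "))

  df <- patients[, covariates, drop = FALSE]
  for (j in names(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  df$.post <- as.integer(patients$period == "post")
  fml <- if (length(covariates))
    stats::as.formula(paste(".post ~", paste(covariates, collapse = " + ")))
  else stats::as.formula(".post ~ 1")

  sep <- FALSE
  model <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  score <- as.numeric(stats::fitted(model))
  eps <- 1e-8  # glm's own convergence scale; scores this extreme mean
               # period membership is deterministic given the covariates
  if (sep || any(score <= eps) || any(score >= 1 - eps))
    stop("propensity model shows (quasi-)separation: some scores are ",
         "numerically 0 or 1; review the covariate set")
  structure(list(
    model = model, covariates = covariates, score = score,
    logit = stats::qlogis(score), data = patients
  ), class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Propensity model (logistic) for post-period membership\n")
  cat("  records:", length(x$score),
      " covariates:", length(x$covariates), "\n")
  cat("  score range:", sprintf("%.4f .. %.4f", min(x$score), max(x$score)),
      "\n")
  invisible(x)
}

#' @export
summary.propensity_fit <- function(object, ...) summary(object$model, ...)

#' @export
coef.propensity_fit <- function(object, ...) stats::coef(object$model)

#' @export
predict.propensity_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$score)
  nd <- ps_frame(newdata)
  for (j in names(nd)) if (is.character(nd[[j]])) nd[[j]] <- factor(nd[[j]])
  as.numeric(stats::predict(object$model, newdata = nd, type = "response"))
}

#' 1:1 greedy caliper matching on the logit of the propensity score
#'
#' Pairs each post-period record with the nearest available pre-period
#' record on the logit scale, processing cases in a seeded random order,
#' without replacement, and discarding pairs wider than the caliper.
#' Distance ties are broken toward the earlier-ingested control. The result
#' is deterministic given the seed.
#'
#' @param fit a [fit_propensity()] object.
#' @param caliper_sd_logit caliper as a multiple of the standard deviation of
#'   the logit scores (default 0.2); `Inf` disables it.
#' @param seed integer seed for the processing order.
#' @return object of class `preop_match`: `pairs` (case/control ids, indices
#'   and distances), `n_pairs`, `unmatched` ids per period, the caliper
#'   actually applied, and `data` — the matched rows with a `pair_id`
#'   column.
#' @export
match_pairs <- function(fit, caliper_sd_logit = 0.2, seed = 1L) {
  stopifnot(inherits(fit, "propensity_fit"))
  patients <- fit$data
  lg <- fit$logit
  case_idx <- which(patients$period == "post")
  ctrl_idx <- which(patients$period == "pre")
  cal <- if (is.finite(caliper_sd_logit))
    caliper_sd_logit * stats::sd(lg) else Inf
  if (is.na(cal)) cal <- Inf  # constant scores: sd undefined, no caliper

  m <- length(ctrl_idx)
  ord <- order(lg[ctrl_idx], ctrl_idx)  # sorted controls, stable
  cs <- lg[ctrl_idx][ord]
  corig <- ctrl_idx[ord]

  set.seed(seed)
  case_order <- case_idx[sample.int(length(case_idx))]

  # union-find style "nearest alive neighbour" arrays over sorted positions
  L <- 0:(m + 1L)          # L[i+1] = largest alive pos <= i (0 = none)
  R <- 0:(m + 1L)          # R[i+1] = smallest alive pos >= i (m+1 = none)
  find_left <- function(i) {
    j <- i
    while (L[j + 1L] != j) j <- L[j + 1L]
    while (L[i + 1L] != j) { nxt <- L[i + 1L]; L[i + 1L] <<- j; i <- nxt }
    j
  }
  find_right <- function(i) {
    j <- i
    while (R[j + 1L] != j) j <- R[j + 1L]
    while (R[i + 1L] != j) { nxt <- R[i + 1L]; R[i + 1L] <<- j; i <- nxt }
    j
  }

  jj <- findInterval(lg[case_order], cs)
  nmax <- length(case_order)
  pair_case <- integer(nmax); pair_ctrl <- integer(nmax)
  pair_dist <- numeric(nmax); np <- 0L
  for (k in seq_len(nmax)) {
    x <- lg[case_order[k]]
    l <- find_left(jj[k])
    r <- find_right(jj[k] + 1L)
    dl <- if (l >= 1L) x - cs[l] else Inf
    dr <- if (r <= m) cs[r] - x else Inf
    if (dl == Inf && dr == Inf) next
    # nearest; ties toward the earlier-ingested control
    pick <- if (dl < dr) l
    else if (dr < dl) r
    else if (corig[l] <= corig[r]) l else r
    d <- min(dl, dr)
    if (d > cal) next
    np <- np + 1L
    pair_case[np] <- case_order[k]
    pair_ctrl[np] <- corig[pick]
    pair_dist[np] <- d
    L[pick + 1L] <- pick - 1L
    R[pick + 1L] <- pick + 1L
  }
  pair_case <- pair_case[seq_len(np)]
  pair_ctrl <- pair_ctrl[seq_len(np)]
  pair_dist <- pair_dist[seq_len(np)]
  if (anyDuplicated(pair_ctrl) || anyDuplicated(pair_case))
    stop("internal error: matching reused a record")

  n_pairs <- length(pair_case)
  pid <- patients$patient_id
  matched_rows <- c(rbind(pair_ctrl, pair_case))  # interleave pre/post
  data <- patients[matched_rows, , drop = FALSE]
  data$pair_id <- rep(seq_len(n_pairs), each = 2L)
  rownames(data) <- NULL
  structure(list(
    pairs = data.frame(pair_id = seq_len(n_pairs),
                       pre_id = pid[pair_ctrl], post_id = pid[pair_case],
                       pre_idx = pair_ctrl, post_idx = pair_case,
                       distance = pair_dist),
    n_pairs = n_pairs,
    unmatched = list(pre = pid[setdiff(ctrl_idx, pair_ctrl)],
                     post = pid[setdiff(case_idx, pair_case)]),
    caliper_sd_logit = caliper_sd_logit, caliper_abs = cal, seed = seed,
    n_pre = length(ctrl_idx), n_post = length(case_idx),
    data = data
  ), class = "preop_match")
}

#' @export
print.preop_match <- function(x, ...) {
  total <- x$n_pre + x$n_post
  cat("1:1 propensity-matched cohort\n")
  cat(sprintf("  pairs: %d  (%d/%d records matched, %.1f%%)\n",
              x$n_pairs, 2L * x$n_pairs, total,
              if (total) 100 * 2 * x$n_pairs / total else NA_real_))
  cat(sprintf("  caliper: %.3g SD of logit (|logit diff| <= %.4g)\n",
              x$caliper_sd_logit, x$caliper_abs))
  invisible(x)
}

# degenerate-safe wrapper: a covariate with an empty margin (e.g. a flag
# nobody has) carries no imbalance information -> statistic 0, p = 1
safe_contingency <- function(tab, ...) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(test_used = "degenerate", statistic = 0, p_value = 1))
  contingency_test(tab, ...)
}

smd_binary <- function(p1, p2) {
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (v == 0) return(0)
  (p1 - p2) / sqrt(v)
}

#' Covariate balance diagnostics
#'
#' Standardized mean differences and pre-vs-post hypothesis tests for each
#' covariate, on a raw cohort or on a matched cohort. Continuous covariates
#' use the pooled-variance SMD and the Mann-Whitney test; binary ones the
#' proportion SMD and the chi-square (or Fisher) test; multi-level factors
#' report the largest per-level SMD and the overall r x c chi-square.
#' SMDs are reported alongside p-values because p-value balance checks
#' depend on sample size.
#'
#' @param x a `preop_match` or a cohort data.frame with a `period` column.
#' @param covariates covariate names; defaults to [preop_covariates()].
#' @return data.frame with `variable`, `type`, `smd` (absolute), `test`,
#'   `p_value`.
#' @export
balance_table <- function(x, covariates = preop_covariates()) {
  df <- if (inherits(x, "preop_match")) x$data else x
  df <- ps_frame(df)
  stopifnot(nrow(df) > 0, "period" %in% names(df))
  pre <- df[df$period == "pre", , drop = FALSE]
  post <- df[df$period == "post", , drop = FALSE]
  rows <- lapply(covariates, function(v) {
    a <- pre[[v]]; b <- post[[v]]
    if (is.numeric(a) && length(unique(df[[v]])) > 2L) {
      vp <- (stats::var(a) + stats::var(b)) / 2
      smd <- if (vp == 0) 0 else (mean(a) - mean(b)) / sqrt(vp)
      p <- mann_whitney(a, b)$p_value
      data.frame(variable = v, type = "continuous", smd = abs(smd),
                 test = "mann_whitney", p_value = p)
    } else if (is.logical(a) || length(unique(df[[v]])) <= 2L) {
      a <- as.logical(factor(a) == levels(factor(df[[v]]))[1])
      b <- as.logical(factor(b) == levels(factor(df[[v]]))[1])
      tab <- rbind(pre = c(yes = sum(a), no = sum(!a)),
                   post = c(yes = sum(b), no = sum(!b)))
      smd <- smd_binary(mean(a), mean(b))
      ct <- safe_contingency(tab)
      data.frame(variable = v, type = "binary", smd = abs(smd),
                 test = ct$test_used, p_value = ct$p_value)
    } else {
      levs <- sort(unique(df[[v]]))
      smds <- vapply(levs, function(lv)
        abs(smd_binary(mean(a == lv), mean(b == lv))), numeric(1))
      tab <- rbind(pre = table(factor(a, levels = levs)),
                   post = table(factor(b, levels = levs)))
      ct <- safe_contingency(tab)
      data.frame(variable = v, type = "categorical", smd = max(smds),
                 test = ct$test_used, p_value = ct$p_value)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
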