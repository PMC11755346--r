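# Score-based clinical stratification and survival statistics.
#
# The product-limit machinery (Kaplan-Meier with Greenwood variance,
# two-group log-rank, fixed-horizon rate z-test, IPCW time-dependent ROC) is
# implemented here; survival::survfit / survdiff serve as independent
# cross-checks in the test suite. The univariate Cox fit wraps
# survival::coxph with Breslow tie handling.

#' Median split of predicted scores
#'
#' Scores at or below the median go to `"low"`, the rest to `"high"` (ties
#' at the median therefore fall in the low group).
#'
#' @param scores Numeric vector, `n >= 2`, not all identical.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) abort("median_split needs at least 2 scores")
  if (length(unique(scores)) == 1) {
    abort("all scores are identical; no median split is possible")
  }
  med <- stats::median(scores)
  factor(ifelse(scores <= med, "low", "high"), levels = c("low", "high"))
}

#' Rank-sum (Mann-Whitney) comparison of two score groups
#'
#' Exact enumeration when `min(n, m) <= 8` and there are no ties; otherwise
#' the normal approximation with tie-corrected variance (and continuity
#' correction).
#'
#' @param a,b Numeric score vectors for the two groups (both non-empty).
#' @return One-row tibble: `u` (the U statistic of `a`), `p_value`,
#'   `exact`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = !exact))
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod(1 - d_i / n_i)` over event times up to `t`, with the
#' Greenwood variance `S(t)^2 * sum(d_i / (n_i * (n_i - d_i)))`.
#' Observations censored at `t` are still at risk at `t` (they leave the
#' risk set just after), the usual convention. Where `S(t)` hits zero the
#' Greenwood expression degenerates and the variance is reported `NA`.
#'
#' @param time Non-negative follow-up times (months).
#' @param event 1 = event, 0 = censored.
#' @return A `km_curve`: tibble `table` with one row per distinct observed
#'   time (`time`, `n_risk`, `n_event`, `n_censor`, `surv`, `var`, `se`)
#'   plus `n` and `max_time`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) != length(event) || length(time) == 0) {
    abort("time and event must be non-empty vectors of equal length")
  }
  if (any(!is.finite(time)) || any(time < 0)) abort("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) abort("event must be 0/1")

  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gterm <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), NA_real_)
  gsum <- cumsum(ifelse(is.na(gterm), 0, gterm))
  var <- surv^2 * gsum
  var[is.na(gterm) | surv == 0] <- NA_real_
  # censor-only times contribute nothing but stay in the table (at-risk audit)
  structure(list(
    table = tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                           n_censor = n_censor, surv = surv, var = var,
                           se = sqrt(var)),
    n = length(time),
    max_time = max(time)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d events, follow-up to %.3g\n",
              x$n, sum(x$table$n_event), x$max_time))
  print(x$table, n = 6)
  invisible(x)
}

# Step-function lookup of S (or any column) at time t; S(t) = 1 before the
# first observed time.
km_step <- function(curve, t, col = "surv", left = FALSE) {
  tab <- curve$table
  idx <- findInterval(t, tab$time, left.open = left)
  ifelse(idx == 0, if (col == "surv") 1 else 0, tab[[col]][pmax(idx, 1)])
}

#' Survival rate at a fixed horizon
#'
#' @param curve A [km_estimate()] curve.
#' @param t Horizon (same time units as the curve); must not exceed the
#'   curve's observed follow-up.
#' @return One-row tibble: `t`, `rate` (= S(t)), `se` (Greenwood).
#' @export
survival_rate_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  stopifnot_scalar_number(t, "t", min = 0)
  if (t > curve$max_time) {
    abort(sprintf("t = %g is beyond the curve's support (max follow-up %g)",
                  t, curve$max_time))
  }
  s <- km_step(curve, t)
  se <- km_step(curve, t, col = "se")
  if (length(se) == 1 && is.na(se) && s == 1) se <- 0
  tibble::tibble(t = t, rate = s, se = se)
}

#' Compare two fixed-horizon survival rates
#'
#' Greenwood-based z-test: `z = (S_A - S_B) / sqrt(se_A^2 + se_B^2)` with a
#' two-sided normal p-value. If `t` is beyond one curve's follow-up (but not
#' both) that curve contributes its last estimate, with a warning.
#'
#' @param curve_a,curve_b [km_estimate()] curves.
#' @param t Horizon.
#' @return One-row tibble: `t`, `rate_a`, `rate_b`, `z`, `p_value`.
#' @export
compare_rates <- function(curve_a, curve_b, t) {
  stopifnot_scalar_number(t, "t", min = 0)
  if (t > curve_a$max_time && t > curve_b$max_time) {
    abort(sprintf("t = %g is beyond both curves' support", t))
  }
  rate_of <- function(curve) {
    if (t > curve$max_time) {
      warn(sprintf("t = %g beyond one curve's follow-up (%g); using its last estimate",
                   t, curve$max_time))
      survival_rate_at(curve, curve$max_time)
    } else {
      survival_rate_at(curve, t)
    }
  }
  ra <- rate_of(curve_a)
  rb <- rate_of(curve_b)
  sed <- sqrt(ra$se^2 + rb$se^2)
  z <- if (isTRUE(all.equal(ra$rate, rb$rate))) 0
       else (ra$rate - rb$rate) / sed
  tibble::tibble(t = t, rate_a = ra$rate, rate_b = rb$rate, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank statistic from the
#' observed-minus-expected summation over the pooled event times.
#'
#' @param time,event Pooled follow-up data.
#' @param group Two-level group labels aligned with `time`.
#' @return One-row tibble: `chi2`, `p_value`, per-group observed and
#'   expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) abort("logrank_test requires exactly two groups")
  if (sum(event) == 0) abort("no events in either group")
  ut <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g == levels(g)[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == levels(g)[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - e1)^2 / v
  tibble::tibble(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 observed_1 = o1, expected_1 = e1)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson via `survival::coxph` with Breslow tie
#' handling; reports the hazard ratio with its Wald 95% interval and
#' p-value. Monotone-likelihood / non-convergence is surfaced through the
#' `flagged` column instead of silent numbers; a constant covariate is an
#' error (the coefficient is inestimable).
#'
#' @param time,event Follow-up data.
#' @param x Covariate (binary indicator or numeric score).
#' @param conf_level Wald interval coverage (default 0.95).
#' @return One-row tibble: `beta`, `hr`, `conf_low`, `conf_high`, `se`,
#'   `p_value`, `n`, `n_event`, `flagged`.
#' @export
cox_univariate <- function(time, event, x, conf_level = 0.95) {
  if (is.factor(x) || is.character(x)) {
    x <- as.integer(as.factor(x)) - 1L
  }
  if (length(unique(x)) < 2) {
    abort("covariate is constant: Cox coefficient is inestimable")
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 100) flagged <- TRUE
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(beta = beta, hr = exp(beta),
                 conf_low = exp(beta - zq * se), conf_high = exp(beta + zq * se),
                 se = se, p_value = 2 * stats::pnorm(-abs(beta / se)),
                 n = fit$n, n_event = fit$nevent, flagged = flagged)
}

#' Time-dependent ROC at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC: cases are subjects with an event
#' by the horizon, controls those still event-free past it. Censoring is
#' handled by inverse-probability-of-censoring weights from the Kaplan-Meier
#' estimate of the censoring distribution (cases weighted by `1/G(T-)`,
#' controls by `1/G(t)`), the cumulative/dynamic estimator that reduces
#' exactly to the Mann-Whitney AUC when no one is censored and satisfies
#' `AUC(score) + AUC(-score) = 1`. Higher scores are taken to predict the
#' event.
#'
#' @param scores Risk scores (higher = higher predicted risk).
#' @param time,event Follow-up data.
#' @param horizon Evaluation time; must lie within the observed follow-up.
#' @return A `ttrec_troc`: `horizon`, `auc`, the swept `curve`
#'   (`cutoff`, `sens`, `spec`), and the Youden-optimal operating point.
#' @export
td_roc <- function(scores, time, event, horizon) {
  n <- length(scores)
  if (length(time) != n || length(event) != n) abort("inputs must be aligned")
  stopifnot_scalar_number(horizon, "horizon", min = 0)
  if (horizon > max(time)) {
    abort(sprintf("horizon %g exceeds the observed follow-up (%g)", horizon, max(time)))
  }

  cens_km <- km_estimate(time, 1 - event)
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  if (!any(is_case)) abort("no cases (events by the horizon)")
  if (!any(is_ctrl)) abort("no controls (subjects past the horizon)")

  g_t <- km_step(cens_km, horizon)
  w <- numeric(n)
  w[is_case] <- 1 / km_step(cens_km, time[is_case], left = TRUE)
  w[is_ctrl] <- 1 / g_t
  if (any(!is.finite(w[is_case | is_ctrl]))) {
    abort("censoring-survival weight degenerate at the horizon")
  }

  case_scores <- scores[is_case]
  case_w <- w[is_case]
  ctrl_scores <- scores[is_ctrl]
  # weighted Mann-Whitney AUC (ties count 1/2)
  cmp <- outer(case_scores, ctrl_scores, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- sum(case_w * rowSums(cmp)) / (sum(case_w) * length(ctrl_scores))

  cutoffs <- sort(unique(scores))
  sens <- vapply(cutoffs, function(c) {
    sum(case_w[case_scores > c]) / sum(case_w)
  }, numeric(1))
  spec <- vapply(cutoffs, function(c) mean(ctrl_scores <= c), numeric(1))
  curve <- tibble::tibble(cutoff = cutoffs, sens = sens, spec = spec)
  youden <- curve[which.max(curve$sens + curve$spec - 1), ]

  structure(list(horizon = horizon, auc = auc, curve = curve, youden = youden,
                 n_case = sum(is_case), n_ctrl = sum(is_ctrl)),
            class = "ttrec_troc")
}

#' @export
print.ttrec_troc <- function(x, ...) {
  cat(sprintf("<ttrec_troc> horizon %g: AUC %.3f (%d cases / %d controls)\n",
              x$horizon, x$auc, x$n_case, x$n_ctrl))
  cat(sprintf("  Youden point: cutoff %.3g, sensitivity %.2f, specificity %.2f\n",
              x$youden$cutoff, x$youden$sens, x$youden$spec))
  invisible(x)
}

#' Score-stratified clinical survival report
#'
#' The full clinical read-out for a scored survival cohort: median split of
#' the predicted score, Kaplan-Meier curves per group, log-rank test,
#' univariate Cox hazard ratio for the low-score group (HR < 1 means lower
#' scores do better), fixed-horizon survival-rate comparisons, and
#' time-dependent ROC at each horizon. When a `bor` column (PD / non-PD) is
#' present the PD vs non-PD rank-sum score comparison is included.
#'
#' @param data Tibble with columns `time`, `event`, `score` (and optionally
#'   `bor`).
#' @param horizons Evaluation horizons in the time unit of `time`
#'   (default months 6 and 12).
#' @return A `ttrec_clinical` object.
#' @export
clinical_report <- function(data, horizons = c(6, 12)) {
  need <- c("time", "event", "score")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("clinical_report: missing column(s) %s", paste(missing, collapse = ", ")))
  }
  grp <- median_split(data$score)
  km <- list(low = km_estimate(data$time[grp == "low"], data$event[grp == "low"]),
             high = km_estimate(data$time[grp == "high"], data$event[grp == "high"]))
  lr <- logrank_test(data$time, data$event, grp)
  cox <- cox_univariate(data$time, data$event, as.integer(grp == "low"))
  rates <- dplyr::bind_rows(lapply(horizons, function(h) {
    tryCatch(compare_rates(km$low, km$high, h),
             error = function(e) tibble::tibble(t = h, rate_a = NA_real_,
                                                rate_b = NA_real_, z = NA_real_,
                                                p_value = NA_real_))
  }))
  names(rates)[names(rates) == "rate_a"] <- "rate_low"
  names(rates)[names(rates) == "rate_b"] <- "rate_high"
  troc <- lapply(horizons, function(h) {
    tryCatch(td_roc(data$score, data$time, data$event, h),
             error = function(e) NULL)
  })
  names(troc) <- paste0("t", horizons)
  ranksum <- NULL
  if ("bor" %in% names(data)) {
    pd <- data$bor %in% c("PD", 1)
    if (any(pd) && any(!pd)) {
      ranksum <- rank_sum_test(data$score[pd], data$score[!pd])
    }
  }
  structure(list(groups = grp, km = km, logrank = lr, cox = cox, rates = rates,
                 troc = troc, ranksum = ranksum, horizons = horizons,
                 data = tibble::as_tibble(data)),
            class = "ttrec_clinical")
}

#' @export
print.ttrec_clinical <- function(x, ...) {
  cat(sprintf("<ttrec_clinical> %d patients (low %d / high %d), %d events\n",
              length(x$groups), sum(x$groups == "low"), sum(x$groups == "high"),
              sum(x$data$event)))
  cat(sprintf("  log-rank chi2 = %.3f (p = %.3g); HR(low vs high) = %.3f [%.2f, %.2f]\n",
              x$logrank$chi2, x$logrank$p_value, x$cox$hr, x$cox$conf_low,
              x$cox$conf_high))
  for (i in seq_len(nrow(x$rates))) {
    r <- x$rates[i, ]
    cat(sprintf("  %g-month rate: low %.4f vs high %.4f (p = %.3g)\n",
                r$t, r$rate_low, r$rate_high, r$p_value))
  }
  for (tr in x$troc) {
    if (!is.null(tr)) cat(sprintf("  AUC at %g months: %.3f\n", tr$horizon, tr$auc))
  }
  invisible(x)
}
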