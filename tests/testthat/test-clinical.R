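# Survival statistics: median split, rank-sum, Kaplan-Meier, log-rank,
# Cox, fixed-horizon rates, time-dependent ROC.

test_that("median split sends ties at the median to the low group", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(1, 2, 2, 4))),
               c("low", "low", "low", "high"))
  expect_equal(as.character(median_split(c(1, 2, 3))), c("low", "low", "high"))
  expect_error(median_split(rep(3, 4)), "identical")
})

test_that("rank-sum test: exact enumeration oracle and the U identity", {
  # complete separation at n = m = 3: enumerate all 20 assignments
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  combos <- utils::combn(6, 3)
  u_of <- function(ranks_a) sum(ranks_a) - 3 * 4 / 2
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(1:3)
  p_exact <- mean(us <= u_obs | us >= (9 - u_obs))  # two-sided, U_max = nm = 9
  expect_true(rs$exact)
  expect_equal(rs$p_value, p_exact)
  expect_equal(rs$p_value, 0.1)

  # U_a + U_b = n * m
  withr::with_seed(5, {
    a <- rnorm(12)
    b <- rnorm(9)
  })
  expect_equal(rank_sum_test(a, b)$u + rank_sum_test(b, a)$u, 12 * 9)

  # identical samples: p near 1
  expect_gt(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 0.9)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  # no censoring: 1 - ECDF
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))

  # all censored: S identically 1
  kmc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(kmc$table$surv, c(1, 1, 1))

  # worked censored example: events at 1, 3, 4; censored at 2
  km2 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(survival_rate_at(km2, 3)$rate, (3 / 4) * (1 / 2))
  expect_equal(survival_rate_at(km2, 3)$rate, 0.375)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("KM survival and Greenwood SE agree with survival::survfit", {
  withr::with_seed(17, {
    time <- round(rexp(60, 0.1), 2)
    event <- rbinom(60, 1, 0.7)
  })
  km <- km_estimate(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, error = "greenwood")
  sm <- summary(sf, times = km$table$time)
  expect_equal(km$table$surv, sm$surv, tolerance = 1e-12)
  # survfit reports the SE of S(t) directly
  expect_equal(km$table$se[!is.na(km$table$se)],
               sm$std.err[!is.na(km$table$se)], tolerance = 1e-10)

  # row order invariance
  perm <- sample(length(time))
  km_p <- km_estimate(time[perm], event[perm])
  expect_equal(km_p$table, km$table)
})

test_that("fixed-horizon rates behave at the boundaries and compare correctly", {
  km <- km_estimate(c(5, 8, 12), c(1, 1, 1))
  expect_equal(survival_rate_at(km, 2)$rate, 1)   # before the first event
  expect_equal(survival_rate_at(km, 2)$se, 0)
  expect_error(survival_rate_at(km, 20), "support")

  # identical curves: z = 0, p = 1
  a <- km_estimate(c(2, 4, 6, 9), c(1, 0, 1, 1))
  expect_equal(compare_rates(a, a, 5)$z, 0)
  expect_equal(compare_rates(a, a, 5)$p_value, 1)
  expect_error(compare_rates(a, a, 50), "both curves")

  # direct arithmetic: S_A = 1 (se 0) vs S_B = 0.5 (se 0.25) -> z = 2
  mock <- function(surv, se, t = 10) {
    structure(list(table = tibble::tibble(time = 1, n_risk = 10, n_event = 1,
                                          n_censor = 0, surv = surv,
                                          var = se^2, se = se),
                   n = 10, max_time = t), class = "km_curve")
  }
  cmp <- compare_rates(mock(1, 0), mock(0.5, 0.25), 5)
  expect_equal(cmp$z, 2)
  expect_equal(cmp$p_value, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(cmp$p_value, 0.0455, tolerance = 1e-3)
})

test_that("log-rank equals the explicit observed-minus-expected summation", {
  # A: events at 1, 3; B: events at 2, 4; no censoring
  time <- c(1, 3, 2, 4)
  event <- c(1, 1, 1, 1)
  group <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, group)
  # hand summation over the four event times
  o1 <- e1 <- v <- 0
  for (t in c(1, 2, 3, 4)) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == "A")
    d <- 1
    o1 <- o1 + as.integer(t %in% c(1, 3))
    e1 <- e1 + n1 / n
    if (n > 1) v <- v + (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chi2, (o1 - e1)^2 / v)

  # cross-check against survival::survdiff on a random dataset
  withr::with_seed(19, {
    tt <- rexp(80, 0.2)
    ee <- rbinom(80, 1, 0.8)
    gg <- rep(c("x", "y"), 40)
  })
  sd_fit <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(logrank_test(tt, ee, gg)$chi2, sd_fit$chisq, tolerance = 1e-10)

  # rank invariance: scaling time leaves the statistic unchanged
  expect_equal(logrank_test(tt * 7, ee, gg)$chi2,
               logrank_test(tt, ee, gg)$chi2)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "events")
})

test_that("the univariate Cox fit is flagged or errors on degenerate input", {
  expect_error(cox_univariate(c(1, 2, 3), c(1, 1, 0), c(1, 1, 1)), "inestimable")
  withr::with_seed(23, {
    x <- rbinom(100, 1, 0.5)
    time <- rexp(100, 0.1 * exp(0.6 * x))
    event <- rep(1L, 100)
  })
  fit <- cox_univariate(time, event, x)
  expect_false(fit$flagged)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$conf_low < fit$hr && fit$hr < fit$conf_high)

  # rank invariance of beta under a strictly monotone time transform
  fit3 <- cox_univariate(time^3, event, x)
  expect_equal(fit3$beta, fit$beta, tolerance = 1e-3)
})

test_that("Cox coefficient is centered at zero under the null", {
  withr::with_seed(29, {
    betas <- vapply(1:40, function(i) {
      x <- rbinom(150, 1, 0.5)
      time <- rexp(150, 0.1)
      cox_univariate(time, rep(1L, 150), x)$beta
    }, numeric(1))
  })
  expect_lt(abs(mean(betas)), 0.08)
})

test_that("time-dependent ROC reduces to the Mann-Whitney AUC and is symmetric", {
  # perfect ranking, no censoring
  time <- c(1, 2, 3, 10, 11, 12)
  event <- rep(1L, 6)
  scores <- c(9, 8, 7, 1, 2, 3)
  expect_equal(td_roc(scores, time, event, 5)$auc, 1)

  # no censoring: equals the binary Mann-Whitney AUC at the horizon
  withr::with_seed(31, {
    n <- 120
    tt <- rexp(n, 0.15)
    sc <- -tt + rnorm(n, 0, 2)
  })
  horizon <- stats::median(tt)
  tr <- td_roc(sc, tt, rep(1L, n), horizon)
  case <- tt <= horizon
  mw <- mean(outer(sc[case], sc[!case], function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(tr$auc, mw, tolerance = 1e-12)

  # with censoring: AUC(score) + AUC(-score) = 1 exactly
  withr::with_seed(37, {
    ev <- rbinom(n, 1, 0.6)
  })
  t1 <- td_roc(sc, tt, ev, horizon)
  t2 <- td_roc(-sc, tt, ev, horizon)
  expect_equal(t1$auc + t2$auc, 1, tolerance = 1e-12)
  expect_true(all(t1$curve$sens >= 0 & t1$curve$sens <= 1))
  expect_true(all(t1$curve$spec >= 0 & t1$curve$spec <= 1))

  expect_error(td_roc(sc, tt, ev, max(tt) + 1), "follow-up")
  expect_error(td_roc(sc, tt, rep(0L, n), horizon), "no cases")
})

test_that("the clinical report assembles all components coherently", {
  co <- small_cohort()
  surv <- co$survival
  surv$bor <- co$bor$value
  rep <- clinical_report(surv, horizons = c(6, 12))
  expect_s3_class(rep, "ttrec_clinical")
  expect_equal(length(rep$groups), nrow(surv))
  expect_equal(nrow(rep$rates), 2)
  td <- tidy(rep)
  expect_true(all(c("logrank_chi2", "hr_low_vs_high") %in% td$statistic))
  expect_true(any(grepl("^auc_", td$statistic)))
  expect_error(clinical_report(surv[, c("time", "event")]), "score")
})
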