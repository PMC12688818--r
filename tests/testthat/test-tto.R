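test_that("onset intervals use the inclusive-day convention", {
  reports <- make_reports(
    list("X", "X", "X"),
    is_target = rep(TRUE, 3),
    event_dt = c("20240101", "20240103", "20231230"),
    start_dt = c("20240101", "20240101", "20240101")
  )
  tto <- extract_tto(reports)
  expect_equal(tto$samples$tto_days, c(1L, 3L))
  expect_equal(tto$exclusions$reason, "event precedes start")
  expect_equal(tto$exclusions$n, 1L)
})

test_that("missing, partial and invalid dates are excluded and tallied", {
  reports <- make_reports(
    rep(list("X"), 5),
    is_target = rep(TRUE, 5),
    event_dt = c("", "202401", "20240105", "20240105", "20241350"),
    start_dt = c("20240101", "20240101", "", "2024", "20240101")
  )
  tto <- extract_tto(reports)
  expect_equal(nrow(tto$samples), 0)
  expect_equal(sum(tto$exclusions$n), 5)
  expect_setequal(tto$exclusions$reason,
                  c("missing event date", "partial or invalid event date",
                    "missing start date", "partial or invalid start date"))
})

test_that("the Weibull fit recovers known parameters and special cases", {
  set.seed(123)
  x <- rweibull(5000, shape = 0.63, scale = 4.46)
  fit <- weibull_tto_fit(x)
  expect_gt(fit$beta, 0.60); expect_lt(fit$beta, 0.66)
  expect_gt(fit$alpha, 4.2); expect_lt(fit$alpha, 4.7)
  expect_equal(fit$failure_type, "early failure")
  expect_lt(fit$beta_ci[1], fit$beta)
  expect_gt(fit$beta_ci[2], fit$beta)

  # exponential data: the shape CI must cover 1
  y <- rexp(5000, rate = 1 / 3)
  fe <- weibull_tto_fit(y)
  expect_lt(fe$beta_ci[1], 1)
  expect_gt(fe$beta_ci[2], 1)
  expect_equal(fe$failure_type, "random failure")

  expect_warning(weibull_tto_fit(c(1, 4, 9)), "unstable")
  expect_error(weibull_tto_fit(rep(2, 20)), "degenerate")
})

test_that("likelihood at the MLE beats moment-style starting values", {
  set.seed(5)
  x <- rweibull(400, 0.8, 3)
  fit <- weibull_tto_fit(x)
  ll <- function(shape, scale) sum(dweibull(x, shape, scale, log = TRUE))
  # crude moment starts: exponential with the sample mean, and a
  # lognormal-motivated guess
  expect_gte(fit$loglik, ll(1, mean(x)))
  expect_gte(fit$loglik, ll(1.2, median(x) / log(2)^(1 / 1.2)))
})

test_that("bootstrap intervals are reproducible and bracket the estimate", {
  set.seed(77)
  x <- rweibull(80, 0.7, 4)
  f1 <- weibull_tto_fit(x, ci = "bootstrap", boot_n = 200, boot_seed = 9)
  f2 <- weibull_tto_fit(x, ci = "bootstrap", boot_n = 200, boot_seed = 9)
  expect_equal(f1$beta_ci, f2$beta_ci)
  expect_lt(f1$beta_ci[1], f1$beta)
  expect_gt(f1$beta_ci[2], f1$beta)
})

test_that("failure types follow the shape-parameter CI rule", {
  expect_equal(classify_failure_type(0.63, c(0.56, 0.70)), "early failure")
  expect_equal(classify_failure_type(1.0, c(0.9, 1.1)), "random failure")
  expect_equal(classify_failure_type(1.6, c(1.2, 2.1)), "wear-out failure")
})

test_that("the KM estimator equals the empirical CDF without censoring", {
  km <- km_curve(c(1, 1, 2, 4))
  expect_equal(km$time, c(1, 2, 4))
  expect_equal(km$cuminc, c(0.5, 0.75, 1.0))
  expect_equal(km$n_risk, c(4, 2, 1))
  single <- km_curve(3)
  expect_equal(single$cuminc, 1)
  set.seed(2)
  x <- sample(1:30, 200, replace = TRUE)
  km2 <- km_curve(x)
  expect_true(all(diff(km2$cuminc) > 0))
  expect_equal(km2$cuminc, ecdf(x)(km2$time))
  expect_equal(max(km2$cuminc), 1)
})

test_that("the log-rank statistic matches a hand computation", {
  # groups A = {1, 3, 5}, B = {2, 3, 8}: tabulate observed minus expected
  # deaths in A at each distinct event time under the hypergeometric model
  a <- c(1, 3, 5); b <- c(2, 3, 8)
  times <- sort(unique(c(a, b)))
  o_minus_e <- 0; v <- 0
  at_risk_a <- length(a); at_risk_b <- length(b)
  for (t in times) {
    da <- sum(a == t); db <- sum(b == t)
    n_ <- at_risk_a + at_risk_b; d_ <- da + db
    o_minus_e <- o_minus_e + (da - d_ * at_risk_a / n_)
    if (n_ > 1) {
      v <- v + d_ * (at_risk_a / n_) * (at_risk_b / n_) * (n_ - d_) / (n_ - 1)
    }
    at_risk_a <- at_risk_a - da; at_risk_b <- at_risk_b - db
  }
  manual <- o_minus_e^2 / v
  got <- logrank_test(a, b)
  expect_equal(got$statistic, manual, tolerance = 1e-10)
  expect_equal(got$df, 1)

  same <- logrank_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(logrank_test(numeric(0), c(1)), "non-empty")
})

test_that("sex-stratified onset analysis mirrors the summary-table layout", {
  set.seed(11)
  n <- 400
  sex <- sample(c("F", "M", NA), n, replace = TRUE, prob = c(0.45, 0.45, 0.1))
  tto <- ifelse(!is.na(sex) & sex == "F",
                ceiling(rweibull(n, 0.58, 6.78)),
                ceiling(rweibull(n, 0.78, 2.95)))
  samples <- tibble::tibble(primaryid = seq_len(n), tto_days = tto, sex = sex)
  res <- tto_analysis(samples)
  expect_setequal(res$summary$stratum, c("all", "F", "M"))
  expect_equal(res$summary$n[res$summary$stratum == "all"], n)
  expect_true(all(res$summary$alpha_lo <= res$summary$alpha))
  expect_true(all(res$summary$beta_hi >= res$summary$beta))
  expect_s3_class(res$km, "km_curve")
  expect_false(is.null(res$logrank))
  # median/IQR come from inclusive (Tukey) quartiles
  f_tto <- samples$tto_days[!is.na(sex) & sex == "F"]
  fn <- fivenum(f_tto)
  expect_equal(res$summary$median[res$summary$stratum == "F"], fn[3])
  expect_equal(res$summary$iqr_low[res$summary$stratum == "F"], fn[2])
})
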