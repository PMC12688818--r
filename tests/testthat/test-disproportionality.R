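test_that("contingency cells match an exhaustive recount on a toy corpus", {
  # 4 reports: target in 2, term X in 1 target + 1 non-target report
  reports <- make_reports(
    list("X", "Y", c("X", "Y"), "Y"),
    is_target = c(TRUE, TRUE, FALSE, FALSE)
  )
  tabs <- build_contingency_tables(reports)
  x <- tabs[tabs$term == "X", ]
  expect_equal(unlist(x[, c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  y <- tabs[tabs$term == "Y", ]
  expect_equal(unlist(y[, c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 2, d = 0))
  expect_true(all(tabs$n == 4))
})

test_that("brute-force recount agrees on generated corpora", {
  for (seed in c(1, 2)) {
    cfg <- generator_config(n_reports = 150, target_drug_fraction = 0.3,
                            seed = seed)
    rep <- generate_faers(cfg)$reports
    tabs <- build_contingency_tables(rep)
    # independent recount: loop over reports and terms
    for (term in sample(tabs$term, 5)) {
      has <- purrr::map_lgl(rep$events, ~ term %in% .x)
      expect_equal(tabs$a[tabs$term == term], sum(has & rep$is_target))
      expect_equal(tabs$c[tabs$term == term], sum(has & !rep$is_target))
    }
  }
})

test_that("a report counts once per term even with repeated REAC rows", {
  reports <- make_reports(list(c("X", "X", "Y")), TRUE)
  tabs <- build_contingency_tables(reports)
  expect_equal(tabs$a[tabs$term == "X"], 1)
})

test_that("an empty stratum yields an empty result with a warning", {
  reports <- make_reports(list("X"), TRUE, sex = "M")
  expect_warning(tabs <- build_contingency_tables(reports, stratum = "F"),
                 "no reports")
  expect_equal(nrow(tabs), 0)
})

test_that("ROR matches the closed form and its oracle values", {
  expect_equal(ror_stats(25, 25, 25, 25)$ror, 1)
  o <- oracle_2x2(10, 90, 100, 9900)
  got <- ror_stats(10, 90, 100, 9900)
  expect_equal(got$ror, 11)
  expect_equal(o$ror_lo, 5.56, tolerance = 1e-3)
  expect_equal(o$ror_hi, 21.76, tolerance = 1e-3)
  expect_equal(got$ror_lo, o$ror_lo, tolerance = 1e-4)
  expect_equal(got$ror_hi, o$ror_hi, tolerance = 1e-4)
  # zero cell: +0.5 on all four cells
  z <- ror_stats(0, 10, 5, 100)
  expect_equal(z$ror, (0.5 * 100.5) / (10.5 * 5.5))
  # correction disabled: an undefined-result marker, not an exception
  expect_true(is.na(ror_stats(0, 10, 5, 100, correct = FALSE)$ror))
})

test_that("PRR and chi-squared match the closed form and its oracle values", {
  flat <- prr_chi2(25, 25, 25, 25)
  expect_equal(flat$prr, 1)
  expect_equal(flat$chi2, 0)
  o <- oracle_2x2(10, 90, 100, 9900)
  got <- prr_chi2(10, 90, 100, 9900)
  expect_equal(got$prr, 10)
  expect_equal(o$chi2_yates, 66.33, tolerance = 1e-3)
  expect_equal(got$chi2, o$chi2_yates, tolerance = 1e-8)
  raw <- prr_chi2(10, 90, 100, 9900, yates = FALSE)
  expect_equal(o$chi2_raw, 74.45, tolerance = 1e-3)
  expect_equal(raw$chi2, o$chi2_raw, tolerance = 1e-8)
  # corrected zero-a table stays finite with PRR below 1
  z <- prr_chi2(0, 10, 50, 100)
  expect_true(is.finite(z$prr) && z$prr < 1)
})

test_that("the information component matches its closed form", {
  # a equal to its expectation gives IC = 0 exactly
  expect_equal(bcpnn_ic(25, 25, 25, 25)$ic, 0)
  o <- oracle_2x2(10, 90, 100, 9900)
  got <- bcpnn_ic(10, 90, 100, 9900)
  expect_equal(o$e, 1.0891, tolerance = 1e-4)
  expect_equal(o$ic, 2.724, tolerance = 1e-3)
  expect_equal(o$ic025, 1.647, tolerance = 1e-3)
  expect_equal(got$ic, o$ic)
  expect_equal(got$ic025, o$ic025)
  # shrinkage keeps a zero count finite
  expect_true(is.finite(bcpnn_ic(0, 100, 50, 9850)$ic025))
})

test_that("the joint criterion requires all four algorithms plus N >= 3", {
  base <- tibble::tibble(
    term = "t", a = 10, b = 90, c = 100, d = 9900, n = 10100,
    level = "PT", stratum = "all",
    ror = 11, ror_lo = 5.6, ror_hi = 21.8, prr = 10, chi2 = 66,
    ic = 2.7, ic025 = 1.6, e_count = 1.09, ebgm = 8, ebgm05 = 4
  )
  expect_true(screen_signals(base)$significant)
  fail_ic <- dplyr::mutate(base, ic025 = -0.1)
  expect_false(screen_signals(fail_ic)$significant)
  small_n <- dplyr::mutate(base, a = 2)
  expect_false(screen_signals(small_n)$significant)
  # thresholds are configurable and the EBGM criterion can target EBGM05
  expect_false(screen_signals(base, signal_thresholds(min_n = 50))$significant)
  strict <- signal_thresholds(ebgm = 5, ebgm_stat = "ebgm05")
  expect_false(screen_signals(base, strict)$significant)
})

test_that("ROR and PRR agree in the rare-event limit", {
  set.seed(4)
  for (i in 1:20) {
    n_t <- sample(500:5000, 1)
    n_c <- sample(50000:200000, 1)
    a <- rbinom(1, n_t, 0.008) + 1
    c_ <- rbinom(1, n_c, 0.008) + 1
    r <- ror_stats(a, n_t - a, c_, n_c - c_)$ror
    p <- prr_chi2(a, n_t - a, c_, n_c - c_)$prr
    expect_lt(abs(log(r) - log(p)), 0.05)
  }
})

test_that("all four statistics are non-decreasing in a with b, c, d fixed", {
  b <- 200; c_ <- 150; d <- 20000
  a <- 1:60
  tabs <- tibble::tibble(term = as.character(a), a = a, b = b, c = c_, d = d,
                         n = a + b + c_ + d, level = "PT", stratum = "all")
  res <- suppressWarnings(signal_stats(tabs))
  expect_true(all(diff(res$ror) > 0))
  expect_true(all(diff(res$prr) > 0))
  expect_true(all(diff(res$ic) > 0))
  expect_true(all(diff(res$ebgm) > -1e-10))
})

test_that("the ROR Wald interval achieves nominal coverage", {
  set.seed(7)
  true_or <- 3
  p0 <- 0.02
  p1 <- plogis(qlogis(p0) + log(true_or))
  n1 <- 500; n0 <- 5000
  a <- rbinom(1000, n1, p1)
  c_ <- rbinom(1000, n0, p0)
  ci <- ror_stats(a, n1 - a, c_, n0 - c_)
  covered <- mean(ci$ror_lo < true_or & true_or < ci$ror_hi, na.rm = TRUE)
  # binomial MC error at 1000 reps is about 0.7%
  expect_gt(covered, 0.92)
  expect_lt(covered, 0.98)
})

test_that("sex-stratified screening restricts background to the stratum", {
  # mirrored corpus: identical report sets for F and M
  ev <- list("X", "Y", c("X", "Y"), "Y")
  tg <- c(TRUE, TRUE, FALSE, FALSE)
  reports <- dplyr::bind_rows(
    make_reports(ev, tg, sex = rep("F", 4)),
    make_reports(ev, tg, sex = rep("M", 4)),
    make_reports(list("X"), TRUE, sex = NA_character_)
  )
  reports$caseid <- seq_len(nrow(reports))
  reports$primaryid <- reports$caseid * 10L + 1L
  f <- build_contingency_tables(reports, stratum = "F")
  m <- build_contingency_tables(reports, stratum = "M")
  expect_equal(f[, c("term", "a", "b", "c", "d")],
               m[, c("term", "a", "b", "c", "d")])
  # the missing-sex report is excluded from both strata
  expect_equal(sum(f$n) / nrow(f), 4)
})

test_that("a female-only planted signal is flagged in females only", {
  cfg <- generator_config(
    n_reports = 30000, target_drug_fraction = 0.02,
    signal_multipliers_by_sex = list(F = c("Phrenic nerve paralysis" = 8)),
    duplicate_fraction = 0, seed = 31
  )
  gen <- generate_faers(cfg)
  res <- suppressWarnings(
    disproportionality(gen$reports, strata = c("F", "M"))
  )
  pnp <- res[res$term == "Phrenic nerve paralysis", ]
  expect_true(pnp$significant[pnp$stratum == "F"])
  expect_false(pnp$significant[pnp$stratum == "M"])
})
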