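test_that("generator config validates its inputs", {
  expect_error(generator_config(n_reports = 0), "n_reports")
  expect_error(generator_config(missing_sex_p = 1.2), "probability")
  expect_error(generator_config(tto_shape = -1), "positive")
  expect_error(generator_config(signal_multipliers = c(NotATerm = 5)),
               "outside the vocabulary")
  bad_vocab <- tibble::tibble(pt = c("A", "B"), prob = c(-1, 0.5))
  expect_error(generator_config(pt_vocabulary = bad_vocab), "normalizable")
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- generator_config(n_reports = 300, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_faers_tables(generate_faers(cfg), d1)
  p2 <- write_faers_tables(generate_faers(cfg), d2)
  expect_equal(basename(p1), basename(p2))
  h1 <- unname(tools::md5sum(sort(p1)))
  h2 <- unname(tools::md5sum(sort(p2)))
  expect_identical(h1, h2)
})

test_that("quarterly files follow the FAERS dialect and naming", {
  cfg <- generator_config(n_reports = 50, quarters = c("23Q4", "24Q1"),
                          seed = 3)
  d <- withr::local_tempdir()
  gen <- generate_faers(cfg, dir = d)
  files <- list.files(d)
  expect_true(any(grepl("^DEMO23Q4\\.txt$", files)))
  expect_true(any(grepl("^REAC24Q1\\.txt$", files)))
  expect_true("truth_table.tsv" %in% files)
  hdr <- readLines(file.path(d, grep("^DEMO", files, value = TRUE)[1], fsep = "/"), n = 1)
  expect_true(grepl("\\$", hdr))
  expect_equal(strsplit(hdr, "\\$")[[1]][1:3], c("primaryid", "caseid", "fda_dt"))
})

test_that("with no planted signal every term's expected ROR is exactly 1", {
  cfg <- generator_config(n_reports = 1000, seed = 5)
  gen <- generate_faers(cfg)
  expect_true(all(gen$truth$lambda == 1))
  expect_equal(gen$truth$expected_ror, rep(1, nrow(gen$truth)),
               tolerance = 1e-12)
  expect_true(all(gen$truth$expected_a >= 0 & gen$truth$expected_c >= 0))
  expect_equal(gen$truth$expected_a + gen$truth$expected_b,
               rep(cfg$n_reports * cfg$target_drug_fraction, nrow(gen$truth)))
})

test_that("a planted tenfold signal is recovered inside the ROR interval", {
  cfg <- generator_config(
    n_reports = 50000, target_drug_fraction = 0.004,
    signal_multipliers = c("Phrenic nerve paralysis" = 10),
    duplicate_fraction = 0, seed = 99
  )
  gen <- generate_faers(cfg)
  tabs <- build_contingency_tables(gen$reports)
  res <- ror_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  i <- which(tabs$term == "Phrenic nerve paralysis")
  truth_ror <- gen$truth$expected_ror[
    gen$truth$pt == "Phrenic nerve paralysis"]
  expect_gt(res$ror_hi[i], 10)
  expect_lt(res$ror_lo[i], 10)
  expect_gt(res$ror_hi[i], truth_ror)
  expect_lt(res$ror_lo[i], truth_ror)
})

test_that("median a/E across replicate corpora recovers planted multipliers", {
  # compensated multipliers keep the target stratum's total event mass at 1,
  # isolating each planted term's relative rate from renormalisation
  v <- default_pt_vocabulary()
  pm <- stats::setNames(v$prob, v$pt)
  planted <- c("Phrenic nerve paralysis" = 10,
               "Local anaesthetic systemic toxicity" = 5,
               "Anaesthetic complication" = 2)
  extra <- sum((planted - 1) * pm[names(planted)])
  comp <- 1 - extra / sum(pm[v$pt[1:5]])
  mult <- c(planted, stats::setNames(rep(comp, 5), v$pt[1:5]))
  runs <- purrr::map_dfr(1:50, function(r) {
    cfg <- generator_config(n_reports = 50000, target_drug_fraction = 0.004,
                            signal_multipliers = mult,
                            duplicate_fraction = 0, seed = 2025 + r)
    gen <- generate_faers(cfg)
    tabs <- build_contingency_tables(gen$reports)
    tabs |>
      dplyr::filter(term %in% names(planted)) |>
      dplyr::mutate(aE = a / ((a + b) * (a + c) / n), run = r)
  })
  med <- runs |>
    dplyr::mutate(lambda = planted[term]) |>
    dplyr::group_by(lambda) |>
    dplyr::summarise(aE = median(aE))
  expect_equal(nrow(med), 3)
  expect_true(all(abs(med$aE - med$lambda) / med$lambda < 0.15))
})

test_that("the demographic fixture reproduces the published marginal counts", {
  fx <- make_table1_fixture()
  expect_equal(nrow(fx), 1463)
  expect_equal(sum(fx$sex == "F", na.rm = TRUE), 748)
  expect_equal(sum(fx$sex == "M", na.rm = TRUE), 444)
  expect_equal(sum(is.na(fx$sex)), 271)
  expect_equal(sum(purrr::map_lgl(fx$outcomes, ~ "HO" %in% .x)), 313)
  expect_equal(sum(is.na(fx$weight_kg)), 1015)
  expect_equal(sum(fx$reporter_code %in% c("HP", "MD", "OT", "PH")), 1327)
})

test_that("onset intervals follow the configured Weibull distribution", {
  cfg <- generator_config(n_reports = 4000, missing_date_p = 0,
                          duplicate_fraction = 0, target_drug_fraction = 1,
                          seed = 21)
  gen <- generate_faers(cfg)
  tto <- extract_tto(gen$reports)
  expect_gte(min(tto$samples$tto_days), 1)
  # ceil(Weibull) intervals: compare the empirical CDF at a few support
  # points with the discretised model CDF
  p_model <- pweibull(c(1, 2, 5, 10), shape = 0.63, scale = 4.46)
  p_obs <- purrr::map_dbl(c(1, 2, 5, 10),
                          ~ mean(tto$samples$tto_days <= .x))
  expect_equal(p_obs, p_model, tolerance = 0.05)
})
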