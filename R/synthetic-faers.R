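#' Default preferred-term vocabulary for the synthetic generator
#'
#' Thirty anaesthesia-flavoured MedDRA-like preferred terms with background
#' reporting probabilities. Probabilities are normalised to sum to 1; rare
#' terms (background probability below 1%) are the natural place to plant
#' signal multipliers.
#'
#' @return A tibble with columns `pt` and `prob`.
#' @export
default_pt_vocabulary <- function() {
  tibble::tibble(
    pt = c(
      "Nausea", "Headache", "Dizziness", "Vomiting", "Pruritus",
      "Hypotension", "Pyrexia", "Rash", "Somnolence", "Paraesthesia",
      "Injection site pain", "Dyspnoea", "Back pain", "Hypoaesthesia",
      "Tachycardia", "Bradycardia", "Urticaria", "Tremor",
      "Confusional state", "Muscular weakness", "Seizure",
      "Anaphylactic shock", "Sinus tachycardia", "Cardiac arrest",
      "Ventricular fibrillation", "Monoplegia", "Neurotoxicity",
      "Anaesthetic complication", "Local anaesthetic systemic toxicity",
      "Phrenic nerve paralysis"
    ),
    prob = c(
      0.085, 0.080, 0.075, 0.070, 0.060,
      0.055, 0.050, 0.050, 0.045, 0.042,
      0.040, 0.038, 0.036, 0.034,
      0.032, 0.030, 0.028, 0.026,
      0.024, 0.022, 0.020,
      0.016, 0.014, 0.012,
      0.010, 0.009, 0.008,
      0.007, 0.006, 0.005
    ) / sum(c(
      0.085, 0.080, 0.075, 0.070, 0.060,
      0.055, 0.050, 0.050, 0.045, 0.042,
      0.040, 0.038, 0.036, 0.034,
      0.032, 0.030, 0.028, 0.026,
      0.024, 0.022, 0.020,
      0.016, 0.014, 0.012,
      0.010, 0.009, 0.008,
      0.007, 0.006, 0.005
    ))
  )
}

#' Configuration for the synthetic FAERS generator
#'
#' Bundles and validates every knob of the report generator. The defaults
#' emulate the demographic structure of a real local-anaesthetic safety
#' corpus: sex/age/weight/date missingness at the proportions observed in
#' spontaneous reports (18.52%, 34.59%, 69.38%, and 91.3% of onset-date
#' pairs unusable), a female:male split of 748:444 among reports with known
#' sex, and Weibull(shape 0.63, scale 4.46) onset times in days.
#'
#' @param n_reports number of unique cases to generate.
#' @param target_drug_fraction probability that a case's primary suspect is
#'   the target drug.
#' @param pt_vocabulary tibble with columns `pt`, `prob` (background
#'   multinomial over event terms; `prob` is normalised if needed).
#' @param signal_multipliers named numeric vector mapping a preferred term
#'   to a relative reporting-rate multiplier `lambda >= 0` applied to
#'   target-drug reports. Terms not named get `lambda = 1`.
#' @param signal_multipliers_by_sex optional list with elements `F` and/or
#'   `M`, each a named multiplier vector overriding `signal_multipliers`
#'   for target-drug reports of that sex (reports with missing sex use
#'   `signal_multipliers`).
#' @param duplicate_fraction probability a case gains 1-2 extra report
#'   versions (same CASEID, later FDA_DT or higher PRIMARYID).
#' @param tto_shape,tto_scale Weibull shape/scale of the onset interval in
#'   days.
#' @param missing_sex_p,missing_age_p,missing_weight_p,missing_date_p
#'   missingness probabilities; `missing_date_p` is the probability that a
#'   report's onset-date pair is degraded (blank or truncated to YYYYMM)
#'   and therefore unusable for time-to-onset.
#' @param events_per_report_mean mean of the Poisson part of the per-report
#'   event count (count ~ Poisson(mean) + 1).
#' @param quarters character vector of quarter labels (`"24Q1"` style);
#'   cases are spread uniformly across them.
#' @param target_drug_name drug name written for target-drug rows; brand
#'   variants with strength suffixes are mixed in to exercise substring
#'   matching.
#' @param seed integer random seed; identical config + seed reproduces the
#'   output byte for byte.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_reports = 5000,
                             target_drug_fraction = 0.05,
                             pt_vocabulary = default_pt_vocabulary(),
                             signal_multipliers = NULL,
                             signal_multipliers_by_sex = NULL,
                             duplicate_fraction = 0.10,
                             tto_shape = 0.63,
                             tto_scale = 4.46,
                             missing_sex_p = 0.1852,
                             missing_age_p = 0.3459,
                             missing_weight_p = 0.6938,
                             missing_date_p = 0.913,
                             events_per_report_mean = 2,
                             quarters = "24Q1",
                             target_drug_name = "ROPIVACAINE",
                             seed = 20040101) {
  if (!is.numeric(n_reports) || length(n_reports) != 1 || n_reports < 1) {
    abort("`n_reports` must be a single integer >= 1.")
  }
  stopifnot(is.data.frame(pt_vocabulary),
            all(c("pt", "prob") %in% names(pt_vocabulary)))
  if (any(pt_vocabulary$prob < 0) || sum(pt_vocabulary$prob) <= 0) {
    abort("`pt_vocabulary$prob` must be non-negative and normalizable.")
  }
  pt_vocabulary$prob <- pt_vocabulary$prob / sum(pt_vocabulary$prob)
  probs <- c(target_drug_fraction, duplicate_fraction, missing_sex_p,
             missing_age_p, missing_weight_p, missing_date_p)
  if (any(probs < 0 | probs > 1)) {
    abort("All probability parameters must lie in [0, 1].")
  }
  if (tto_shape <= 0 || tto_scale <= 0) {
    abort("`tto_shape` and `tto_scale` must be positive.")
  }
  mult <- stats::setNames(rep(1, nrow(pt_vocabulary)), pt_vocabulary$pt)
  if (!is.null(signal_multipliers)) {
    unknown <- setdiff(names(signal_multipliers), pt_vocabulary$pt)
    if (length(unknown)) {
      abort(paste0("signal_multipliers name terms outside the vocabulary: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(signal_multipliers < 0)) abort("multipliers must be >= 0.")
    mult[names(signal_multipliers)] <- signal_multipliers
  }
  by_sex <- NULL
  if (!is.null(signal_multipliers_by_sex)) {
    by_sex <- purrr::map(signal_multipliers_by_sex, function(sm) {
      m <- mult
      m[names(sm)] <- sm
      m
    })
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      target_drug_fraction = target_drug_fraction,
      pt_vocabulary = tibble::as_tibble(pt_vocabulary),
      signal_multipliers = mult,
      signal_multipliers_by_sex = by_sex,
      duplicate_fraction = duplicate_fraction,
      tto_shape = tto_shape, tto_scale = tto_scale,
      missing_sex_p = missing_sex_p, missing_age_p = missing_age_p,
      missing_weight_p = missing_weight_p, missing_date_p = missing_date_p,
      events_per_report_mean = events_per_report_mean,
      quarters = quarters,
      target_drug_name = target_drug_name,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Sex distribution used by the generator: missingness then a 748:444
# female:male split among reports with known sex.
sex_probs <- function(config) {
  known <- 1 - config$missing_sex_p
  c(F = known * 748 / 1192, M = known * 444 / 1192, missing = config$missing_sex_p)
}

# Renormalised event-term probabilities for one generator stratum.
stratum_event_probs <- function(config, target, sex = NA_character_) {
  p <- config$pt_vocabulary$prob
  names(p) <- config$pt_vocabulary$pt
  if (!target) return(p)
  mult <- config$signal_multipliers
  if (!is.null(config$signal_multipliers_by_sex) && !is.na(sex) &&
      sex %in% names(config$signal_multipliers_by_sex)) {
    mult <- config$signal_multipliers_by_sex[[sex]]
  }
  p <- p * mult[names(p)]
  p / sum(p)
}

# P(report in this stratum lists term t at least once), under
# count ~ Poisson(mu) + 1 draws with replacement from prob vector p:
# P(absent | k draws) = (1 - p)^k, marginalised over k.
term_presence_prob <- function(p, mu) {
  kmax <- max(30, ceiling(mu + 10 * sqrt(mu)))
  k <- 1:(kmax + 1)
  wk <- stats::dpois(k - 1, mu)
  wk <- wk / sum(wk)
  1 - colSums(wk * outer(k, p, function(k, p) (1 - p)^k))
}

# Expected contingency cells for every vocabulary term under the
# generator's model, mixing target-report event probabilities over the sex
# distribution when per-sex multipliers are in play.
truth_table <- function(config) {
  mu <- config$events_per_report_mean
  n <- config$n_reports
  tf <- config$target_drug_fraction
  sp <- sex_probs(config)
  p_bg <- term_presence_prob(stratum_event_probs(config, FALSE), mu)
  strata <- c("F", "M", NA_character_)
  wts <- c(sp[["F"]], sp[["M"]], sp[["missing"]])
  p_tg <- Reduce(`+`, purrr::map2(strata, wts, function(s, w) {
    w * term_presence_prob(stratum_event_probs(config, TRUE, s), mu)
  }))
  a <- unname(n * tf * p_tg)
  b <- n * tf - a
  c_ <- unname(n * (1 - tf) * p_bg)
  d <- n * (1 - tf) - c_
  tibble::tibble(
    pt = config$pt_vocabulary$pt,
    lambda = unname(config$signal_multipliers[config$pt_vocabulary$pt]),
    expected_a = a, expected_b = b, expected_c = c_, expected_d = d,
    expected_ror = (a * d) / (b * c_),
    expected_rr = (a / (a + b)) / ((a + c_) / n)
  )
}

quarter_bounds <- function(q) {
  yy <- as.integer(substr(q, 1, 2))
  yr <- ifelse(yy < 50, 2000 + yy, 1900 + yy)
  qn <- as.integer(substr(q, 4, 4))
  start <- as.Date(sprintf("%d-%02d-01", yr, (qn - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  list(start = start, end = end)
}

#' Generate a synthetic FAERS-like corpus with known ground truth
#'
#' Draws `n_reports` unique cases from the configured model: a target-drug
#' indicator, demographics with realistic missingness, 1 + Poisson event
#' terms per report drawn from the background multinomial (re-weighted by
#' the planted multipliers for target-drug reports and renormalised),
#' therapy start dates, onset dates placed so the recorded onset interval
#' is a Weibull draw rounded up to whole days, and duplicate case versions
#' that exercise both branches of the FDA deduplication rule. Returns the
#' raw quarterly tables (with duplicates), the deduplicated report-level
#' ground truth, and a truth table of expected contingency cells per term.
#'
#' @param config a [generator_config()].
#' @param dir optional directory; when given, the quarterly tables are also
#'   written as FAERS-dialect `"$"`-delimited files via
#'   [write_faers_tables()].
#' @return A list of class `synthetic_faers` with elements `tables` (named
#'   list of tibbles: demo, drug, reac, ther, outc, rpsr — duplicates
#'   included), `reports` (deduplicated case-report tibble with the ground
#'   truth `is_target` flag), `truth` (expected cells per term), `config`,
#'   and `paths` (when `dir` was given).
#' @export
generate_faers <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_reports

  caseid <- 10000000L + seq_len(n)
  quarter <- sample(config$quarters, n, replace = TRUE)
  qb <- purrr::map(config$quarters, quarter_bounds)
  names(qb) <- config$quarters
  q_start <- as.Date(purrr::map_dbl(qb, ~ as.numeric(.x$start))[quarter])
  q_len <- purrr::map_dbl(qb, ~ as.numeric(.x$end - .x$start))[quarter]
  fda_dt <- q_start + floor(runif(n) * (q_len + 1))

  sp <- sex_probs(config)
  sex <- sample(c("F", "M", NA_character_), n, replace = TRUE, prob = sp)

  age <- rep(NA_real_, n)
  has_age <- runif(n) >= config$missing_age_p
  band <- sample(1:4, n, replace = TRUE, prob = c(67, 605, 273, 12) / 957)
  age[has_age & band == 1] <- sample(1:17, sum(has_age & band == 1), TRUE)
  age[has_age & band == 2] <- sample(18:64, sum(has_age & band == 2), TRUE)
  age[has_age & band == 3] <- sample(65:85, sum(has_age & band == 3), TRUE)
  age[has_age & band == 4] <- sample(86:95, sum(has_age & band == 4), TRUE)

  wt <- rep(NA_real_, n)
  has_wt <- runif(n) >= config$missing_weight_p
  wband <- sample(1:3, n, replace = TRUE, prob = c(58, 349, 41) / 448)
  wt[has_wt & wband == 1] <- sample(30:49, sum(has_wt & wband == 1), TRUE)
  wt[has_wt & wband == 2] <- sample(50:100, sum(has_wt & wband == 2), TRUE)
  wt[has_wt & wband == 3] <- sample(101:140, sum(has_wt & wband == 3), TRUE)

  occp <- sample(c("CN", "HP", "LW", "MD", "OT", "PH", "RN", NA_character_),
                 n, replace = TRUE,
                 prob = c(54, 175, 12, 495, 397, 260, 3, 67) / 1463)
  country <- sample(c("US", "FR", "JP", "PT", "AU", "DE", "GB", "IT"),
                    n, replace = TRUE,
                    prob = c(531, 229, 117, 105, 52, 180, 150, 99) / 1463)
  outcome <- sample(c("CA", "DE", "DS", "HO", "LT", "OT", "RI", NA_character_),
                    n, replace = TRUE,
                    prob = c(3, 75, 87, 313, 213, 464, 32, 276) / 1463)

  is_target <- runif(n) < config$target_drug_fraction

  # events: draw per stratum so planted multipliers (possibly sex-specific)
  # re-weight only target-drug reports
  k <- rpois(n, config$events_per_report_mean) + 1L
  strat_sex <- ifelse(is_target & !is.na(sex), sex, "none")
  strat_key <- paste0(is_target, ".", ifelse(is_target, strat_sex, "bg"))
  ev <- purrr::map_dfr(split(seq_len(n), strat_key), function(idx) {
    tgt <- is_target[idx[1]]
    sx <- if (tgt) sex[idx[1]] else NA_character_
    p <- stratum_event_probs(config, tgt, sx)
    drawn <- sample(names(p), sum(k[idx]), replace = TRUE, prob = p)
    tibble::tibble(row = rep(idx, k[idx]), pt = drawn)
  })
  ev <- dplyr::distinct(ev, .data$row, .data$pt) |> dplyr::arrange(.data$row, .data$pt)

  # therapy start precedes FDA receipt; onset interval = ceil(Weibull) days,
  # so event_dt = start_dt + floor(W) and the recorded interval
  # (difference + 1) has minimum 1 day
  start_dt <- fda_dt - sample(30:120, n, replace = TRUE)
  w <- rweibull(n, shape = config$tto_shape, scale = config$tto_scale)
  event_dt <- start_dt + floor(w)

  event_raw <- format_faers_date(event_dt)
  start_raw <- format_faers_date(start_dt)
  degrade <- runif(n) < config$missing_date_p
  how <- sample(1:4, n, replace = TRUE)
  event_raw[degrade & how == 1] <- ""
  event_raw[degrade & how == 2] <- substr(event_raw[degrade & how == 2], 1, 6)
  start_raw[degrade & how == 3] <- ""
  start_raw[degrade & how == 4] <- substr(start_raw[degrade & how == 4], 1, 6)

  target_variants <- c(config$target_drug_name,
                       "NAROPIN 0.2% INJ", "NAROPEINE",
                       paste0(config$target_drug_name, " HCL"))
  other_pool <- c("LIDOCAINE", "BUPIVACAINE", "FENTANYL", "MIDAZOLAM",
                  "PROPOFOL", "MORPHINE", "KETAMINE", "DEXAMETHASONE",
                  "ONDANSETRON", "PARACETAMOL", "IBUPROFEN", "CEFAZOLIN")
  ps_name <- ifelse(is_target,
                    sample(target_variants, n, replace = TRUE),
                    sample(other_pool, n, replace = TRUE))
  has_conmed <- runif(n) < 0.3
  conmed <- sample(other_pool, n, replace = TRUE)

  reports <- tibble::tibble(
    caseid = caseid,
    primaryid = caseid * 10L + 1L,
    quarter = quarter,
    fda_dt = format_faers_date(fda_dt),
    sex = sex, age_years = age, weight_kg = wt,
    reporter_code = occp, country = country,
    outcome = outcome,
    event_dt = event_raw, start_dt = start_raw,
    is_target = is_target,
    ps_name = ps_name, has_conmed = has_conmed, conmed = conmed
  )

  # duplicate case versions: extra rows with the same CASEID and either a
  # later FDA_DT (and next version id) or the same FDA_DT and a higher
  # PRIMARYID, with equal probability
  dup_case <- runif(n) < config$duplicate_fraction
  dups <- NULL
  if (any(dup_case)) {
    idx <- which(dup_case)
    n_extra <- sample(1:2, length(idx), replace = TRUE)
    drow <- rep(idx, n_extra)
    version <- unlist(lapply(n_extra, function(m) seq_len(m) + 1L))
    branch_date <- runif(length(drow)) < 0.5
    dups <- reports[drow, ]
    dups$primaryid <- dups$caseid * 10L + version
    bump <- sample(1:90, length(drow), replace = TRUE)
    new_fda <- as.Date(dups$fda_dt, "%Y%m%d") + bump
    dups$fda_dt[branch_date] <- format_faers_date(new_fda)[branch_date]
  }
  versions <- dplyr::bind_rows(reports, dups) |> dplyr::arrange(.data$primaryid)

  ev_by_case <- tibble::tibble(caseid = caseid[ev$row], pt = ev$pt)
  key <- versions |> dplyr::select("primaryid", "caseid", "quarter")

  demo <- versions |>
    dplyr::transmute(
      primaryid = .data$primaryid, caseid = .data$caseid,
      fda_dt = .data$fda_dt, event_dt = .data$event_dt,
      sex = dplyr::coalesce(.data$sex, ""),
      age = ifelse(is.na(.data$age_years), "", as.character(.data$age_years)),
      age_cod = ifelse(is.na(.data$age_years), "", "YR"),
      wt = ifelse(is.na(.data$weight_kg), "", as.character(.data$weight_kg)),
      wt_cod = ifelse(is.na(.data$weight_kg), "", "KG"),
      occp_cod = dplyr::coalesce(.data$reporter_code, ""),
      reporter_country = .data$country,
      quarter = .data$quarter
    )
  drug <- dplyr::bind_rows(
    versions |>
      dplyr::transmute(primaryid = .data$primaryid, caseid = .data$caseid,
                       drug_seq = 1L, role_cod = "PS",
                       drugname = .data$ps_name, prod_ai = .data$ps_name,
                       quarter = .data$quarter),
    versions |>
      dplyr::filter(.data$has_conmed) |>
      dplyr::transmute(primaryid = .data$primaryid, caseid = .data$caseid,
                       drug_seq = 2L, role_cod = "C",
                       drugname = .data$conmed, prod_ai = .data$conmed,
                       quarter = .data$quarter)
  ) |> dplyr::arrange(.data$primaryid, .data$drug_seq)
  reac <- key |>
    dplyr::inner_join(ev_by_case, by = "caseid",
                      relationship = "many-to-many") |>
    dplyr::transmute(primaryid = .data$primaryid, caseid = .data$caseid,
                     pt = .data$pt, quarter = .data$quarter) |>
    dplyr::arrange(.data$primaryid, .data$pt)
  ther <- versions |>
    dplyr::transmute(primaryid = .data$primaryid, caseid = .data$caseid,
                     dsg_drug_seq = 1L, start_dt = .data$start_dt,
                     end_dt = "", quarter = .data$quarter)
  outc <- versions |>
    dplyr::filter(!is.na(.data$outcome)) |>
    dplyr::transmute(primaryid = .data$primaryid, caseid = .data$caseid,
                     outc_cod = .data$outcome, quarter = .data$quarter)
  rpsr <- versions |>
    dplyr::transmute(
      primaryid = .data$primaryid, caseid = .data$caseid,
      rpsr_cod = ifelse(is.na(.data$reporter_code), "",
                 ifelse(.data$reporter_code %in% c("HP", "MD", "OT", "PH", "RN"),
                        "HP", "CSM")),
      quarter = .data$quarter
    )

  events_nested <- ev_by_case |>
    dplyr::group_by(.data$caseid) |>
    dplyr::summarise(events = list(.data$pt), .groups = "drop")
  report_level <- reports |>
    dplyr::left_join(events_nested, by = "caseid") |>
    dplyr::mutate(
      events = purrr::map(.data$events, ~ .x %||% character(0)),
      outcomes = purrr::map(.data$outcome, ~ if (is.na(.x)) character(0) else .x)
    ) |>
    dplyr::select("primaryid", "caseid", "fda_dt", "sex", "age_years",
                  "weight_kg", "reporter_code", "country", "event_dt",
                  "start_dt", "outcomes", "events", "is_target")

  out <- structure(
    list(
      tables = list(demo = demo, drug = drug, reac = reac, ther = ther,
                    outc = outc, rpsr = rpsr),
      reports = report_level,
      truth = truth_table(config),
      config = config
    ),
    class = "synthetic_faers"
  )
  if (!is.null(dir)) out$paths <- write_faers_tables(out, dir)
  out
}

#' Write synthetic tables in the FAERS quarterly-file dialect
#'
#' One `"$"`-delimited text file per table per quarter (`DEMO24Q1.txt`
#' naming), plus the truth table as `truth_table.tsv`.
#'
#' @param gen result of [generate_faers()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the character vector of file paths written.
#' @export
write_faers_tables <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_faers"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tab in names(gen$tables)) {
    df <- gen$tables[[tab]]
    for (q in unique(df$quarter)) {
      path <- file.path(dir, paste0(toupper(tab), q, ".txt"))
      readr::write_delim(dplyr::filter(df, .data$quarter == q) |>
                           dplyr::select(-"quarter"),
                         path, delim = "$", eol = "\n")
      paths <- c(paths, path)
    }
  }
  truth_path <- file.path(dir, "truth_table.tsv")
  readr::write_tsv(gen$truth, truth_path)
  invisible(c(paths, truth_path))
}

#' Demographic fixture reproducing a published report-level table
#'
#' A deterministic corpus of exactly 1463 deduplicated case reports whose
#' marginal counts match a published demographic table for a
#' local-anaesthetic safety cohort: sex 748 F / 444 M / 271 missing; age
#' bands 67 (<18), 605 (18-64), 273 (65-85), 12 (>85), 506 missing; weight
#' bands 58 (<50 kg), 349 (50-100 kg), 41 (>100 kg), 1015 missing;
#' reporter codes 54 CN, 175 HP, 12 LW, 495 MD, 397 OT, 260 PH, 3 RN, 67
#' missing; countries topped by 531 US, 229 FR, 117 JP, 105 PT, 52 AU; and
#' serious outcomes 3 CA, 75 DE, 87 DS, 313 HO, 213 LT, 464 OT, 32 RI,
#' 276 missing.
#'
#' @return A case-report tibble in the shape produced by
#'   [read_faers_tables()] after deduplication and target selection.
#' @export
make_table1_fixture <- function() {
  n <- 1463L
  expand <- function(values, counts) {
    stopifnot(sum(counts) == n)
    rep(values, counts)
  }
  vocab <- default_pt_vocabulary()$pt
  drugs_row <- tibble::tibble(drug_seq = 1L, role_cod = "PS",
                              drugname = "ROPIVACAINE",
                              prod_ai = "ROPIVACAINE")
  tibble::tibble(
    primaryid = 90000000L + seq_len(n),
    caseid = 80000000L + seq_len(n),
    fda_dt = "20240215",
    sex = expand(c("F", "M", NA_character_), c(748L, 444L, 271L)),
    age_years = expand(c(10, 40, 70, 90, NA), c(67L, 605L, 273L, 12L, 506L)),
    weight_kg = expand(c(45, 75, 120, NA), c(58L, 349L, 41L, 1015L)),
    reporter_code = expand(c("CN", "HP", "LW", "MD", "OT", "PH", "RN",
                             NA_character_),
                           c(54L, 175L, 12L, 495L, 397L, 260L, 3L, 67L)),
    country = expand(c("US", "FR", "JP", "PT", "AU", "DE", "GB", "IT", "ES",
                       "CN", "CA", "BR", "CH", "NL"),
                     c(531L, 229L, 117L, 105L, 52L, 48L, 48L, 48L, 48L,
                       48L, 48L, 47L, 47L, 47L)),
    event_dt = "", start_dt = "",
    outcomes = purrr::map(
      expand(c("CA", "DE", "DS", "HO", "LT", "OT", "RI", NA_character_),
             c(3L, 75L, 87L, 313L, 213L, 464L, 32L, 276L)),
      ~ if (is.na(.x)) character(0) else .x
    ),
    drugs = rep(list(drugs_row), n),
    events = purrr::map(vocab[(seq_len(n) - 1L) %% length(vocab) + 1L], ~.x),
    is_target = TRUE
  )
}
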