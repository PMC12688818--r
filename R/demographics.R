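#' Summarise report demographics and outcomes
#'
#' Produces the standard report-level descriptive table for a
#' spontaneous-report cohort: sex, age band (<18, 18-64, 65-85, >85),
#' weight band (<50, 50-100, >100 kg), reporter occupation (with a
#' healthcare-professional aggregate of HP + MD + OT + PH), top-k reporter
#' countries, and serious outcomes (a report counts once per distinct
#' outcome code; reports with no code count as missing). Percentages are
#' of the total report count, rounded half-up to two decimals.
#'
#' @param reports deduplicated case-report tibble.
#' @param top_countries how many countries to list individually.
#' @return A tibble with `block`, `category`, `count`, `pct`.
#' @export
summarize_demographics <- function(reports, top_countries = 5) {
  n <- nrow(reports)
  if (n == 0) {
    return(tibble::tibble(block = character(0), category = character(0),
                          count = integer(0), pct = numeric(0)))
  }
  pct <- function(k) round_half_up(100 * k / n, 2)
  row <- function(block, category, count) {
    tibble::tibble(block = block, category = category,
                   count = as.integer(count), pct = pct(count))
  }
  tally_block <- function(block, x, levels) {
    x <- factor(x, levels = levels)
    counts <- table(x, useNA = "always")
    dplyr::bind_rows(
      purrr::map2(c(levels, "Missing"), as.integer(counts),
                  ~ row(block, .x, .y))
    )
  }

  sex_tbl <- tally_block("sex", reports$sex, c("F", "M"))

  age_band <- dplyr::case_when(
    is.na(reports$age_years) ~ NA_character_,
    reports$age_years < 18 ~ "<18",
    reports$age_years <= 64 ~ "18-64",
    reports$age_years <= 85 ~ "65-85",
    TRUE ~ ">85"
  )
  age_tbl <- tally_block("age", age_band, c("<18", "18-64", "65-85", ">85"))

  wt_band <- dplyr::case_when(
    is.na(reports$weight_kg) ~ NA_character_,
    reports$weight_kg < 50 ~ "<50 kg",
    reports$weight_kg <= 100 ~ "50-100 kg",
    TRUE ~ ">100 kg"
  )
  wt_tbl <- tally_block("weight", wt_band, c("<50 kg", "50-100 kg", ">100 kg"))

  rep_levels <- c("CN", "HP", "LW", "MD", "OT", "PH", "RN")
  rep_tbl <- tally_block("reporter", reports$reporter_code, rep_levels)
  hp_n <- sum(reports$reporter_code %in% c("HP", "MD", "OT", "PH"))
  rep_tbl <- dplyr::bind_rows(
    rep_tbl, row("reporter", "Healthcare professional (HP+MD+OT+PH)", hp_n)
  )

  ctry <- table(reports$country)
  top <- head(sort(ctry, decreasing = TRUE), top_countries)
  ctry_tbl <- dplyr::bind_rows(
    purrr::map2(names(top), as.integer(top), ~ row("country", .x, .y)),
    row("country", "Other", n - sum(top) - sum(is.na(reports$country))),
    row("country", "Missing", sum(is.na(reports$country)))
  )

  out_codes <- c("CA", "DE", "DS", "HO", "LT", "OT", "RI")
  flat <- unlist(purrr::map(reports$outcomes, unique), use.names = FALSE)
  out_counts <- table(factor(flat, levels = out_codes))
  missing_outc <- sum(purrr::map_int(reports$outcomes, length) == 0)
  outc_tbl <- dplyr::bind_rows(
    purrr::map2(out_codes, as.integer(out_counts), ~ row("outcome", .x, .y)),
    row("outcome", "Missing", missing_outc)
  )

  dplyr::bind_rows(row("total", "N", n), sex_tbl, wt_tbl, age_tbl, rep_tbl,
                   ctry_tbl, outc_tbl)
}
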