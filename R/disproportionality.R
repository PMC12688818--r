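#' Build 2x2 contingency tables per (target drug, event term)
#'
#' For every term present in the corpus at the chosen level, counts
#' a = target-drug reports listing the term, b = target-drug reports
#' without it, c = other-drug reports with it, d = other-drug reports
#' without it. The counting unit is the unique report-term pair: a report
#' contributes at most once per term. An optional sex stratum restricts
#' the whole corpus (target and background) before counting; reports with
#' missing sex belong to no stratum.
#'
#' @param reports case-report tibble with logical `is_target`, list-column
#'   `events` (already rolled up to the desired level), and `sex`.
#' @param level label recorded on the output (`"PT"`, `"HLGT"`, `"SOC"`).
#' @param stratum `"all"`, `"F"`, or `"M"`.
#' @return A tibble with one row per term: `term`, `a`, `b`, `c`, `d`, `n`,
#'   `level`, `stratum`.
#' @export
build_contingency_tables <- function(reports, level = "PT", stratum = "all") {
  stopifnot(all(c("is_target", "events") %in% names(reports)))
  if (stratum != "all") {
    reports <- dplyr::filter(reports, !is.na(.data$sex), .data$sex == stratum)
  }
  n_target <- sum(reports$is_target)
  n_other <- sum(!reports$is_target)
  if (nrow(reports) == 0) {
    warn(sprintf("Stratum '%s' contains no reports.", stratum))
    return(tibble::tibble(term = character(0), a = integer(0), b = integer(0),
                          c = integer(0), d = integer(0), n = integer(0),
                          level = character(0), stratum = character(0)))
  }
  len <- purrr::map_int(reports$events, length)
  pairs <- tibble::tibble(
    rid = rep(seq_len(nrow(reports)), len),
    is_target = rep(reports$is_target, len),
    term = unlist(reports$events, use.names = FALSE)
  ) |>
    dplyr::distinct() # a report counts once per term
  pairs |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(a = sum(.data$is_target), c = sum(!.data$is_target),
                     .groups = "drop") |>
    dplyr::mutate(b = n_target - .data$a, d = n_other - .data$c,
                  n = .data$a + .data$b + .data$c + .data$d,
                  level = level, stratum = stratum) |>
    dplyr::select("term", "a", "b", "c", "d", "n", "level", "stratum") |>
    dplyr::arrange(.data$term)
}

# Haldane-Anscombe continuity correction: +0.5 on all four cells when any
# cell is zero. Applied to the frequentist statistics (ROR, PRR, chi2)
# only; the Bayesian statistics shrink zero cells on their own.
continuity_correct <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  k <- ifelse(zero, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = zero)
}

#' Reporting odds ratio with 95% Wald confidence interval
#'
#' ROR = (a d)/(b c); CI = exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' Zero cells receive the +0.5 Haldane-Anscombe correction when
#' `correct = TRUE`; with the correction disabled a zero cell yields `NA`
#' rather than an error.
#'
#' @param a,b,c,d contingency cells (vectorised).
#' @param conf_level confidence level for the Wald interval.
#' @param correct apply the +0.5 correction to zero cells.
#' @return A tibble with `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_stats <- function(a, b, c, d, conf_level = 0.95, correct = TRUE) {
  if (correct) {
    cc <- continuity_correct(a, b, c, d)
    a <- cc$a; b <- cc$b; c <- cc$c; d <- cc$d
  }
  bad <- a <= 0 | b <= 0 | c <= 0 | d <= 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  out <- tibble::tibble(
    ror = est,
    ror_lo = exp(log(est) - z * se),
    ror_hi = exp(log(est) + z * se)
  )
  out[bad, ] <- NA_real_
  out
}

#' Proportional reporting ratio and chi-squared statistic
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\]. The accompanying chi-squared statistic
#' is the 1-df test of independence on the 2x2 table; the classic
#' signal-detection criteria use the Yates-corrected form
#' chi2 = n (|ad - bc| - n/2)^2 / ((a+b)(c+d)(a+c)(b+d)), clamped at 0
#' when the half-count exceeds |ad - bc|.
#'
#' @inheritParams ror_stats
#' @param yates use the Yates continuity correction (default TRUE).
#' @return A tibble with `prr`, `chi2`.
#' @export
prr_chi2 <- function(a, b, c, d, yates = TRUE, correct = TRUE) {
  if (correct) {
    cc <- continuity_correct(a, b, c, d)
    a <- cc$a; b <- cc$b; c <- cc$c; d <- cc$d
  }
  n <- a + b + c + d
  bad <- (a + b) <= 0 | (c + d) <= 0 | c <= 0 | n <= 0
  prr <- (a / (a + b)) / (c / (c + d))
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - n / 2, 0)
  chi2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  out <- tibble::tibble(prr = prr, chi2 = chi2)
  out[bad, ] <- NA_real_
  out
}

#' BCPNN information component with shrinkage lower bound
#'
#' The information component compares the observed count a with its
#' independence expectation E = (a+b)(a+c)/n on the log2 scale, with a
#' +0.5 shrinkage on both numerator and denominator that keeps the
#' statistic finite at a = 0:
#' IC = log2((a + 0.5)/(E + 0.5)). The 2.5th-percentile credibility bound
#' uses the standard closed-form approximation to the posterior
#' distribution of log2(lambda) under lambda ~ Gamma(a + 0.5, E + 0.5):
#' IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2.0 (a+0.5)^(-3/2).
#'
#' @inheritParams ror_stats
#' @return A tibble with `ic`, `ic025` and the expectation `e_count`.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-1 / 2) - 2.0 * (a + 0.5)^(-3 / 2)
  tibble::tibble(ic = ic, ic025 = ic025, e_count = e)
}

#' Default joint significance thresholds
#'
#' The conventional joint criterion for a positive signal: at least three
#' reports, ROR 95% CI lower bound above 1, PRR at least 2 with
#' chi-squared at least 4, IC025 above 0, and EBGM above 2 — all
#' simultaneously.
#'
#' @param min_n,ror_lo,prr,chi2,ic025,ebgm threshold values.
#' @param ebgm_stat which EBGM quantity the `ebgm` threshold applies to:
#'   the posterior geometric mean (`"ebgm"`, the printed rule) or its 5th
#'   percentile (`"ebgm05"`, the common conservative variant).
#' @return A named list of thresholds.
#' @export
signal_thresholds <- function(min_n = 3, ror_lo = 1, prr = 2, chi2 = 4,
                              ic025 = 0, ebgm = 2,
                              ebgm_stat = c("ebgm", "ebgm05")) {
  list(min_n = min_n, ror_lo = ror_lo, prr = prr, chi2 = chi2,
       ic025 = ic025, ebgm = ebgm, ebgm_stat = match.arg(ebgm_stat))
}

#' Compute all four disproportionality statistics for a set of tables
#'
#' Applies ROR, PRR + chi-squared, the BCPNN information component, and
#' MGPS EBGM to every contingency table, fitting the MGPS prior across
#' the supplied tables (or reusing a prior fitted elsewhere).
#'
#' @param tables output of [build_contingency_tables()].
#' @param mgps_prior optional [mgps_fit()] result; fitted on `tables` when
#'   omitted.
#' @param correct apply the +0.5 zero-cell correction for ROR/PRR.
#' @param yates Yates-correct the chi-squared statistic.
#' @return `tables` augmented with `ror`, `ror_lo`, `ror_hi`, `prr`,
#'   `chi2`, `ic`, `ic025`, `e_count`, `ebgm`, `ebgm05`.
#' @export
signal_stats <- function(tables, mgps_prior = NULL, correct = TRUE,
                         yates = TRUE) {
  if (nrow(tables) == 0) {
    return(dplyr::mutate(tables, ror = numeric(0), ror_lo = numeric(0),
                         ror_hi = numeric(0), prr = numeric(0),
                         chi2 = numeric(0), ic = numeric(0),
                         ic025 = numeric(0), e_count = numeric(0),
                         ebgm = numeric(0), ebgm05 = numeric(0)))
  }
  if (is.null(mgps_prior)) mgps_prior <- mgps_fit(tables)
  bc <- bcpnn_ic(tables$a, tables$b, tables$c, tables$d)
  eb <- ebgm_stats(tables$a, bc$e_count, mgps_prior)
  dplyr::bind_cols(
    tables,
    ror_stats(tables$a, tables$b, tables$c, tables$d, correct = correct),
    prr_chi2(tables$a, tables$b, tables$c, tables$d, yates = yates,
             correct = correct),
    bc, eb
  )
}

#' Apply the joint significance criterion
#'
#' Marks a term significant only when every one of the four algorithms
#' meets its threshold (and the case count is at least `min_n`). `NA`
#' statistics fail their criterion.
#'
#' @param results output of [signal_stats()].
#' @param thresholds a [signal_thresholds()] list.
#' @return `results` with a logical `significant` column.
#' @export
screen_signals <- function(results, thresholds = signal_thresholds()) {
  eb_val <- if (thresholds$ebgm_stat == "ebgm05") results$ebgm05 else results$ebgm
  ok <- function(x) !is.na(x)
  dplyr::mutate(
    results,
    significant =
      .data$a >= thresholds$min_n &
      ok(.data$ror_lo) & .data$ror_lo > thresholds$ror_lo &
      ok(.data$prr) & .data$prr >= thresholds$prr &
      ok(.data$chi2) & .data$chi2 >= thresholds$chi2 &
      ok(.data$ic025) & .data$ic025 > thresholds$ic025 &
      ok(eb_val) & eb_val > thresholds$ebgm
  )
}

#' Disproportionality screening at one level, overall or within sex strata
#'
#' Convenience wrapper running tables -> four statistics -> joint screen
#' for each requested stratum. Within a sex stratum the background is
#' restricted to same-stratum reports; reports with missing sex are
#' excluded from both sex strata.
#'
#' @param reports flagged, rolled-up case-report tibble.
#' @param level level label for the output.
#' @param strata subset of `c("all", "F", "M")`.
#' @param thresholds a [signal_thresholds()] list.
#' @inheritParams signal_stats
#' @return A tibble of screened results across strata.
#' @export
disproportionality <- function(reports, level = "PT",
                               strata = "all",
                               thresholds = signal_thresholds(),
                               correct = TRUE, yates = TRUE) {
  purrr::map_dfr(strata, function(s) {
    tabs <- build_contingency_tables(reports, level = level, stratum = s)
    screen_signals(signal_stats(tabs, correct = correct, yates = yates),
                   thresholds)
  })
}
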