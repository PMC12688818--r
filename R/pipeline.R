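#' Read a key=value thresholds file
#'
#' Plain-text configuration with one `key=value` per line (`#` comments
#' allowed). Recognised keys are the arguments of [signal_thresholds()].
#'
#' @param path file path.
#' @return A [signal_thresholds()] list.
#' @export
read_thresholds <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  kv <- stringr::str_split_fixed(lines, "=", 2)
  vals <- stats::setNames(stringr::str_trim(kv[, 2]), stringr::str_trim(kv[, 1]))
  args <- list()
  for (k in c("min_n", "ror_lo", "prr", "chi2", "ic025", "ebgm")) {
    if (k %in% names(vals)) args[[k]] <- as.numeric(vals[[k]])
  }
  if ("ebgm_stat" %in% names(vals)) args$ebgm_stat <- vals[["ebgm_stat"]]
  do.call(signal_thresholds, args)
}

#' Run the full signal-detection pipeline
#'
#' Orchestrates ingest -> deduplication -> target-case selection ->
#' hierarchy roll-up -> disproportionality screening at PT/HLGT/SOC level
#' for the overall corpus and each sex stratum -> time-to-onset analysis
#' (Weibull fit, failure type, KM curves, log-rank by sex) -> demographic
#' summary, and writes every result as a tab-separated file plus a run
#' manifest with the row counts at each stage.
#'
#' @param input directory of FAERS-dialect quarterly files, or an
#'   already-ingested case-report tibble.
#' @param drug_names names identifying the target drug.
#' @param out_dir output directory.
#' @param hierarchy a `hierarchy_map` (default: the packaged synthetic
#'   hierarchy).
#' @param thresholds a [signal_thresholds()] list or path to a key=value
#'   file.
#' @param levels hierarchy levels to screen.
#' @param strata strata to screen (`"all"`, `"F"`, `"M"`).
#' @param role target drug role code.
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic given its inputs).
#' @return Invisibly, a list with `results` (per level/stratum), `tto`,
#'   `demographics`, `manifest`, and `out_dir`.
#' @export
run_pipeline <- function(input, drug_names, out_dir,
                         hierarchy = synthetic_hierarchy(),
                         thresholds = signal_thresholds(),
                         levels = c("PT", "HLGT", "SOC"),
                         strata = c("all", "F", "M"),
                         role = "PS", seed = 1L) {
  if (is.character(thresholds)) thresholds <- read_thresholds(thresholds)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)

  stage <- function(name, value) inform(sprintf("[%s] %s", name, value))

  raw <- if (is.data.frame(input)) input else read_faers_tables(input)
  stage("ingest", sprintf("%d report versions", nrow(raw)))
  deduped <- deduplicate_reports(raw)
  stage("dedup", sprintf("%d unique cases", nrow(deduped)))
  flagged <- select_target_cases(deduped, drug_names, role = role,
                                 keep_all = TRUE)
  target <- dplyr::filter(flagged, .data$is_target)
  stage("target", sprintf("%d target-drug cases", nrow(target)))

  results <- list()
  for (lev in levels) {
    rolled <- roll_up(flagged, level = lev, hierarchy = hierarchy,
                      ignore_unmapped = TRUE)
    res <- disproportionality(rolled, level = lev, strata = strata,
                              thresholds = thresholds)
    results[[lev]] <- res
    for (s in unique(res$stratum)) {
      readr::write_tsv(
        format_signal_table(dplyr::filter(res, .data$stratum == s)),
        file.path(out_dir, sprintf("signals_%s_%s.tsv", lev, s))
      )
    }
  }

  tto <- extract_tto(target)
  stage("tto", sprintf("%d usable onset intervals (%d excluded)",
                       nrow(tto$samples), sum(tto$exclusions$n)))
  tto_res <- NULL
  if (nrow(tto$samples) >= 10) {
    tto_res <- tto_analysis(tto$samples)
    readr::write_tsv(tto_res$summary, file.path(out_dir, "tto_summary.tsv"))
    readr::write_tsv(tto_res$km, file.path(out_dir, "km_curves.tsv"))
    if (!is.null(tto_res$logrank)) {
      readr::write_tsv(tto_res$logrank, file.path(out_dir, "logrank.tsv"))
    }
  }
  readr::write_tsv(tto$exclusions, file.path(out_dir, "tto_exclusions.tsv"))

  demo <- summarize_demographics(target)
  readr::write_tsv(demo, file.path(out_dir, "demographics.tsv"))

  manifest <- c(
    sprintf("pharmsig_version=%s",
            as.character(utils::packageVersion("pharmsig"))),
    sprintf("seed=%d", seed),
    sprintf("n_report_versions=%d", nrow(raw)),
    sprintf("n_unique_cases=%d", nrow(deduped)),
    sprintf("n_target_cases=%d", nrow(target)),
    sprintf("n_tto_usable=%d", nrow(tto$samples)),
    sprintf("thresholds=min_n:%g,ror_lo:%g,prr:%g,chi2:%g,ic025:%g,ebgm:%g(%s)",
            thresholds$min_n, thresholds$ror_lo, thresholds$prr,
            thresholds$chi2, thresholds$ic025, thresholds$ebgm,
            thresholds$ebgm_stat),
    "reporter_aggregate=HP+MD+OT+PH"
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(results = results, tto = tto_res, tto_samples = tto$samples,
                 demographics = demo, manifest = manifest,
                 reports = flagged, out_dir = out_dir))
}

# Tables 2-4-style presentation: statistic (interval) pairs at 2 decimals.
format_signal_table <- function(res) {
  f2 <- function(x) formatC(x, format = "f", digits = 2)
  res |>
    dplyr::arrange(dplyr::desc(.data$significant), dplyr::desc(.data$a)) |>
    dplyr::transmute(
      term = .data$term, level = .data$level, stratum = .data$stratum,
      N = .data$a,
      `ROR (95%CI)` = sprintf("%s (%s-%s)", f2(.data$ror), f2(.data$ror_lo),
                              f2(.data$ror_hi)),
      `PRR (chi2)` = sprintf("%s (%s)", f2(.data$prr), f2(.data$chi2)),
      `EBGM (EBGM05)` = sprintf("%s (%s)", f2(.data$ebgm), f2(.data$ebgm05)),
      `IC (IC025)` = sprintf("%s (%s)", f2(.data$ic), f2(.data$ic025)),
      significant = .data$significant
    )
}
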