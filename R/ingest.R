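faers_required_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age", "wt",
           "occp_cod", "reporter_country"),
  drug = c("primaryid", "caseid", "role_cod", "drugname"),
  reac = c("primaryid", "caseid", "pt"),
  ther = c("primaryid", "caseid", "start_dt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  rpsr = c("primaryid", "caseid", "rpsr_cod")
)

# Locate quarterly files for one table by their DEMOyyQq.txt-style prefix.
find_table_files <- function(paths, table) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
  }
  paths[grepl(paste0("^", toupper(table), ".*\\.txt$"), basename(paths))]
}

read_one_table <- function(files, table) {
  req <- faers_required_cols[[table]]
  purrr::map_dfr(files, function(f) {
    df <- readr::read_delim(f, delim = "$", col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    names(df) <- tolower(names(df))
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols)) {
      abort(sprintf("File %s is missing mandatory column(s): %s",
                    basename(f), paste(missing_cols, collapse = ", ")))
    }
    df
  })
}

#' Read FAERS-dialect quarterly tables into one case-report table
#'
#' Reads the `"$"`-delimited DEMO/DRUG/REAC/THER/OUTC/RPSR files found in
#' `paths` (a directory or explicit file vector; quarters are identified by
#' the `DEMOyyQq.txt` naming) and joins them by PRIMARYID into one row per
#' report version. Rows with an unparseable PRIMARYID are skipped and
#' counted; DEMO rows with no REAC row are dropped with a message, since an
#' event-less report can enter no contingency table.
#'
#' @param paths directory containing quarterly files, or a character vector
#'   of file paths.
#' @param drop_eventless drop reports without any event term (default TRUE).
#' @return A tibble with one row per report version: `primaryid`, `caseid`,
#'   `fda_dt`, `sex`, `age_years`, `weight_kg`, `reporter_code`, `country`,
#'   `event_dt`, `start_dt`, and list-columns `outcomes`, `drugs`, `events`.
#' @export
read_faers_tables <- function(paths, drop_eventless = TRUE) {
  tabs <- purrr::imap(faers_required_cols, function(req, tab) {
    files <- find_table_files(paths, tab)
    if (!length(files)) {
      abort(sprintf("No %s*.txt files found in the given paths.", toupper(tab)))
    }
    read_one_table(files, tab)
  })
  join_faers_tables(tabs$demo, tabs$drug, tabs$reac, tabs$ther, tabs$outc,
                    drop_eventless = drop_eventless)
}

# Shared by the file reader and the generator's in-memory path.
join_faers_tables <- function(demo, drug, reac, ther, outc,
                              drop_eventless = TRUE) {
  demo <- tibble::as_tibble(demo)
  n_raw <- nrow(demo)
  pid <- suppressWarnings(as.integer(demo$primaryid))
  bad <- is.na(pid)
  if (any(bad)) {
    inform(sprintf("Skipped %d DEMO row(s) with unparseable PRIMARYID.",
                   sum(bad)))
  }
  demo <- demo[!bad, ]

  blank_to_na <- function(x) {
    x <- stringr::str_trim(as.character(x))
    dplyr::if_else(x == "" | x == "NA", NA_character_, x)
  }
  reports <- demo |>
    dplyr::transmute(
      primaryid = as.integer(.data$primaryid),
      caseid = as.integer(.data$caseid),
      fda_dt = as.character(.data$fda_dt),
      sex = blank_to_na(.data$sex),
      age_years = suppressWarnings(as.numeric(blank_to_na(.data$age))),
      weight_kg = suppressWarnings(as.numeric(blank_to_na(.data$wt))),
      reporter_code = blank_to_na(.data$occp_cod),
      country = blank_to_na(.data$reporter_country),
      event_dt = dplyr::coalesce(as.character(.data$event_dt), ""),
      start_dt = ""
    )
  reports$sex[!reports$sex %in% c("F", "M")] <- NA_character_

  ther2 <- ther |>
    dplyr::mutate(primaryid = as.integer(.data$primaryid)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(start_dt2 = dplyr::first(as.character(.data$start_dt)),
                     .groups = "drop")
  reports <- reports |>
    dplyr::left_join(ther2, by = "primaryid") |>
    dplyr::mutate(start_dt = dplyr::coalesce(.data$start_dt2, ""),
                  .keep = "unused")

  drugs_n <- drug |>
    dplyr::mutate(primaryid = as.integer(.data$primaryid)) |>
    dplyr::select(dplyr::any_of(c("primaryid", "drug_seq", "role_cod",
                                  "drugname", "prod_ai"))) |>
    tidyr::nest(drugs = -"primaryid")
  events_n <- reac |>
    dplyr::mutate(primaryid = as.integer(.data$primaryid)) |>
    dplyr::distinct(.data$primaryid, .data$pt) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(events = list(.data$pt), .groups = "drop")
  outc_n <- outc |>
    dplyr::mutate(primaryid = as.integer(.data$primaryid)) |>
    dplyr::distinct(.data$primaryid, .data$outc_cod) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(outcomes = list(.data$outc_cod), .groups = "drop")

  reports <- reports |>
    dplyr::left_join(outc_n, by = "primaryid") |>
    dplyr::left_join(drugs_n, by = "primaryid") |>
    dplyr::left_join(events_n, by = "primaryid") |>
    dplyr::mutate(
      outcomes = purrr::map(.data$outcomes, ~ .x %||% character(0)),
      events = purrr::map(.data$events, ~ .x %||% character(0))
    )
  no_event <- purrr::map_int(reports$events, length) == 0
  if (drop_eventless && any(no_event)) {
    inform(sprintf("Dropped %d report(s) with no event terms.", sum(no_event)))
    reports <- reports[!no_event, ]
  }
  if (nrow(reports) < n_raw) {
    inform(sprintf("Ingested %d of %d raw DEMO rows.", nrow(reports), n_raw))
  }
  reports
}

#' Deduplicate case versions by the FDA-recommended rule
#'
#' FAERS publishes multiple versions of the same case under one CASEID.
#' For each CASEID the version with the latest FDA receipt date (FDA_DT)
#' is retained; among versions sharing the latest FDA_DT, the one with the
#' highest PRIMARYID is retained. The operation is idempotent.
#'
#' @param reports case-report tibble with `caseid`, `fda_dt`, `primaryid`.
#' @return The tibble restricted to one row per CASEID.
#' @export
deduplicate_reports <- function(reports) {
  stopifnot(all(c("caseid", "fda_dt", "primaryid") %in% names(reports)))
  reports |>
    dplyr::group_by(.data$caseid) |>
    dplyr::filter(.data$fda_dt == max(.data$fda_dt)) |>
    dplyr::filter(.data$primaryid == max(.data$primaryid)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$caseid)
}

normalize_drug_name <- function(x) {
  x <- toupper(stringr::str_trim(as.character(x)))
  stringr::str_squish(stringr::str_replace_all(x, "[^A-Z0-9 ]", " "))
}

#' Flag or select reports naming a target drug in a given role
#'
#' A report matches when at least one of its drug rows has the requested
#' role code and a name (DRUGNAME or active-ingredient field, both
#' searched by default) containing any of the listed names after
#' normalisation (uppercase, punctuation stripped, substring match — so
#' "NAROPIN 0.2% INJ" matches "Naropin").
#'
#' @param reports case-report tibble with a `drugs` list-column.
#' @param drug_names character vector of generic/brand names to search.
#' @param role required role code (default `"PS"`, primary suspect).
#' @param fields drug-name columns searched (`drugname`, `prod_ai`).
#' @param keep_all if TRUE, return all reports with an `is_target` flag
#'   instead of filtering.
#' @return The matching reports (or all reports flagged).
#' @export
select_target_cases <- function(reports, drug_names,
                                role = "PS",
                                fields = c("drugname", "prod_ai"),
                                keep_all = FALSE) {
  if (length(drug_names) == 0) abort("`drug_names` must be non-empty.")
  pats <- normalize_drug_name(drug_names)
  hit <- purrr::map_lgl(reports$drugs, function(d) {
    if (is.null(d) || !nrow(d)) return(FALSE)
    d <- d[d$role_cod == role, , drop = FALSE]
    if (!nrow(d)) return(FALSE)
    nm <- unlist(d[intersect(fields, names(d))], use.names = FALSE)
    nm <- normalize_drug_name(nm)
    any(purrr::map_lgl(pats, ~ any(stringr::str_detect(nm, stringr::fixed(.x)))))
  })
  if (keep_all) {
    dplyr::mutate(reports, is_target = hit)
  } else {
    reports[hit, ]
  }
}
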