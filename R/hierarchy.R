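#' Load a PT -> HLGT -> SOC hierarchy map
#'
#' Reads a tab-separated file with columns `pt_id`, `pt_name`, `hlgt_id`,
#' `hlgt_name`, `soc_id`, `soc_name`. Duplicate rows are collapsed; a PT
#' may map to several (HLGT, SOC) pairs (multi-axiality). Every PT must
#' carry a SOC.
#'
#' @param path tab-separated hierarchy file.
#' @return A validated hierarchy tibble of class `hierarchy_map`.
#' @export
load_hierarchy <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  req <- c("pt_id", "pt_name", "hlgt_id", "hlgt_name", "soc_id", "soc_name")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("Hierarchy file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_hierarchy_map(df[req])
}

#' @rdname load_hierarchy
#' @param df a data frame with the six hierarchy columns.
#' @export
as_hierarchy_map <- function(df) {
  df <- tibble::as_tibble(df) |> dplyr::distinct()
  bad <- is.na(df$soc_name) | df$soc_name == "" | is.na(df$soc_id) | df$soc_id == ""
  if (any(bad)) {
    abort(paste0("PT(s) without a SOC in the hierarchy: ",
                 paste(unique(df$pt_name[bad]), collapse = ", ")))
  }
  structure(df, class = c("hierarchy_map", class(df)))
}

#' Synthetic MedDRA-like hierarchy for the generator vocabulary
#'
#' The real MedDRA dictionary is licensed, so the package ships a synthetic
#' hierarchy covering [default_pt_vocabulary()]: each PT maps to one HLGT
#' and one SOC, except "Local anaesthetic systemic toxicity", which is
#' multi-axial (nervous-system and procedural-injury SOCs) to exercise
#' per-SOC counting.
#'
#' @return A `hierarchy_map` tibble.
#' @export
synthetic_hierarchy <- function() {
  h <- function(pt, hlgt, soc) tibble::tibble(pt_name = pt, hlgt_name = hlgt,
                                              soc_name = soc)
  rows <- dplyr::bind_rows(
    h(c("Nausea", "Vomiting"), "Gastrointestinal motility and defaecation conditions",
      "Gastrointestinal disorders"),
    h(c("Headache", "Dizziness", "Somnolence", "Confusional state"),
      "Neurological disorders NEC", "Nervous system disorders"),
    h(c("Paraesthesia", "Hypoaesthesia", "Neurotoxicity"),
      "Peripheral neuropathies", "Nervous system disorders"),
    h(c("Seizure"), "Seizures (including subtypes)", "Nervous system disorders"),
    h(c("Monoplegia", "Muscular weakness", "Phrenic nerve paralysis"),
      "Neuromuscular disorders", "Nervous system disorders"),
    h(c("Tremor"), "Movement disorders", "Nervous system disorders"),
    h(c("Hypotension"), "Decreased and nonspecific blood pressure disorders and shock",
      "Cardiac disorders"),
    h(c("Tachycardia", "Bradycardia", "Sinus tachycardia",
        "Ventricular fibrillation", "Cardiac arrest"),
      "Cardiac arrhythmias", "Cardiac disorders"),
    h(c("Rash", "Pruritus", "Urticaria"), "Epidermal and dermal conditions",
      "Skin and subcutaneous tissue disorders"),
    h(c("Anaphylactic shock"), "Allergic conditions", "Immune system disorders"),
    h(c("Dyspnoea"), "Respiratory disorders NEC",
      "Respiratory, thoracic and mediastinal disorders"),
    h(c("Pyrexia", "Injection site pain"), "General system disorders NEC",
      "General disorders and administration site conditions"),
    h(c("Back pain"), "Musculoskeletal and connective tissue disorders NEC",
      "Musculoskeletal and connective tissue disorders"),
    h(c("Anaesthetic complication", "Local anaesthetic systemic toxicity"),
      "Procedural related injuries and complications NEC",
      "Injury, poisoning and procedural complications"),
    # multi-axial secondary assignment
    h("Local anaesthetic systemic toxicity", "Neurological disorders NEC",
      "Nervous system disorders")
  )
  ids <- function(x, prefix) paste0(prefix, formatC(as.integer(factor(x)),
                                                   width = 4, flag = "0"))
  rows |>
    dplyr::mutate(pt_id = ids(.data$pt_name, "PT"),
                  hlgt_id = ids(.data$hlgt_name, "HLGT"),
                  soc_id = ids(.data$soc_name, "SOC")) |>
    dplyr::select("pt_id", "pt_name", "hlgt_id", "hlgt_name", "soc_id",
                  "soc_name") |>
    as_hierarchy_map()
}

#' Roll report event terms up to PT, HLGT, or SOC level
#'
#' Re-labels each report's event set at the requested hierarchy level and
#' de-duplicates within report, so a report contributes at most once per
#' term per level. A multi-axial PT contributes once to each of its SOCs.
#'
#' @param reports case-report tibble with an `events` list-column of PT
#'   names.
#' @param level `"PT"` (identity), `"HLGT"`, or `"SOC"`.
#' @param hierarchy a `hierarchy_map`.
#' @param ignore_unmapped if TRUE, PTs absent from the map are dropped
#'   silently; otherwise they raise an error.
#' @return The reports tibble with `events` re-labelled at `level`.
#' @export
roll_up <- function(reports, level = c("PT", "HLGT", "SOC"),
                    hierarchy = synthetic_hierarchy(),
                    ignore_unmapped = FALSE) {
  level <- match.arg(level)
  if (level == "PT") {
    return(dplyr::mutate(reports,
                         events = purrr::map(.data$events, unique)))
  }
  col <- if (level == "HLGT") "hlgt_name" else "soc_name"
  map_tbl <- dplyr::distinct(tibble::as_tibble(hierarchy)[, c("pt_name", col)])
  lut <- split(map_tbl[[col]], map_tbl$pt_name)
  known <- names(lut)
  all_pts <- unique(unlist(reports$events, use.names = FALSE))
  unmapped <- setdiff(all_pts, known)
  if (length(unmapped) && !ignore_unmapped) {
    abort(paste0("PT(s) not in the hierarchy map: ",
                 paste(unmapped, collapse = ", ")))
  }
  dplyr::mutate(reports, events = purrr::map(.data$events, function(e) {
    unique(unlist(lut[intersect(e, known)], use.names = FALSE)) %||% character(0)
  }))
}
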