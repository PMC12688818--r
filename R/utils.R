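#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for the demographic percentage
#' tables so that e.g. 313/1463 prints as 21.39 and 464/1463 as 31.72.
#' Base `round()` rounds half to even and would disagree on exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Parse FAERS-style date strings. Full dates are 8-digit YYYYMMDD; partial
# dates (YYYYMM or YYYY) and blanks are common in real quarters and carry
# precision "partial"/"missing". Returns a tibble(date, precision).
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringr::str_trim(x)
  precision <- dplyr::case_when(
    x == "" | x == "NA" ~ "missing",
    stringr::str_detect(x, "^\\d{8}$") ~ "full",
    stringr::str_detect(x, "^\\d{4}(\\d{2})?$") ~ "partial",
    TRUE ~ "invalid"
  )
  date <- rep(as.Date(NA), length(x))
  full <- precision == "full"
  if (any(full)) {
    parsed <- as.Date(x[full], format = "%Y%m%d")
    date[full] <- parsed
    # e.g. 20231350 is 8 digits but no calendar date
    precision[full][is.na(parsed)] <- "invalid"
  }
  tibble::tibble(date = date, precision = precision)
}

# Format a Date as a YYYYMMDD integer string (the FAERS on-disk form).
format_faers_date <- function(d) {
  out <- format(d, "%Y%m%d")
  out[is.na(out)] <- ""
  out
}

`%||%` <- rlang::`%||%`
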