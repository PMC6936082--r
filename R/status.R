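# Core vocabulary: the three-valued Indigenous-status field, the four linked
# data sources, and the 18 five-year age bands used for standardisation.

#' Indigenous status values
#'
#' The three-valued status field carried by every source record:
#' `"aboriginal"` (Aboriginal and/or Torres Strait Islander),
#' `"non-aboriginal"`, and `"unknown"`. For rate reporting an unknown status
#' is folded into non-Aboriginal; the unrecoded value is preserved for the
#' change-origin decomposition.
#'
#' @return Character vector of the three canonical status strings.
#' @export
status_levels <- function() c("aboriginal", "non-aboriginal", "unknown")

#' Linked data sources
#'
#' The four person-linked collections: the NSW Cancer Registry (`NSWCR`),
#' the Admitted Patient Data Collection (`APDC`), the Emergency Department
#' Data Collection (`EDDC`), and the Cause of Death Unit Record File
#' (`COD_URF`).
#'
#' @return Character vector of the four source codes.
#' @export
source_levels <- function() c("NSWCR", "APDC", "EDDC", "COD_URF")

#' Enhancement method names
#'
#' @return Character vector naming the four enhancement algorithms.
#' @export
method_levels <- function() {
  c("ever", "most_recent", "weight_of_evidence", "multi_stage_median")
}

# Parse a status vector case-insensitively into the canonical strings.
# Accepts "aboriginal"/"non-aboriginal"/"non_aboriginal"/"unknown" in any
# case; anything else is an error (or NA if .na_bad).
parse_status <- function(x, .na_bad = FALSE) {
  s <- tolower(trimws(as.character(x)))
  s[s == "non_aboriginal"] <- "non-aboriginal"
  bad <- !(s %in% status_levels()) & !is.na(s)
  if (any(bad) && !.na_bad) {
    stop(sprintf("unparseable status value(s): %s",
                 paste(unique(s[bad]), collapse = ", ")), call. = FALSE)
  }
  s[bad] <- NA_character_
  s
}

parse_source <- function(x) {
  s <- toupper(trimws(as.character(x)))
  s[s %in% c("COD", "COD-URF", "COD URF")] <- "COD_URF"
  bad <- !(s %in% source_levels())
  if (any(bad)) {
    stop(sprintf("unknown source value(s): %s",
                 paste(unique(s[bad]), collapse = ", ")), call. = FALSE)
  }
  s
}

#' Five-year age bands
#'
#' Labels for the 18 five-year age bands 0-4, 5-9, ..., 80-84, 85+ used for
#' direct age-standardisation.
#'
#' @return Character vector of 18 band labels.
#' @export
age_band_levels <- function() {
  c(paste(seq(0, 80, 5), seq(4, 84, 5), sep = "-"), "85+")
}

#' Map an age in years to its five-year band
#'
#' @param age Numeric vector of non-negative ages in completed years.
#' @return Factor over [age_band_levels()]; ages of 85 and over map to `"85+"`.
#' @examples
#' age_to_band(c(0, 4, 5, 67, 85, 101))
#' @export
age_to_band <- function(age) {
  if (any(age < 0, na.rm = TRUE)) stop("ages must be non-negative", call. = FALSE)
  idx <- pmin(age %/% 5, 17L)
  factor(age_band_levels()[idx + 1L], levels = age_band_levels())
}

# Validate a records data frame against the schema
# (person_id, source, event_date, status); returns it normalised.
as_records <- function(records) {
  need <- c("person_id", "source", "event_date", "status")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(sprintf("records are missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  records$person_id <- as.character(records$person_id)
  records$source <- parse_source(records$source)
  records$status <- parse_status(records$status)
  if (!inherits(records$event_date, "Date")) {
    records$event_date <- as.Date(records$event_date)
  }
  records
}
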