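# The four status-enhancement algorithms plus the precedence and
# change-eligibility rules. A person recorded as Aboriginal on the cancer
# registry or on a death certificate is accepted as Aboriginal outright;
# enhancement only ever changes persons recorded as non-Aboriginal or with
# unknown status, and only ever towards Aboriginal.

#' Extract units of information from one person's records
#'
#' A unit of information is a single record whose status is known (not
#' `"unknown"`), drawn from the sources that contribute evidence. Units are
#' ordered by event date ascending, with ties broken by the fixed source
#' order APDC < EDDC < COD_URF and then input order.
#'
#' @param records Data frame of one person's records with columns
#'   `source`, `event_date`, `status` (a `person_id` column is allowed and
#'   ignored).
#' @param unit_sources Sources whose records count as units. Defaults to the
#'   three non-registry collections; the registry status is the quantity
#'   being corrected and is excluded by default.
#' @return Data frame with columns `source`, `event_date`, `status`
#'   (`"aboriginal"`/`"non-aboriginal"` only), possibly zero rows.
#' @examples
#' r <- data.frame(
#'   source = c("APDC", "APDC", "EDDC"),
#'   event_date = as.Date(c("2012-03-01", "2010-05-20", "2011-01-01")),
#'   status = c("aboriginal", "unknown", "non-aboriginal")
#' )
#' extract_units(r)
#' @export
extract_units <- function(records, unit_sources = c("APDC", "EDDC", "COD_URF")) {
  unit_sources <- parse_source(unit_sources)
  if (!all(unit_sources %in% c("APDC", "EDDC", "COD_URF"))) {
    stop("unit_sources must be a subset of APDC, EDDC, COD_URF", call. = FALSE)
  }
  if (nrow(records) == 0L) {
    return(data.frame(source = character(), event_date = as.Date(character()),
                      status = character()))
  }
  src <- parse_source(records$source)
  st <- parse_status(records$status)
  keep <- src %in% unit_sources & st != "unknown"
  u <- data.frame(source = src[keep],
                  event_date = as.Date(records$event_date)[keep],
                  status = st[keep],
                  stringsAsFactors = FALSE)
  src_rank <- match(u$source, c("APDC", "EDDC", "COD_URF"))
  u[order(u$event_date, src_rank, seq_len(nrow(u))), , drop = FALSE]
}

#' Apply the precedence rule
#'
#' A person recorded as Aboriginal on the cancer registry, or as Aboriginal
#' on any cause-of-death record, is considered Aboriginal regardless of
#' other evidence. Everyone else is eligible for algorithmic enhancement.
#'
#' @param nswcr_status The person-level registry status (one of
#'   [status_levels()]).
#' @param records Data frame of the person's records (only `COD_URF` rows
#'   are consulted).
#' @return List with elements `eligible` (logical) and `forced_status`
#'   (`"aboriginal"` or `NA`).
#' @export
apply_precedence <- function(nswcr_status, records) {
  nswcr_status <- parse_status(nswcr_status)
  cod_ab <- FALSE
  if (nrow(records) > 0L) {
    src <- parse_source(records$source)
    st <- parse_status(records$status)
    cod_ab <- any(src == "COD_URF" & st == "aboriginal")
  }
  if (identical(nswcr_status, "aboriginal") || cod_ab) {
    list(eligible = FALSE, forced_status = "aboriginal")
  } else {
    list(eligible = TRUE, forced_status = NA_character_)
  }
}

# The weight-of-evidence classification rule on unit counts:
# Aboriginal iff (>=3 units and >=2 Aboriginal) or (1-2 units and >=1
# Aboriginal). Vectorised; zero units -> FALSE (caller falls back to base).
woe_rule <- function(n_units, n_aboriginal) {
  (n_units >= 3L & n_aboriginal >= 2L) |
    (n_units >= 1L & n_units <= 2L & n_aboriginal >= 1L)
}

fold_unknown <- function(status) {
  ifelse(status == "aboriginal", "aboriginal", "non-aboriginal")
}

#' Ever-reported rule
#'
#' Classifies a person Aboriginal if any unit of information records them as
#' Aboriginal; with no units the (unknown-folded) base status is retained.
#'
#' @param units Data frame from [extract_units()].
#' @param base_status The registry status used as fallback.
#' @return `"aboriginal"` or `"non-aboriginal"`.
#' @export
ever_reported <- function(units, base_status = "unknown") {
  if (nrow(units) == 0L) return(fold_unknown(parse_status(base_status)))
  if (any(units$status == "aboriginal")) "aboriginal" else
    fold_unknown(parse_status(base_status))
}

#' Most-recent-record rule
#'
#' Classifies a person by the status of their latest-dated unit of
#' information. When several units share the latest date the person is
#' classified Aboriginal if any of the tied units is Aboriginal. With no
#' units the base status is retained.
#'
#' @inheritParams ever_reported
#' @return `"aboriginal"` or `"non-aboriginal"`.
#' @export
most_recent <- function(units, base_status = "unknown") {
  if (nrow(units) == 0L) return(fold_unknown(parse_status(base_status)))
  latest <- units[units$event_date == max(units$event_date), , drop = FALSE]
  if (any(latest$status == "aboriginal")) "aboriginal" else "non-aboriginal"
}

#' Weight-of-evidence rule
#'
#' Classifies a person Aboriginal if there are three or more units of
#' information of which at least two are Aboriginal, or one or two units of
#' which at least one is Aboriginal; otherwise the (unknown-folded) base
#' status is retained.
#'
#' @inheritParams ever_reported
#' @return `"aboriginal"` or `"non-aboriginal"`.
#' @export
weight_of_evidence <- function(units, base_status = "unknown") {
  n <- nrow(units)
  n_ab <- sum(units$status == "aboriginal")
  if (n > 0L && woe_rule(n, n_ab)) "aboriginal" else
    fold_unknown(parse_status(base_status))
}

#' Multi-stage-median rule
#'
#' Applies the weight-of-evidence rule in two stages: first within each
#' source dataset that contributed at least one unit, yielding one
#' dataset-level unit per such source; then across those dataset-level
#' units. Sources with no units contribute nothing; with no units anywhere
#' the base status is retained.
#'
#' @inheritParams ever_reported
#' @return `"aboriginal"` or `"non-aboriginal"`.
#' @export
multi_stage_median <- function(units, base_status = "unknown") {
  if (nrow(units) == 0L) return(fold_unknown(parse_status(base_status)))
  stage1 <- vapply(split(units$status, units$source), function(s) {
    woe_rule(length(s), sum(s == "aboriginal"))
  }, logical(1))
  if (woe_rule(length(stage1), sum(stage1))) "aboriginal" else
    fold_unknown(parse_status(base_status))
}

#' Enhance Indigenous status across a linked cohort
#'
#' The central constructor of the package. Takes the full linked record set,
#' derives each person's registry status, applies the precedence rule, and
#' for eligible persons applies the requested enhancement algorithms to the
#' units of information. Returns a classed object carrying one final binary
#' status per person per method.
#'
#' @param records Data frame of source records with columns `person_id`,
#'   `source`, `event_date`, `status`.
#' @param persons Optional character vector of person identifiers defining
#'   the cohort; defaults to every person appearing in `records`. Persons
#'   with no records receive unknown base status and are reported
#'   non-Aboriginal under every method. Must not contain duplicates.
#' @param methods Which of the four algorithms to run; see
#'   [method_levels()].
#' @param unit_sources Sources contributing units of information; see
#'   [extract_units()].
#' @return An object of class `"enhancement"`: a data frame with one row per
#'   person and columns `person_id`, `base_status` (three-valued registry
#'   status), one binary final-status column per method, and per-method
#'   `changed_<method>` / `origin_<method>` columns recording whether the
#'   status was changed to Aboriginal and from which base value
#'   (`"from_non_aboriginal"`, `"from_unknown"`, `"not_changed"`).
#' @examples
#' r <- data.frame(
#'   person_id = c("p1", "p1", "p2"),
#'   source = c("NSWCR", "APDC", "NSWCR"),
#'   event_date = as.Date(c("2012-01-01", "2013-06-01", "2011-01-01")),
#'   status = c("non-aboriginal", "aboriginal", "aboriginal")
#' )
#' e <- enhance(r)
#' summary(e)
#' @export
enhance <- function(records, persons = NULL,
                    methods = method_levels(),
                    unit_sources = c("APDC", "EDDC", "COD_URF")) {
  records <- as_records(records)
  methods <- match.arg(methods, method_levels(), several.ok = TRUE)
  unit_sources <- parse_source(unit_sources)
  if (!all(unit_sources %in% c("APDC", "EDDC", "COD_URF"))) {
    stop("unit_sources must be a subset of APDC, EDDC, COD_URF", call. = FALSE)
  }
  if (is.null(persons)) {
    persons <- unique(records$person_id)
  } else {
    persons <- as.character(persons)
    dup <- unique(persons[duplicated(persons)])
    if (length(dup)) {
      stop(sprintf("duplicate person_id in cohort: %s",
                   paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
    }
  }
  n <- length(persons)
  pid <- factor(records$person_id, levels = persons)
  records <- records[!is.na(pid), , drop = FALSE]
  pid <- pid[!is.na(pid)]

  # person-level registry status: positive identification wins, then
  # non-aboriginal, then unknown (absent registry record -> unknown)
  is_reg <- records$source == "NSWCR"
  reg_ab <- tabulate(pid[is_reg & records$status == "aboriginal"], n) > 0L
  reg_known <- tabulate(pid[is_reg & records$status != "unknown"], n) > 0L
  reg_any <- tabulate(pid[is_reg], n) > 0L
  base_status <- rep("unknown", n)
  base_status[reg_any & reg_known & !reg_ab] <- "non-aboriginal"
  base_status[reg_ab] <- "aboriginal"

  cod_ab <- tabulate(pid[records$source == "COD_URF" &
                           records$status == "aboriginal"], n) > 0L
  forced <- base_status == "aboriginal" | cod_ab

  # unit tallies
  is_unit <- records$source %in% unit_sources & records$status != "unknown"
  upid <- pid[is_unit]
  uab <- records$status[is_unit] == "aboriginal"
  n_units <- tabulate(upid, n)
  n_ab <- tabulate(upid[uab], n)

  out <- data.frame(person_id = persons, base_status = base_status,
                    stringsAsFactors = FALSE)
  folded <- fold_unknown(base_status)

  res <- list()
  if ("ever" %in% methods) {
    res$ever <- ifelse(n_units > 0L, ifelse(n_ab > 0L, "aboriginal",
                                            "non-aboriginal"), folded)
  }
  if ("most_recent" %in% methods) {
    mr <- folded
    if (any(is_unit)) {
      ud <- as.numeric(records$event_date[is_unit])
      if (anyNA(ud)) {
        stop("records contributing units must carry an event_date",
             call. = FALSE)
      }
      dmax <- rep(-Inf, n)
      agg <- tapply(ud, upid, max)
      dmax[!is.na(agg)] <- agg[!is.na(agg)]
      tied_ab <- tabulate(upid[uab & ud == dmax[as.integer(upid)]], n) > 0L
      mr[n_units > 0L] <- ifelse(tied_ab[n_units > 0L], "aboriginal",
                                 "non-aboriginal")
    }
    res$most_recent <- mr
  }
  if ("weight_of_evidence" %in% methods) {
    res$weight_of_evidence <- ifelse(n_units > 0L & woe_rule(n_units, n_ab),
                                     "aboriginal", folded)
  }
  if ("multi_stage_median" %in% methods) {
    msm <- folded
    if (any(is_unit)) {
      usrc <- records$source[is_unit]
      s_n <- tapply(uab, list(upid, usrc), length)   # persons x sources
      s_ab <- tapply(uab, list(upid, usrc), sum)
      s_res <- woe_rule(s_n, s_ab)                   # NA where no units
      m_n <- rowSums(!is.na(s_n))
      m_ab <- rowSums(s_res, na.rm = TRUE)
      msm[m_n > 0L] <- ifelse(woe_rule(m_n, m_ab)[m_n > 0L], "aboriginal",
                              "non-aboriginal")
    }
    res$multi_stage_median <- msm
  }

  for (m in methods) {
    final <- ifelse(forced, "aboriginal", res[[m]])
    changed <- final == "aboriginal" & base_status != "aboriginal"
    out[[m]] <- final
    out[[paste0("changed_", m)]] <- changed
    out[[paste0("origin_", m)]] <- ifelse(
      !changed, "not_changed",
      ifelse(base_status == "unknown", "from_unknown", "from_non_aboriginal"))
  }

  structure(out, class = c("enhancement", "data.frame"),
            methods = methods, unit_sources = unit_sources)
}

#' @export
print.enhancement <- function(x, ...) {
  cat(sprintf("Indigenous status enhancement: %d persons, methods: %s\n",
              nrow(x), paste(attr(x, "methods"), collapse = ", ")))
  cat(sprintf("Unit sources: %s\n", paste(attr(x, "unit_sources"),
                                          collapse = ", ")))
  base_ab <- sum(x$base_status == "aboriginal")
  cat(sprintf("Base (registry) Aboriginal: %d (%.1f%%)\n", base_ab,
              100 * base_ab / nrow(x)))
  for (m in attr(x, "methods")) {
    cat(sprintf("  %-20s Aboriginal: %d (+%d changed)\n", m,
                sum(x[[m]] == "aboriginal"), sum(x[[paste0("changed_", m)]])))
  }
  invisible(x)
}

#' Summarise an enhancement
#'
#' @param object An `"enhancement"` object from [enhance()].
#' @param ... Unused.
#' @return Data frame with one row per method: Aboriginal count, number of
#'   persons changed, and the change-origin decomposition (previously
#'   non-Aboriginal vs previously unknown).
#' @export
summary.enhancement <- function(object, ...) {
  methods <- attr(object, "methods")
  base_ab <- sum(object$base_status == "aboriginal")
  rows <- lapply(methods, function(m) {
    ch <- object[[paste0("changed_", m)]]
    orig <- object[[paste0("origin_", m)]]
    data.frame(method = m,
               n_aboriginal = sum(object[[m]] == "aboriginal"),
               n_changed = sum(ch),
               from_non_aboriginal = sum(orig == "from_non_aboriginal"),
               from_unknown = sum(orig == "from_unknown"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "base_aboriginal") <- base_ab
  out
}
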