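# Reporting tables: case counts and relative increases by stratifier, and
# age-standardised rates by sex scope and cancer site for the base registry
# variable and each enhancement method. Enhancement changes numerators
# only; Aboriginal population denominators are held fixed across methods.

# Expand an ICD-10 site specification like "C50" or "C18-C20" into the
# three-character codes it covers.
parse_site_codes <- function(spec) {
  spec <- toupper(gsub(" ", "", spec))
  parts <- strsplit(spec, ",")[[1]]
  out <- unlist(lapply(parts, function(p) {
    if (grepl("^[A-Z][0-9]{2}$", p)) return(p)
    m <- regmatches(p, regexec("^([A-Z])([0-9]{2})-([A-Z])([0-9]{2})$", p))[[1]]
    if (length(m) == 0L || m[2] != m[4]) {
      stop(sprintf("unparseable site code specification: %s", p),
           call. = FALSE)
    }
    lo <- as.integer(m[3]); hi <- as.integer(m[5])
    if (lo > hi) stop(sprintf("empty site code range: %s", p), call. = FALSE)
    sprintf("%s%02d", m[2], lo:hi)
  }))
  unique(out)
}

case_in_sites <- function(site, codes) {
  if (is.null(codes)) rep(TRUE, length(site)) else
    toupper(substr(site, 1, 3)) %in% codes
}

# Attach person-level base and enhanced statuses to a case file.
join_statuses <- function(cases, enhanced) {
  i <- match(cases$person_id, enhanced$person_id)
  if (anyNA(i)) {
    stop(sprintf("cases reference persons absent from the enhancement: %s",
                 paste(utils::head(unique(cases$person_id[is.na(i)]), 5),
                       collapse = ", ")), call. = FALSE)
  }
  cases$base_status <- enhanced$base_status[i]
  for (m in attr(enhanced, "methods")) cases[[m]] <- enhanced[[m]][i]
  cases
}

#' Case counts and relative increases by stratum
#'
#' For each level of a stratifying variable, tabulates the number of cancer
#' cases recorded Aboriginal under the base registry variable and under each
#' enhancement method, the percentage each count represents of the stratum's
#' total caseload, and the relative increase over the base count.
#'
#' @param cases Case data frame (one row per case, with `person_id` and the
#'   stratifier column).
#' @param enhanced An `"enhancement"` object from [enhance()]; person-level
#'   statuses are shared across a person's cases.
#' @param stratifier Name of the column of `cases` to stratify by, or `NULL`
#'   for a single overall row.
#' @param round_dp Decimal places for percentages (half-away-from-zero).
#' @return Data frame with one row per stratum: `stratum`, `total`,
#'   `base_n`, `base_pct`, then `<method>_n`, `<method>_pct`,
#'   `<method>_increase` for each method.
#' @export
build_count_table <- function(cases, enhanced, stratifier = NULL,
                              round_dp = 1) {
  if (!is.null(stratifier) && !stratifier %in% names(cases)) {
    stop(sprintf("unknown stratifier '%s'; available: %s", stratifier,
                 paste(names(cases), collapse = ", ")), call. = FALSE)
  }
  cases <- join_statuses(cases, enhanced)
  strata <- if (is.null(stratifier)) rep("all", nrow(cases)) else
    as.character(cases[[stratifier]])
  levs <- if (is.null(stratifier)) "all" else sort(unique(strata))
  methods <- attr(enhanced, "methods")
  rows <- lapply(levs, function(lv) {
    cc <- cases[strata == lv, , drop = FALSE]
    total <- nrow(cc)
    base_n <- sum(cc$base_status == "aboriginal")
    row <- data.frame(stratum = lv, total = total, base_n = base_n,
                      base_pct = proportion_of_total(base_n, total, round_dp),
                      stringsAsFactors = FALSE)
    for (m in methods) {
      n <- sum(cc[[m]] == "aboriginal")
      row[[paste0(m, "_n")]] <- n
      row[[paste0(m, "_pct")]] <- proportion_of_total(n, total, round_dp)
      row[[paste0(m, "_increase")]] <-
        relative_increase(base_n, n, round_dp)$pct_increase
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_rate_sites <- function() {
  data.frame(
    label = c("all_cancers", "colorectal", "lung", "melanoma", "breast",
              "cervix", "prostate"),
    codes = c(NA, "C18-C20", "C34", "C43", "C50", "C53", "C61"),
    sex = c("both", "both", "both", "both", "female", "female", "male"),
    stringsAsFactors = FALSE)
}

asr_row <- function(cases, population, standard, years, ci_method) {
  r <- direct_asr(cases, population, standard = standard, years = years,
                  ci_method = ci_method)
  c(asr = r$asr, ci_low = r$ci_low, ci_high = r$ci_high)
}

#' Age-standardised rates by site and method
#'
#' Computes directly age-standardised incidence rates per 100,000 (with 95%
#' confidence intervals) for non-Aboriginal people (base registry variable,
#' unknown folded to non-Aboriginal), for Aboriginal people under the base
#' variable, and for Aboriginal people under each enhancement method, for
#' each cancer site and sex scope. Aboriginal population denominators are
#' identical across methods; only numerators change.
#'
#' @param cases Case data frame with `person_id`, `sex`, `age_band`,
#'   `diagnosis_year`, `site` columns.
#' @param enhanced An `"enhancement"` object from [enhance()].
#' @param population Denominators with columns `sex`, `age_band`, `year`,
#'   `group`, `persons`.
#' @param standard Standard population (see [standard_population()]).
#' @param sites Data frame with columns `label`, `codes` (ICD-10
#'   specification such as `"C18-C20"`, `NA` for all sites) and `sex`
#'   (`"both"`, `"female"` or `"male"`); defaults to the all-cancers plus
#'   six-site study set.
#' @param ci_method `"gamma"` or `"normal"`.
#' @param round_dp Decimal places for the increase percentages.
#' @return Data frame with one row per site x scope: ASR and CI for the
#'   non-Aboriginal group, the base Aboriginal group, and each method, with
#'   `<method>_increase` relative to the base Aboriginal ASR.
#' @export
build_rate_table <- function(cases, enhanced, population,
                             standard = standard_population(),
                             sites = default_rate_sites(),
                             ci_method = c("gamma", "normal"),
                             round_dp = 1) {
  ci_method <- match.arg(ci_method)
  cases <- join_statuses(cases, enhanced)
  methods <- attr(enhanced, "methods")
  years <- sort(unique(cases$diagnosis_year))
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    codes <- if (is.na(sites$codes[i])) NULL else
      parse_site_codes(sites$codes[i])
    scopes <- if (sites$sex[i] == "both") c("persons", "females", "males")
      else c(female = "females", male = "males")[[sites$sex[i]]]
    for (scope in scopes) {
      sx <- switch(scope, persons = c("female", "male"), females = "female",
                   males = "male")
      cc <- cases[case_in_sites(cases$site, codes) & cases$sex %in% sx, ,
                  drop = FALSE]
      pop <- population[population$sex %in% sx, , drop = FALSE]
      pop_ab <- pop[pop$group == "aboriginal", , drop = FALSE]
      pop_non <- pop[pop$group == "non-aboriginal", , drop = FALSE]
      row <- data.frame(site = sites$label[i], scope = scope,
                        stringsAsFactors = FALSE)
      non <- asr_row(cc[cc$base_status != "aboriginal", , drop = FALSE],
                     pop_non, standard, years, ci_method)
      row[paste0("non_aboriginal_", names(non))] <- as.list(non)
      base <- asr_row(cc[cc$base_status == "aboriginal", , drop = FALSE],
                      pop_ab, standard, years, ci_method)
      row[paste0("base_", names(base))] <- as.list(base)
      for (m in methods) {
        em <- asr_row(cc[cc[[m]] == "aboriginal", , drop = FALSE],
                      pop_ab, standard, years, ci_method)
        row[paste0(m, "_", names(em))] <- as.list(em)
        row[[paste0(m, "_increase")]] <-
          relative_increase(base[["asr"]], em[["asr"]], round_dp)$pct_increase
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
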