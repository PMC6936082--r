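# Direct age-standardisation of incidence rates with gamma (Dobson-type)
# confidence intervals, plus the relative-increase and proportion helpers
# used throughout the reporting tables.

#' Load a standard population
#'
#' @param name Either `"aus2001"` (the 2001 Australian standard population,
#'   packaged with this package) or a path to a CSV file with columns
#'   `age_band` and either `persons` or `weight`.
#' @return Data frame with columns `age_band` (the 18 five-year bands) and
#'   `weight` (proportions summing to 1).
#' @export
standard_population <- function(name = "aus2001") {
  path <- if (identical(name, "aus2001")) {
    system.file("extdata", "aus_standard_population_2001.csv",
                package = "idenhance", mustWork = TRUE)
  } else name
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"age_band" %in% names(sp)) {
    stop("standard population file must have an age_band column", call. = FALSE)
  }
  if (!"weight" %in% names(sp)) {
    if (!"persons" %in% names(sp)) {
      stop("standard population file must have a persons or weight column",
           call. = FALSE)
    }
    sp$weight <- sp$persons / sum(sp$persons)
  }
  if (any(sp$weight <= 0)) stop("standard weights must be positive", call. = FALSE)
  if (abs(sum(sp$weight) - 1) > 1e-9) sp$weight <- sp$weight / sum(sp$weight)
  sp[, c("age_band", "weight")]
}

# Round half away from zero (SAS/registry convention); base round() is
# round-half-even and would not reproduce printed table percentages.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Sum population persons per age band over the observation years and
# whatever sex/group slice the caller already applied.
person_years_by_band <- function(population, years = NULL) {
  need <- c("age_band", "year", "persons")
  miss <- setdiff(need, names(population))
  if (length(miss)) {
    stop(sprintf("population is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(years)) population <- population[population$year %in% years, ,
                                                drop = FALSE]
  if (nrow(population) == 0L) stop("empty population table", call. = FALSE)
  py <- tapply(population$persons, factor(population$age_band,
                                          levels = age_band_levels()), sum)
  py[is.na(py)] <- 0
  py
}

#' Age-specific incidence rates
#'
#' Computes cases, person-years and the rate per 100,000 person-years for
#' each five-year age band. The caller supplies cases and population already
#' restricted to one group (and sex scope); person-years are the annual
#' population counts summed over the diagnosis-year range.
#'
#' @param cases Data frame of cases with an `age_band` column (values from
#'   [age_band_levels()]).
#' @param population Data frame with columns `age_band`, `year`, `persons`
#'   (already filtered to the group and sexes of interest; multiple rows per
#'   band/year are summed).
#' @param years Diagnosis years defining the person-year accumulation;
#'   defaults to the years present in `population`.
#' @return Data frame with columns `age_band`, `cases`, `person_years`,
#'   `rate` (per 100,000 person-years).
#' @examples
#' cases <- data.frame(age_band = rep("50-54", 5))
#' pop <- data.frame(age_band = "50-54", year = 2010, persons = 1e5)
#' age_specific_rates(cases, pop)
#' @export
age_specific_rates <- function(cases, population, years = NULL) {
  if (!"age_band" %in% names(cases)) {
    stop("cases must have an age_band column", call. = FALSE)
  }
  py <- person_years_by_band(population, years)
  d <- tabulate(factor(cases$age_band, levels = age_band_levels()),
                nbins = 18L)
  bad <- d > 0 & py == 0
  if (any(bad)) {
    stop(sprintf("cases present in strata with no population: %s",
                 paste(age_band_levels()[bad], collapse = ", ")),
         call. = FALSE)
  }
  rate <- ifelse(py > 0, d / py * 1e5, 0)
  data.frame(age_band = age_band_levels(), cases = d,
             person_years = as.numeric(py), rate = rate,
             stringsAsFactors = FALSE)
}

# Gamma (Dobson-type) confidence interval for a directly standardised rate.
# asr and var are on the per-100,000 scale; w_max is the largest single-case
# contribution max_i(1e5 * w_i / n_i). Exact at zero counts.
gamma_ci <- function(asr, var, w_max, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lo <- if (asr <= 0 || var <= 0) 0 else
    stats::qgamma(a, shape = asr^2 / var, scale = var / asr)
  hi_shape <- (asr + w_max)^2 / (var + w_max^2)
  hi <- stats::qgamma(1 - a, shape = hi_shape,
                      scale = (var + w_max^2) / (asr + w_max))
  c(lower = lo, upper = hi)
}

#' Directly age-standardised rate with confidence interval
#'
#' Computes the directly standardised incidence rate per 100,000
#' person-years: the standard-population-weighted sum of the age-specific
#' rates. The 95% interval uses a gamma approximation to the weighted
#' Poisson sum (the Dobson-type interval conventional in registry
#' reporting; exact at zero counts), with a normal approximation available
#' as an alternative.
#'
#' @inheritParams age_specific_rates
#' @param standard Standard population from [standard_population()]. Weights
#'   are renormalised (with a warning) over the bands present in the
#'   population table if any band is absent.
#' @param conf_level Confidence level, default 0.95.
#' @param ci_method `"gamma"` (default) or `"normal"`.
#' @return Object of class `"rate_result"`: a list with `asr`, `ci_low`,
#'   `ci_high` (per 100,000 person-years), `cases`, `person_years`,
#'   `conf_level`, `ci_method`, and the underlying `age_specific` table.
#' @examples
#' cases <- data.frame(age_band = c(rep("50-54", 10), rep("70-74", 2)))
#' pop <- rbind(
#'   data.frame(age_band = "50-54", year = 2010, persons = 50000),
#'   data.frame(age_band = "70-74", year = 2010, persons = 200000)
#' )
#' std <- data.frame(age_band = c("50-54", "70-74"), weight = c(0.6, 0.4))
#' direct_asr(cases, pop, standard = std)
#' @export
direct_asr <- function(cases, population, standard = standard_population(),
                       years = NULL, conf_level = 0.95,
                       ci_method = c("gamma", "normal")) {
  ci_method <- match.arg(ci_method)
  asp <- age_specific_rates(cases, population, years)
  w <- standard$weight[match(asp$age_band, standard$age_band)]
  w[is.na(w)] <- 0
  present <- asp$person_years > 0 & w > 0
  if (!any(present)) stop("no overlap between population and standard bands",
                          call. = FALSE)
  if (sum(w[present]) < 1 - 1e-9) {
    warning("standard weights renormalised over bands present in the population")
  }
  w <- w / sum(w[present])
  wi <- ifelse(present, 1e5 * w / asp$person_years, 0)  # per-case contribution
  asr <- sum(wi * asp$cases)
  v <- sum(wi^2 * asp$cases)
  if (ci_method == "gamma") {
    ci <- gamma_ci(asr, v, max(wi), conf_level)
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(lower = max(0, asr - z * sqrt(v)), upper = asr + z * sqrt(v))
  }
  structure(list(asr = asr, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 cases = sum(asp$cases),
                 person_years = sum(asp$person_years[present]),
                 conf_level = conf_level, ci_method = ci_method,
                 age_specific = asp),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("ASR %.1f per 100,000 (%.0f%% CI %.1f-%.1f); %d cases, %s person-years [%s]\n",
              x$asr, 100 * x$conf_level, x$ci_low, x$ci_high, x$cases,
              format(x$person_years, big.mark = ","), x$ci_method))
  invisible(x)
}

#' Relative increase of an enhanced value over its base
#'
#' @param base Base (registry-variable) count or rate; must be positive for
#'   a defined percentage.
#' @param enhanced Enhanced count or rate of the same kind.
#' @param round_dp Decimal places for the percentage, rounded half away
#'   from zero (default 1).
#' @return Data frame with columns `base`, `enhanced`, `pct_increase`
#'   (`NA` with `defined = FALSE` when `base <= 0`).
#' @examples
#' relative_increase(1329, 1920)  # 44.5
#' @export
relative_increase <- function(base, enhanced, round_dp = 1) {
  defined <- base > 0
  pct <- ifelse(defined,
                round_half_up(100 * (enhanced - base) / base, round_dp),
                NA_real_)
  data.frame(base = base, enhanced = enhanced, pct_increase = pct,
             defined = defined)
}

#' Proportion of a total as a percentage
#'
#' @param part Numerator count, `0 <= part <= total`.
#' @param total Positive denominator count.
#' @param round_dp Decimal places, rounded half away from zero (default 1).
#' @return Numeric percentage.
#' @examples
#' proportion_of_total(2703, 204948)  # 1.3
#' @export
proportion_of_total <- function(part, total, round_dp = 1) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(part < 0 | part > total)) {
    stop("part must lie between 0 and total", call. = FALSE)
  }
  round_half_up(100 * part / total, round_dp)
}
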