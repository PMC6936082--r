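# Seeded generator of person-linked multi-source status records, cancer
# cases, truth labels and population denominators. Each simulated person
# carries a latent true status; every source records it with its own
# sensitivity, false-positive and unknown-rate process, drawn independently
# per record so that within-person inconsistency -- the signal the
# enhancement algorithms exploit -- arises naturally.

default_source_params <- function() {
  list(
    NSWCR = list(mean_records_per_person = 2.0, sensitivity = 0.55,
                 false_positive_rate = 0.002, unknown_rate = 0.005,
                 date_window = as.Date(c("2010-01-01", "2014-12-31"))),
    APDC = list(mean_records_per_person = 3.0, sensitivity = 0.85,
                false_positive_rate = 0.005, unknown_rate = 0.05,
                date_window = as.Date(c("2001-07-01", "2017-12-31"))),
    EDDC = list(mean_records_per_person = 2.0, sensitivity = 0.80,
                false_positive_rate = 0.005, unknown_rate = 0.08,
                date_window = as.Date(c("2005-01-01", "2017-12-31"))),
    COD_URF = list(mean_records_per_person = 1.0, sensitivity = 0.90,
                   false_positive_rate = 0.002, unknown_rate = 0.02,
                   date_window = as.Date(c("1985-01-01", "2015-12-31")))
  )
}

# Age distribution of incident cancer cases over the 18 five-year bands:
# strongly skewed towards older ages, as in registry data.
default_age_weights <- function() {
  w <- c(0.006, 0.004, 0.004, 0.006, 0.010, 0.016, 0.024, 0.034, 0.048,
         0.068, 0.090, 0.110, 0.128, 0.136, 0.124, 0.096, 0.060, 0.036)
  w / sum(w)
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic linked-cohort
#' generator. Defaults emulate the study conditions: diagnoses in
#' 2010-2014, source coverage windows of July 2001 to December 2017
#' (admissions), January 2005 to December 2017 (emergency) and January 1985
#' to December 2015 (deaths), and a latent Aboriginal prevalence of 3%.
#' Per-source misrecording magnitudes are plausible defaults, not estimates.
#'
#' @param n_persons Number of persons (each with one incident cancer case).
#' @param prevalence_true Probability a person's latent status is Aboriginal.
#' @param sources Named list over `NSWCR`, `APDC`, `EDDC`, `COD_URF`; each
#'   element a list with `mean_records_per_person` (Poisson mean; registry
#'   and death records are capped at one per person),
#'   `sensitivity`, `false_positive_rate`, `unknown_rate` (applied before
#'   the sensitivity/false-positive draw), and `date_window` (two dates).
#'   Partial overrides are merged over the defaults.
#' @param diagnosis_years Two integers, first and last diagnosis year.
#' @param age_band_distribution Weights over the 18 five-year age bands;
#'   must sum to 1 within 1e-9.
#' @param sex_ratio Probability a person is male.
#' @param death_probability Probability a person dies within the
#'   cause-of-death window (only decedents have `COD_URF` records).
#' @param per_person_consistency Probability in `[0,1]` that a record's
#'   identification draw reuses a single person-level draw rather than an
#'   independent one, correlating recorded statuses within a person across
#'   records and sources. `0` (the default) draws every record
#'   independently, which is what lets within-person inconsistency -- the
#'   signal the enhancement algorithms exploit -- arise; `1` makes a
#'   person's known statuses fully consistent when sources share a
#'   sensitivity.
#' @param population_multiplier Background population scale: denominators
#'   are the cohort's age/sex/prevalence structure scaled by this factor.
#' @param seed Integer seed; all randomness derives from it.
#' @return Object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_persons = 20000, prevalence_true = 0.03,
                       sources = list(),
                       diagnosis_years = c(2010L, 2014L),
                       age_band_distribution = default_age_weights(),
                       sex_ratio = 0.5,
                       death_probability = 0.2,
                       per_person_consistency = 0,
                       population_multiplier = 100,
                       seed = 1L) {
  cfg <- list(n_persons = n_persons, prevalence_true = prevalence_true,
              sources = default_source_params(),
              diagnosis_years = as.integer(diagnosis_years),
              age_band_distribution = age_band_distribution,
              sex_ratio = sex_ratio, death_probability = death_probability,
              per_person_consistency = per_person_consistency,
              population_multiplier = population_multiplier,
              seed = as.integer(seed))
  for (s in names(sources)) {
    if (!s %in% source_levels()) {
      stop(sprintf("unknown source in config: %s", s), call. = FALSE)
    }
    for (f in names(sources[[s]])) {
      if (!f %in% names(cfg$sources[[s]])) {
        stop(sprintf("unknown field %s for source %s", f, s), call. = FALSE)
      }
      cfg$sources[[s]][[f]] <- sources[[s]][[f]]
    }
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("configuration error: %s must be a probability in [0,1]",
                   field), call. = FALSE)
    }
  }
  if (!is.numeric(cfg$n_persons) || cfg$n_persons < 1) {
    stop("configuration error: n_persons must be a positive integer",
         call. = FALSE)
  }
  chk_prob(cfg$prevalence_true, "prevalence_true")
  chk_prob(cfg$sex_ratio, "sex_ratio")
  chk_prob(cfg$death_probability, "death_probability")
  chk_prob(cfg$per_person_consistency %||% 0, "per_person_consistency")
  for (s in names(cfg$sources)) {
    p <- cfg$sources[[s]]
    chk_prob(p$sensitivity, paste0(s, "$sensitivity"))
    chk_prob(p$false_positive_rate, paste0(s, "$false_positive_rate"))
    chk_prob(p$unknown_rate, paste0(s, "$unknown_rate"))
    if (p$mean_records_per_person < 0) {
      stop(sprintf("configuration error: %s$mean_records_per_person must be non-negative", s),
           call. = FALSE)
    }
    dw <- as.Date(p$date_window)
    if (length(dw) != 2L || anyNA(dw) || dw[1] >= dw[2]) {
      stop(sprintf("configuration error: %s$date_window must be a non-degenerate [start, end]", s),
           call. = FALSE)
    }
    cfg$sources[[s]]$date_window <- dw
  }
  if (length(cfg$diagnosis_years) != 2L ||
      cfg$diagnosis_years[1] > cfg$diagnosis_years[2]) {
    stop("configuration error: diagnosis_years must be [first, last]",
         call. = FALSE)
  }
  w <- cfg$age_band_distribution
  if (length(w) != 18L || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("configuration error: age_band_distribution must be 18 non-negative weights summing to 1",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Cancer sites assigned to simulated cases (ICD-10 codes), with rough
# registry-like frequencies; breast and cervix restricted to females,
# prostate to males. "Other" sites keep the all-cancers total realistic.
site_table <- function() {
  data.frame(
    site = c("C50", "C61", "C18", "C19", "C20", "C34", "C43", "C53",
             "C64", "C25", "C82", "C16"),
    weight = c(0.14, 0.15, 0.06, 0.01, 0.03, 0.09, 0.11, 0.01,
               0.04, 0.03, 0.05, 0.28),
    sex = c("female", "male", "both", "both", "both", "both", "both",
            "female", "both", "both", "both", "both"),
    stringsAsFactors = FALSE
  )
}

rdates <- function(n, window) {
  window[1] + floor(stats::runif(n) * (as.numeric(window[2] - window[1]) + 1))
}

# Draw recorded statuses for n records of persons with latent status
# `true_ab` (logical): unknown with unknown_rate, otherwise aboriginal with
# sensitivity (true) or false_positive_rate (false). `u_person` is the
# person-level identification draw reused (per record, with probability
# `consistency`) to correlate statuses within a person.
draw_status <- function(true_ab, p, u_person = NULL, consistency = 0) {
  n <- length(true_ab)
  st <- rep("non-aboriginal", n)
  u <- stats::runif(n)
  if (consistency > 0 && !is.null(u_person)) {
    shared <- stats::runif(n) < consistency
    u[shared] <- u_person[shared]
  }
  p_ab <- ifelse(true_ab, p$sensitivity, p$false_positive_rate)
  st[u < p_ab] <- "aboriginal"
  st[stats::runif(n) < p$unknown_rate] <- "unknown"
  st
}

#' Simulate a person-linked multi-source cohort
#'
#' Generates, from a latent true status per person, the linked structure the
#' enhancement analysis consumes: dated status records from four sources,
#' one cancer case per person with demographic and cancer stratifiers,
#' ground-truth labels, and population denominators by sex, age band, year
#' and group. Deterministic given the configuration (which carries the
#' seed).
#'
#' @param config A [sim_config()] object.
#' @return Object of class `"sim_cohort"`: list with data frames `records`
#'   (`person_id`, `source`, `event_date`, `status`), `cases` (`case_id`,
#'   `person_id`, `diagnosis_year`, `age`, `age_band`, `sex`, `site`,
#'   `spread`, `remoteness`, `seifa_quintile`, `nswcr_status`), `truth`
#'   (`person_id`, `true_status`), and `population` (`sex`, `age_band`,
#'   `year`, `group`, `persons`), plus the `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_persons = 200, seed = 7))
#' nrow(cohort$truth)
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- validate_sim_config(config)
  n <- as.integer(config$n_persons)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  pid <- sprintf("p%07d", seq_len(n))
  true_ab <- stats::runif(n) < config$prevalence_true
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
  band <- sample(age_band_levels(), n, replace = TRUE,
                 prob = config$age_band_distribution)
  age <- match(band, age_band_levels()) * 5L - 5L +
    sample.int(5L, n, replace = TRUE) - 1L
  age[band == "85+"] <- 85L + sample.int(15L, sum(band == "85+"),
                                         replace = TRUE) - 1L
  died <- stats::runif(n) < config$death_probability
  u_person <- stats::runif(n)  # shared identification propensity
  consistency <- config$per_person_consistency %||% 0

  recs <- list()
  for (s in source_levels()) {
    p <- config$sources[[s]]
    k <- stats::rpois(n, p$mean_records_per_person)
    if (s %in% c("NSWCR", "COD_URF")) k <- pmin(k, 1L)
    if (s == "COD_URF") k[!died] <- 0L
    idx <- rep.int(seq_len(n), k)
    if (length(idx) == 0L) next
    recs[[s]] <- data.frame(
      person_id = pid[idx], source = s,
      event_date = rdates(length(idx), p$date_window),
      status = draw_status(true_ab[idx], p, u_person[idx], consistency),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  # registry person-level status for the case file
  nswcr_status <- rep("unknown", n)
  if (!is.null(recs$NSWCR)) {
    i <- match(recs$NSWCR$person_id, pid)
    nswcr_status[i] <- recs$NSWCR$status
  }

  # one incident case per person
  st <- site_table()
  site <- character(n)
  for (sx in c("female", "male")) {
    ok <- st$sex %in% c("both", sx)
    who <- sex == sx
    site[who] <- sample(st$site[ok], sum(who), replace = TRUE,
                        prob = st$weight[ok])
  }
  cases <- data.frame(
    case_id = sprintf("c%07d", seq_len(n)),
    person_id = pid,
    diagnosis_year = sample(seq(config$diagnosis_years[1],
                                config$diagnosis_years[2]), n, replace = TRUE),
    age = age, age_band = as.character(band), sex = sex, site = site,
    spread = sample(c("localised", "regional", "distant", "unknown"), n,
                    replace = TRUE, prob = c(0.40, 0.26, 0.17, 0.17)),
    remoteness = sample(c("major_cities", "inner_regional", "outer_regional",
                          "remote_very_remote"), n, replace = TRUE,
                        prob = c(0.67, 0.24, 0.08, 0.01)),
    seifa_quintile = sample(paste0("Q", 1:5), n, replace = TRUE),
    nswcr_status = nswcr_status,
    stringsAsFactors = FALSE)

  truth <- data.frame(person_id = pid,
                      true_status = ifelse(true_ab, "aboriginal",
                                           "non-aboriginal"),
                      stringsAsFactors = FALSE)

  # deterministic background denominators: expected cohort structure scaled
  # by the population multiplier, constant across years
  years <- seq(config$diagnosis_years[1], config$diagnosis_years[2])
  grid <- expand.grid(sex = c("female", "male"), age_band = age_band_levels(),
                      year = years, group = c("aboriginal", "non-aboriginal"),
                      stringsAsFactors = FALSE)
  p_sex <- ifelse(grid$sex == "male", config$sex_ratio, 1 - config$sex_ratio)
  p_band <- config$age_band_distribution[match(grid$age_band,
                                               age_band_levels())]
  p_grp <- ifelse(grid$group == "aboriginal", config$prevalence_true,
                  1 - config$prevalence_true)
  grid$persons <- round(n * config$population_multiplier *
                          p_sex * p_band * p_grp)
  structure(list(records = records, cases = cases, truth = truth,
                 population = grid, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated linked cohort: %d persons (%d truly Aboriginal), %d records, seed %d\n",
    nrow(x$truth), sum(x$truth$true_status == "aboriginal"),
    nrow(x$records), x$config$seed))
  invisible(x)
}

#' Score an enhancement against simulation truth
#'
#' Cross-tabulates each method's final binary status against the latent
#' true status and reports sensitivity, specificity, positive predictive
#' value and the enhanced prevalence. PPV is `NA` (not applicable) when no
#' person is classified Aboriginal.
#'
#' @param truth Data frame with `person_id` and `true_status`.
#' @param enhanced An `"enhancement"` object from [enhance()] over the same
#'   persons.
#' @return Data frame with one row per method and columns `method`,
#'   `sensitivity`, `specificity`, `ppv`, `prevalence_enhanced`, and the
#'   2x2 cell counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_recovery <- function(truth, enhanced) {
  miss <- setdiff(truth$person_id, enhanced$person_id)
  extra <- setdiff(enhanced$person_id, truth$person_id)
  if (length(miss) || length(extra)) {
    stop(sprintf("person sets differ; missing from enhancement: %s; missing from truth: %s",
                 paste(utils::head(miss, 5), collapse = ", "),
                 paste(utils::head(extra, 5), collapse = ", ")), call. = FALSE)
  }
  tr <- truth$true_status[match(enhanced$person_id, truth$person_id)] ==
    "aboriginal"
  rows <- lapply(attr(enhanced, "methods"), function(m) {
    pred <- enhanced[[m]] == "aboriginal"
    tp <- sum(pred & tr); fp <- sum(pred & !tr)
    fn <- sum(!pred & tr); tn <- sum(!pred & !tr)
    data.frame(method = m,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               prevalence_enhanced = (tp + fp) / length(pred),
               tp = tp, fp = fp, fn = fn, tn = tn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
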