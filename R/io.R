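# CSV readers/writers for the four schemas (UTF-8, comma, header row,
# ISO-8601 dates) and the end-to-end pipeline driver.

read_schema <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("schema error in %s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

# Line numbers reported to users are file lines (header is line 1).
report_bad_rows <- function(bad, path, what) {
  if (any(bad)) {
    lines <- which(bad) + 1L
    stop(sprintf("%d row(s) with %s in %s (lines %s)", sum(bad), what,
                 basename(path),
                 paste(utils::head(lines, 10), collapse = ", ")),
         call. = FALSE)
  }
}

#' Read source records
#'
#' Reads a records CSV with columns `person_id`, `source`, `event_date`
#' (ISO-8601) and `status`. Statuses are parsed case-insensitively into the
#' three-valued enumeration; malformed rows are reported with their file
#' line numbers.
#'
#' @param path Path to the CSV file.
#' @return Data frame of validated source records.
#' @export
read_records <- function(path) {
  df <- read_schema(path, c("person_id", "source", "event_date", "status"))
  st <- parse_status(df$status, .na_bad = TRUE)
  report_bad_rows(is.na(st) & !is.na(df$status), path, "unparseable status")
  dt <- as.Date(df$event_date, format = "%Y-%m-%d")
  report_bad_rows(is.na(dt) & nzchar(df$event_date), path,
                  "unparseable event_date")
  data.frame(person_id = df$person_id, source = parse_source(df$source),
             event_date = dt, status = st, stringsAsFactors = FALSE)
}

#' Read cancer cases
#' @param path Path to a cases CSV (`case_id`, `person_id`,
#'   `diagnosis_year`, `age`, `age_band`, `sex`, `site`, plus optional
#'   stratifiers).
#' @return Data frame of cases.
#' @export
read_cases <- function(path) {
  df <- read_schema(path, c("case_id", "person_id", "diagnosis_year",
                            "age_band", "sex", "site"))
  df$diagnosis_year <- as.integer(df$diagnosis_year)
  if ("age" %in% names(df)) df$age <- as.integer(df$age)
  bad <- !df$age_band %in% age_band_levels()
  report_bad_rows(bad, path, "invalid age_band")
  df
}

#' Read truth labels
#' @param path Path to a truth CSV (`person_id`, `true_status`).
#' @return Data frame of truth labels.
#' @export
read_truth <- function(path) {
  df <- read_schema(path, c("person_id", "true_status"))
  df$true_status <- parse_status(df$true_status)
  df
}

#' Read population denominators
#' @param path Path to a population CSV (`sex`, `age_band`, `year`,
#'   `group`, `persons`).
#' @return Data frame of population strata.
#' @export
read_population <- function(path) {
  df <- read_schema(path, c("sex", "age_band", "year", "group", "persons"))
  df$year <- as.integer(df$year)
  df$persons <- as.numeric(df$persons)
  df$group <- parse_status(df$group)
  report_bad_rows(df$persons < 0 | is.na(df$persons), path,
                  "negative or missing persons")
  df
}

write_csv_utf8 <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Write a simulated cohort to CSV files
#'
#' Writes `records.csv`, `cases.csv`, `truth.csv` and `population.csv`
#' (UTF-8, header row, ISO-8601 dates) into a directory.
#'
#' @param cohort A `"sim_cohort"` object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    records = write_csv_utf8(cohort$records, file.path(dir, "records.csv")),
    cases = write_csv_utf8(cohort$cases, file.path(dir, "cases.csv")),
    truth = write_csv_utf8(cohort$truth, file.path(dir, "truth.csv")),
    population = write_csv_utf8(cohort$population,
                                file.path(dir, "population.csv")))
  invisible(paths)
}

#' Run the end-to-end enhancement pipeline
#'
#' Drives simulate (or read) -> enhance -> count and rate tables ->
#' recovery scoring, writing every output plus a machine-readable run
#' manifest to an output directory. Deterministic given the configuration.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   * `simulate`: arguments for [sim_config()] (mutually exclusive with
#'     `inputs`);
#'   * `inputs`: paths `records`, `cases`, `population` and optionally
#'     `truth`;
#'   * `methods`, `unit_sources`, `stratifiers`, `ci_method`, `standard`
#'     (all optional with sensible defaults);
#'   * `seed` (used by simulation).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the enhancement, the tables, the recovery
#'   summary (when truth is available) and the manifest. On error, partial
#'   outputs are removed and the failing stage is named.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(p) { written <<- c(written, p); p }
  stage <- "configuration"
  result <- tryCatch({
    methods <- config$methods %||% method_levels()
    unit_sources <- config$unit_sources %||% c("APDC", "EDDC", "COD_URF")
    stratifiers <- config$stratifiers %||% c("sex", "age_band")
    ci_method <- config$ci_method %||% "gamma"
    standard <- standard_population(config$standard %||% "aus2001")

    truth <- NULL
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sim_args <- config$simulate
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      cohort <- simulate_cohort(do.call(sim_config, sim_args))
      records <- cohort$records; cases <- cohort$cases
      population <- cohort$population; truth <- cohort$truth
      note(write_cohort(cohort, out_dir))
    } else if (!is.null(config$inputs)) {
      stage <- "read"
      records <- read_records(config$inputs$records)
      cases <- read_cases(config$inputs$cases)
      population <- read_population(config$inputs$population)
      if (!is.null(config$inputs$truth)) truth <- read_truth(config$inputs$truth)
    } else {
      stop("config must provide either 'simulate' or 'inputs'", call. = FALSE)
    }

    stage <- "enhance"
    enh <- enhance(records, persons = unique(cases$person_id),
                   methods = methods, unit_sources = unit_sources)
    note(write_csv_utf8(as.data.frame(enh), file.path(out_dir, "enhanced.csv")))

    stage <- "count tables"
    count_tables <- lapply(stratifiers, function(s)
      build_count_table(cases, enh, stratifier = s))
    names(count_tables) <- stratifiers
    overall <- build_count_table(cases, enh, stratifier = NULL)
    count_tables <- c(list(overall = overall), count_tables)
    counts <- do.call(rbind, lapply(names(count_tables), function(nm) {
      cbind(stratifier = nm, count_tables[[nm]])
    }))
    note(write_csv_utf8(counts, file.path(out_dir, "count_table.csv")))

    stage <- "rate table"
    rate_table <- build_rate_table(cases, enh, population,
                                   standard = standard, ci_method = ci_method)
    note(write_csv_utf8(rate_table, file.path(out_dir, "rate_table.csv")))

    recovery <- NULL
    if (!is.null(truth)) {
      stage <- "recovery"
      recovery <- evaluate_recovery(truth, enh)
      note(write_csv_utf8(recovery, file.path(out_dir, "recovery.csv")))
    }

    stage <- "manifest"
    manifest <- list(
      package = "idenhance",
      version = as.character(utils::packageVersion("idenhance")),
      r_version = R.version.string,
      config = config,
      rows = list(records = nrow(records), cases = nrow(cases),
                  population = nrow(population),
                  truth = if (is.null(truth)) 0L else nrow(truth)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    list(enhancement = enh, count_tables = count_tables,
         rate_table = rate_table, recovery = recovery, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
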