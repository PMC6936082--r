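# Synthetic linked-cohort generator: limits, determinism, calibration,
# and recovery scoring.

noiseless_sources <- function(mean_recs = 2) {
  src <- list()
  for (s in c("NSWCR", "APDC", "EDDC", "COD_URF")) {
    src[[s]] <- list(sensitivity = 1, false_positive_rate = 0,
                     unknown_rate = 0)
  }
  src$APDC$mean_records_per_person <- mean_recs
  src$EDDC$mean_records_per_person <- mean_recs
  src$NSWCR$mean_records_per_person <- 50  # guarantees a registry record
  src
}

test_that("noiseless recording reproduces the latent status on every record", {
  co <- simulate_cohort(sim_config(n_persons = 800, prevalence_true = 0.3,
                                   sources = noiseless_sources(), seed = 5))
  truth <- co$truth$true_status[match(co$records$person_id,
                                      co$truth$person_id)]
  expect_true(all(co$records$status == truth))
})

test_that("zero prevalence with zero false positives yields no Aboriginal record", {
  src <- list(NSWCR = list(false_positive_rate = 0),
              APDC = list(false_positive_rate = 0),
              EDDC = list(false_positive_rate = 0),
              COD_URF = list(false_positive_rate = 0))
  co <- simulate_cohort(sim_config(n_persons = 500, prevalence_true = 0,
                                   sources = src, seed = 9))
  expect_false(any(co$records$status == "aboriginal"))
  expect_true(all(co$truth$true_status == "non-aboriginal"))
})

test_that("simulation is deterministic given the seed and respects structure", {
  cfg <- sim_config(n_persons = 3000, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$cases, b$cases)
  expect_identical(a$truth, b$truth)
  expect_identical(a$population, b$population)
  c2 <- simulate_cohort(sim_config(n_persons = 3000, seed = 43))
  expect_false(identical(a$records, c2$records))

  # person_id unique in truth; record dates inside per-source windows;
  # registry/death records capped at one per person
  expect_false(any(duplicated(a$truth$person_id)))
  for (s in source_levels()) {
    rs <- a$records[a$records$source == s, ]
    w <- cfg$sources[[s]]$date_window
    expect_true(all(rs$event_date >= w[1] & rs$event_date <= w[2]))
    if (s %in% c("NSWCR", "COD_URF")) {
      expect_false(any(duplicated(rs$person_id)))
    }
  }
  # case registry status equals the person's simulated registry record
  nswcr <- a$records[a$records$source == "NSWCR", ]
  i <- match(a$cases$person_id, nswcr$person_id)
  expect_equal(a$cases$nswcr_status,
               ifelse(is.na(i), "unknown", nswcr$status[i]))
  # denominators exist for every (sex, band, year, group) stratum
  expect_equal(nrow(a$population), 2 * 18 * 5 * 2)
  expect_true(all(a$population$persons >= 0))
})

test_that("registry recording frequency is within 3 SE of configured sensitivity", {
  sens <- 0.55
  src <- list(NSWCR = list(sensitivity = sens, unknown_rate = 0,
                           mean_records_per_person = 50))
  co <- simulate_cohort(sim_config(n_persons = 50000, prevalence_true = 0.05,
                                   sources = src, seed = 21))
  ab <- co$truth$person_id[co$truth$true_status == "aboriginal"]
  nswcr <- co$records[co$records$source == "NSWCR" &
                        co$records$person_id %in% ab, ]
  p_hat <- mean(nswcr$status == "aboriginal")
  se <- sqrt(sens * (1 - sens) / nrow(nswcr))
  expect_lt(abs(p_hat - sens), 3 * se)
})

test_that("per-person consistency correlates within-person statuses", {
  shared <- list(sensitivity = 0.6, false_positive_rate = 0.1,
                 unknown_rate = 0)
  mk <- function(cons) {
    src <- list(NSWCR = shared, APDC = c(shared,
                                         list(mean_records_per_person = 4)),
                EDDC = c(shared, list(mean_records_per_person = 4)),
                COD_URF = shared)
    co <- simulate_cohort(sim_config(n_persons = 2000, prevalence_true = 0.5,
                                     sources = src,
                                     per_person_consistency = cons,
                                     seed = 77))
    known <- co$records[co$records$status != "unknown", ]
    tapply(known$status == "aboriginal", known$person_id,
           function(x) length(unique(x)))
  }
  # fully shared draws with a common sensitivity: one status per person
  expect_true(all(mk(1) == 1))
  # independent draws: many persons carry conflicting statuses
  expect_gt(mean(mk(0) > 1), 0.2)
  expect_error(sim_config(per_person_consistency = 2),
               "per_person_consistency")
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(prevalence_true = 1.5), "prevalence_true")
  expect_error(sim_config(sources = list(APDC = list(sensitivity = -0.1))),
               "APDC\\$sensitivity")
  expect_error(sim_config(sources = list(EDDC = list(
    date_window = as.Date(c("2017-01-01", "2017-01-01"))))),
    "EDDC\\$date_window")
  expect_error(sim_config(age_band_distribution = rep(1, 18)),
               "age_band_distribution")
  expect_error(sim_config(n_persons = 0), "n_persons")
})

test_that("recovery scoring builds a consistent 2x2 and flags degenerate PPV", {
  co <- simulate_cohort(sim_config(n_persons = 2000, seed = 11))
  e <- enhance(co$records, persons = co$truth$person_id)
  rv <- evaluate_recovery(co$truth, e)
  expect_equal(rv$tp + rv$fp + rv$fn + rv$tn, rep(2000L, nrow(rv)))
  ok <- !is.na(rv$ppv)
  expect_true(all(rv$sensitivity >= 0 & rv$sensitivity <= 1))
  expect_true(all(rv$ppv[ok] >= 0 & rv$ppv[ok] <= 1))

  # all-non-Aboriginal truth with no false positives: PPV not applicable
  src <- list(NSWCR = list(false_positive_rate = 0),
              APDC = list(false_positive_rate = 0),
              EDDC = list(false_positive_rate = 0),
              COD_URF = list(false_positive_rate = 0))
  co0 <- simulate_cohort(sim_config(n_persons = 300, prevalence_true = 0,
                                    sources = src, seed = 2))
  e0 <- enhance(co0$records, persons = co0$truth$person_id)
  rv0 <- evaluate_recovery(co0$truth, e0)
  expect_true(all(is.na(rv0$ppv)))
  expect_true(all(rv0$specificity == 1))

  expect_error(evaluate_recovery(co$truth[-1, ], e), "person sets differ")
})
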