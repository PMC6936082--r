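# Unit extraction, precedence, and the four classification rules.

test_that("extract_units drops unknowns and orders by date then source", {
  r <- recs(rec(date = "2012-03-01", status = "aboriginal"),
            rec(date = "2010-05-20", status = "unknown"),
            rec(date = "2011-01-01", source = "EDDC",
                status = "non-aboriginal"))
  u <- extract_units(r)
  expect_equal(nrow(u), 2L)
  expect_equal(u$status, c("non-aboriginal", "aboriginal"))

  # same-date tie broken by fixed source order APDC < EDDC < COD_URF
  r2 <- recs(rec(source = "COD_URF", date = "2011-01-01"),
             rec(source = "APDC", date = "2011-01-01"),
             rec(source = "EDDC", date = "2011-01-01"))
  expect_equal(extract_units(r2)$source, c("APDC", "EDDC", "COD_URF"))

  expect_equal(nrow(extract_units(rec()[0, ])), 0L)
  # registry records never contribute units by default
  expect_equal(nrow(extract_units(rec(source = "NSWCR"))), 0L)
  expect_error(extract_units(rec(), unit_sources = "NSWCR"), "subset")
})

test_that("precedence forces Aboriginal from registry or death certificate", {
  expect_equal(apply_precedence("aboriginal",
                                rec(status = "non-aboriginal"))$forced_status,
               "aboriginal")
  p <- apply_precedence("non-aboriginal",
                        rec(source = "COD_URF", status = "aboriginal"))
  expect_false(p$eligible)
  expect_equal(p$forced_status, "aboriginal")
  expect_true(apply_precedence("unknown", rec()[0, ])$eligible)
  # an Aboriginal admission record alone does not force
  expect_true(apply_precedence("non-aboriginal",
                               rec(source = "APDC",
                                   status = "aboriginal"))$eligible)
})

test_that("ever/most-recent/weight-of-evidence rules match their definitions", {
  u3 <- extract_units(recs(
    rec(date = "2010-01-01", status = "non-aboriginal"),
    rec(date = "2011-01-01", status = "non-aboriginal"),
    rec(date = "2012-01-01", status = "aboriginal")))
  expect_equal(ever_reported(u3, "non-aboriginal"), "aboriginal")
  expect_equal(ever_reported(u3[0, ], "unknown"), "non-aboriginal")
  expect_equal(ever_reported(u3[1, ], "non-aboriginal"), "non-aboriginal")

  u2 <- extract_units(recs(rec(date = "2011-06-01", status = "aboriginal"),
                           rec(date = "2015-06-01",
                               status = "non-aboriginal")))
  expect_equal(most_recent(u2, "non-aboriginal"), "non-aboriginal")
  tie <- extract_units(recs(rec(date = "2015-06-01", status = "aboriginal"),
                            rec(date = "2015-06-01",
                                status = "non-aboriginal")))
  expect_equal(most_recent(tie, "non-aboriginal"), "aboriginal")
  expect_equal(most_recent(u2[0, ], "non-aboriginal"), "non-aboriginal")

  # 1 of 3 Aboriginal -> not enough; 1 of 2 -> enough; 2 of 4 -> enough
  expect_equal(weight_of_evidence(u3, "non-aboriginal"), "non-aboriginal")
  expect_equal(weight_of_evidence(u2, "non-aboriginal"), "aboriginal")
  u4 <- extract_units(recs(rec(status = "aboriginal"),
                           rec(status = "aboriginal"),
                           rec(status = "non-aboriginal"),
                           rec(status = "non-aboriginal")))
  expect_equal(weight_of_evidence(u4, "non-aboriginal"), "aboriginal")
  expect_equal(weight_of_evidence(u4[0, ], "unknown"), "non-aboriginal")
})

test_that("multi-stage median diverges from pooled weight of evidence", {
  u <- extract_units(recs(
    rec(source = "APDC", date = "2010-01-01", status = "aboriginal"),
    rec(source = "EDDC", date = "2010-02-01", status = "non-aboriginal"),
    rec(source = "EDDC", date = "2010-03-01", status = "non-aboriginal"),
    rec(source = "EDDC", date = "2010-04-01", status = "non-aboriginal")))
  # stage 1: APDC -> Aboriginal, EDDC -> non-Aboriginal; stage 2: 1 of 2
  expect_equal(multi_stage_median(u, "non-aboriginal"), "aboriginal")
  expect_equal(weight_of_evidence(u, "non-aboriginal"), "non-aboriginal")

  # single source: identical to pooled weight of evidence
  u1 <- extract_units(recs(rec(date = "2010-01-01", status = "aboriginal"),
                           rec(date = "2010-02-01",
                               status = "non-aboriginal")))
  expect_equal(multi_stage_median(u1, "non-aboriginal"),
               weight_of_evidence(u1, "non-aboriginal"))
})

test_that("enhance() applies precedence first and tracks change origin", {
  r <- recs(
    rec("a", "NSWCR", "2012-01-01", "aboriginal"),
    rec("a", "APDC", "2013-01-01", "non-aboriginal"),
    rec("b", "NSWCR", "2012-01-01", "non-aboriginal"),
    rec("b", "APDC", "2013-01-01", "aboriginal"),
    rec("c", "NSWCR", "2012-01-01", "unknown"),
    rec("c", "EDDC", "2013-01-01", "aboriginal"),
    rec("d", "NSWCR", "2012-01-01", "non-aboriginal"))
  e <- enhance(r, persons = c("a", "b", "c", "d", "e"))
  expect_s3_class(e, "enhancement")
  expect_equal(e$base_status, c("aboriginal", "non-aboriginal", "unknown",
                                "non-aboriginal", "unknown"))
  for (m in method_levels()) {
    # registry Aboriginal never changes; single Aboriginal unit changes
    # under every method
    expect_equal(e[[m]][1], "aboriginal")
    expect_false(e[[paste0("changed_", m)]][1])
    expect_equal(e[[m]][2], "aboriginal")
    expect_equal(e[[paste0("origin_", m)]][2], "from_non_aboriginal")
    expect_equal(e[[paste0("origin_", m)]][3], "from_unknown")
    # no evidence: unknown folds to non-Aboriginal
    expect_equal(e[[m]][4], "non-aboriginal")
    expect_equal(e[[m]][5], "non-aboriginal")
  }
  s <- summary(e)
  expect_equal(s$n_changed, s$from_non_aboriginal + s$from_unknown)
  expect_error(enhance(r, persons = c("a", "a")), "duplicate")
})

test_that("vectorised cohort path agrees with per-person rules on random cohorts", {
  set.seed(101)
  for (rep in 1:3) {
    n_per <- 60
    rows <- list()
    for (i in seq_len(n_per)) {
      k <- sample(0:6, 1)
      if (stats::runif(1) < 0.7) {
        rows[[length(rows) + 1]] <- rec(sprintf("p%02d", i), "NSWCR",
                                        "2012-01-01",
                                        sample(status_levels(), 1))
      }
      if (k > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          person_id = sprintf("p%02d", i),
          source = sample(c("APDC", "EDDC", "COD_URF"), k, replace = TRUE),
          event_date = as.Date("2005-01-01") + sample(0:4000, k),
          status = sample(status_levels(), k, replace = TRUE,
                          prob = c(0.3, 0.5, 0.2)),
          stringsAsFactors = FALSE)
      }
    }
    r <- do.call(rbind, rows)
    persons <- sprintf("p%02d", seq_len(n_per))
    e <- enhance(r, persons = persons)
    for (i in seq_len(n_per)) {
      ri <- r[r$person_id == persons[i], , drop = FALSE]
      u <- extract_units(ri)
      reg <- ri$status[ri$source == "NSWCR"]
      base <- if (length(reg) == 0) "unknown" else reg[1]
      pr <- apply_precedence(base, ri)
      expected <- function(rule) {
        if (!pr$eligible) "aboriginal" else rule(u, base)
      }
      j <- match(persons[i], e$person_id)
      expect_equal(e$ever[j], expected(ever_reported))
      expect_equal(e$most_recent[j], expected(most_recent))
      expect_equal(e$weight_of_evidence[j], expected(weight_of_evidence))
      expect_equal(e$multi_stage_median[j], expected(multi_stage_median))
    }
  }
})
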