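# Shared fixtures: record builders and an independently written scalar
# evaluator of the four classification rules, used as the oracle against
# which the package implementation is checked.

rec <- function(person = "p1", source = "APDC", date = "2010-01-01",
                status = "aboriginal") {
  data.frame(person_id = person, source = source,
             event_date = as.Date(date), status = status,
             stringsAsFactors = FALSE)
}

recs <- function(...) do.call(rbind, list(...))

# Scalar, loop-based rule evaluator. `units` is a data.frame with columns
# source, event_date, status (no unknowns); `base` the registry status.
oracle_classify <- function(method, units, base) {
  base_bin <- if (identical(base, "aboriginal")) "aboriginal" else "non-aboriginal"
  n <- nrow(units)
  if (n == 0L) return(base_bin)
  k <- 0L
  for (i in seq_len(n)) if (units$status[i] == "aboriginal") k <- k + 1L
  woe <- function(nn, kk) (nn >= 3 && kk >= 2) || ((nn == 1 || nn == 2) && kk >= 1)
  switch(method,
    ever = if (k >= 1) "aboriginal" else base_bin,
    most_recent = {
      dmax <- max(units$event_date)
      tied_ab <- FALSE
      for (i in seq_len(n)) {
        if (units$event_date[i] == dmax && units$status[i] == "aboriginal")
          tied_ab <- TRUE
      }
      if (tied_ab) "aboriginal" else "non-aboriginal"
    },
    weight_of_evidence = if (woe(n, k)) "aboriginal" else base_bin,
    multi_stage_median = {
      m <- 0L; mk <- 0L
      for (s in unique(units$source)) {
        ss <- units$status[units$source == s]
        m <- m + 1L
        if (woe(length(ss), sum(ss == "aboriginal"))) mk <- mk + 1L
      }
      if (woe(m, mk)) "aboriginal" else base_bin
    })
}

# Enumerate every multiset of units of size <= max_n over the three
# contributing sources and two known statuses: a data.frame of counts per
# (source, status) cell.
enumerate_unit_multisets <- function(max_n) {
  cells <- expand.grid(source = c("APDC", "EDDC", "COD_URF"),
                       status = c("aboriginal", "non-aboriginal"),
                       stringsAsFactors = FALSE)
  counts <- expand.grid(rep(list(0:max_n), 6))
  counts <- counts[rowSums(counts) <= max_n, , drop = FALSE]
  list(cells = cells, counts = as.matrix(counts))
}

# Build the unit data.frame for row i of an enumeration, with distinct
# ascending dates (or one shared date when tie_dates is TRUE).
units_from_counts <- function(cells, cnt, tie_dates = FALSE) {
  idx <- rep.int(seq_len(nrow(cells)), cnt)
  n <- length(idx)
  if (n == 0L) {
    return(data.frame(source = character(), event_date = as.Date(character()),
                      status = character()))
  }
  dates <- if (tie_dates) rep(as.Date("2012-06-01"), n) else
    as.Date("2010-01-01") + seq_len(n)
  data.frame(source = cells$source[idx], event_date = dates,
             status = cells$status[idx], stringsAsFactors = FALSE)
}
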