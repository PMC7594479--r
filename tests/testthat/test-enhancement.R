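test_that("era_rule matches its stated thresholds and rejects invalid counts", {
  expect_equal(as.character(era_rule(3, 2)), "aboriginal")
  expect_equal(as.character(era_rule(1, 1)), "aboriginal")
  expect_equal(as.character(era_rule(5, 1)), "non_aboriginal")
  expect_equal(as.character(era_rule(0, 0)), "non_aboriginal")
  expect_error(era_rule(2, 3), "exceeds")
  expect_error(era_rule(-1, 0), "non-negative")

  # brute-force enumeration over every unit vector up to length 8: apply the
  # written rule to the vector itself and compare with the vectorised rule
  for (n in 0:8) {
    for (a in 0:n) {
      units <- rep(c(TRUE, FALSE), c(a, n - a))
      expected <- if (length(units) >= 3) {
        sum(units) >= 2
      } else {
        length(units) >= 1 && sum(units) >= 1
      }
      expect_equal(
        as.character(era_rule(n, a)),
        if (expected) "aboriginal" else "non_aboriginal",
        info = sprintf("n=%d a=%d", n, a)
      )
    }
  }
})

test_that("per-person rules match hand-worked examples", {
  A <- "aboriginal"
  N <- "non_aboriginal"
  status_of <- function(d) as.character(d$status)

  # ERA over records
  expect_equal(status_of(derive_era(flags_records(c(A, A, N, N)))), A)
  expect_equal(status_of(derive_era(flags_records(c(A, N)))), A)
  all_missing <- derive_era(flags_records(c("missing", "missing")))
  expect_equal(status_of(all_missing), N)
  expect_equal(all_missing$n_units, 0L)

  # MSM: APDC (A,N,N) -> N, EDDC (A) -> A, PDC (A) -> A; stage 2 era(3,2) -> A
  msm_recs <- dplyr::bind_rows(
    flags_records(c(A, N, N), "APDC"),
    flags_records(A, "EDDC"),
    flags_records(A, "PDC")
  )
  d <- derive_msm(msm_recs)
  expect_equal(status_of(d), A)
  expect_equal(d$n_units, 3L) # collections with evidence
  expect_equal(d$n_aboriginal_units, 2L)
  five_neg <- dplyr::bind_rows(lapply(
    c("APDC", "EDDC", "PDC", "RBDM", "CODURF"),
    function(cl) flags_records(N, cl)
  ))
  expect_equal(status_of(derive_msm(five_neg)), N)

  # ever / always reported
  expect_equal(status_of(derive_ever_reported(flags_records(c(N, N, A)))), A)
  expect_equal(status_of(derive_ever_reported(flags_records(c(N, N)))), N)
  expect_equal(status_of(derive_ever_reported(flags_records("missing"))), N)
  expect_equal(status_of(derive_always_reported(flags_records(c(A, A, A)))), A)
  expect_equal(status_of(derive_always_reported(flags_records(c(A, N)))), N)
  expect_equal(status_of(derive_always_reported(flags_records(c(A, "missing")))), A)

  # most recent / index record, including the date tie-break
  two_dates <- flags_records(c(A, N), dates = as.Date(c("2014-01-01", "2015-06-30")))
  expect_equal(status_of(derive_most_recent(two_dates)), N)
  expect_equal(status_of(derive_index_record(two_dates)), A)
  expect_equal(status_of(derive_most_recent(flags_records(A))), A)
  tie <- dplyr::bind_rows(
    rec_row("P1", "CODURF", "2015-01-01", N),
    rec_row("P1", "APDC", "2015-01-01", A)
  )
  expect_equal(status_of(derive_most_recent(tie)), A) # APDC priority wins
  tie2 <- dplyr::bind_rows(
    rec_row("P1", "CODURF", "2015-01-01", A),
    rec_row("P1", "APDC", "2015-01-01", N)
  )
  expect_equal(status_of(derive_most_recent(tie2)), N)
  expect_equal(status_of(derive_index_record(tie)), A)

  # majority of public hospital admissions (APDC only by default)
  expect_equal(status_of(derive_majority(flags_records(c(A, N)))), A) # exactly 50%
  expect_equal(status_of(derive_majority(flags_records(c(A, N, N)))), N)
  expect_equal(status_of(derive_majority(flags_records(A, "PDC"))), N) # no APDC
  expect_equal(status_of(derive_majority(flags_records(A, "PDC"), majority_scope = "all")), A)

  # at least two hospitals (distinct APDC/EDDC facilities)
  two_fac <- dplyr::bind_rows(
    rec_row("P1", "APDC", flag = A, facility_id = "H1"),
    rec_row("P1", "EDDC", flag = A, facility_id = "H2")
  )
  expect_equal(status_of(derive_two_hospitals(two_fac)), A)
  one_fac <- flags_records(c(A, A, A), facility_id = "H1")
  expect_equal(status_of(derive_two_hospitals(one_fac)), N)
  with_pdc <- dplyr::bind_rows(
    rec_row("P1", "APDC", flag = A, facility_id = "H1"),
    rec_row("P1", "PDC", flag = A)
  )
  expect_equal(status_of(derive_two_hospitals(with_pdc)), N) # non-hospital excluded

  # as recorded: only the sampled record counts
  samp <- dplyr::bind_rows(
    rec_row("P1", "APDC", flag = A, is_sampled = TRUE),
    flags_records(rep(N, 10), "EDDC")
  )
  expect_equal(status_of(derive_as_recorded(samp)), A)
  samp$flag[1] <- N
  expect_equal(status_of(derive_as_recorded(samp)), N)
  expect_error(derive_as_recorded(flags_records(c(A, N))), "sampled")
  samp$flag[1] <- "missing"
  expect_error(derive_as_recorded(samp), "sampled")

  # rules reject multi-person input
  expect_error(
    derive_era(dplyr::bind_rows(flags_records(A, person_id = "P1"), flags_records(A, person_id = "P2"))),
    "more than one person"
  )
})

test_that("derive_all covers every person-method pair and logs not-evaluable persons", {
  persons <- dplyr::bind_rows(ref_row("P1"), ref_row("P2", "non_aboriginal"), ref_row("P3"))
  records <- dplyr::bind_rows(
    rec_row("P1", "APDC", flag = "aboriginal", is_sampled = TRUE),
    rec_row("P2", "PDC", flag = "non_aboriginal")
    # P3 has zero linked records
  )
  ds <- linked_dataset(persons, records)

  d <- derive_all(ds, c("era", "ever_reported"))
  expect_equal(nrow(d), 6)
  expect_setequal(as.character(unique(d$method)), c("era", "ever_reported"))

  # zero-record and zero-evidence persons derive non-Aboriginal
  expect_equal(
    as.character(d$status[d$person_id == "P3"]),
    rep("non_aboriginal", 2)
  )

  # as_recorded is not evaluable without a usable sampled record, and logged
  withr::local_options(linkenhance.verbose = TRUE)
  expect_message(
    d2 <- derive_all(ds, "as_recorded"),
    "2 person\\(s\\) not evaluable"
  )
  expect_true(is.na(d2$status[d2$person_id == "P2"]))
  expect_equal(as.character(d2$status[d2$person_id == "P1"]), "aboriginal")

  expect_equal(nrow(derive_all(ds, character())), 0)

  # row-count oracle on a simulated cohort
  sim <- simulate_cohort(small_config(2000, seed = 2))
  d3 <- derive_all(sim$dataset, "all")
  expect_equal(nrow(d3), 2000 * 9)
  expect_true(all(d3$n_aboriginal_units <= d3$n_units))
  # status = aboriginal implies at least one aboriginal unit
  pos <- d3[!is.na(d3$status) & d3$status == "aboriginal", ]
  expect_true(all(pos$n_aboriginal_units >= 1))
})
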