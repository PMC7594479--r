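test_that("confusion matrices match hand labelling on tiny datasets", {
  # one reference-Aboriginal person, two APDC records flagged (A, N)
  persons <- ref_row("P1", "aboriginal", "20-39")
  records <- dplyr::bind_rows(
    rec_row("P1", "APDC", "2014-01-01", "aboriginal", is_sampled = TRUE),
    rec_row("P1", "APDC", "2014-06-01", "non_aboriginal")
  )
  ds <- linked_dataset(persons, records)
  d <- derive_all(ds, "all")

  cm <- build_confusion(ds, d, "as_recorded", "APDC", mode = "all_records")
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(1, 0, 0, 1))

  # person-level ever-reported status applies to both records
  cm <- build_confusion(ds, d, "ever_reported", "APDC")
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(2, 0, 0, 0))

  # sampled-only mode keeps the one sampled record
  cm <- build_confusion(ds, d, "as_recorded", "APDC", mode = "sampled_only")
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(1, 0, 0, 0))

  # no records in the source -> zero matrix
  cm <- build_confusion(ds, d, "era", "EDDC")
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 0)

  # stratum restriction: the person is 20-39, so 65+ is empty
  cm <- build_confusion(ds, d, "era", "APDC", stratum = "65plus")
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 0)

  # exhaustive hand labelling on a 4-person mixed dataset
  persons <- dplyr::bind_rows(
    ref_row("P1", "aboriginal", "0-19"), # era-positive: flags (A, A, N)
    ref_row("P2", "aboriginal", "65plus"), # never identified: flags (N, N)
    ref_row("P3", "non_aboriginal", "0-19"), # misreported once: flags (A, N, N, N)
    ref_row("P4", "non_aboriginal", "65plus") # flags (N,)
  )
  records <- dplyr::bind_rows(
    flags_records(c("aboriginal", "aboriginal", "non_aboriginal"), person_id = "P1"),
    flags_records(c("non_aboriginal", "non_aboriginal"), person_id = "P2"),
    flags_records(rep(c("aboriginal", "non_aboriginal"), c(1, 3)), person_id = "P3"),
    flags_records("non_aboriginal", person_id = "P4")
  )
  ds <- linked_dataset(persons, records)
  d <- derive_all(ds, "all")
  # ERA statuses: P1 A (3 units, 2 ab), P2 N, P3 N (4 units, 1 ab), P4 N.
  # APDC record-level counts: P1 3 tp, P2 2 fn, P3 4 tn, P4 1 tn.
  cm <- build_confusion(ds, d, "era", "APDC")
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(3, 0, 5, 2))
  # ever-reported: P3 becomes positive -> its 4 records turn fp
  cm <- build_confusion(ds, d, "ever_reported", "APDC")
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(3, 4, 1, 2))
  # as-recorded all-records mode labels each record by its own flag
  cm <- build_confusion(ds, d, "as_recorded", "APDC")
  expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), c(2, 1, 4, 3))
})

test_that("rate definitions follow the standard formulas and signal undefined", {
  cm <- linkenhance:::.new_confusion(84, 10, 190, 16, "era", "APDC", "Total", "all_records")
  expect_equal(sensitivity(cm), 84)
  expect_equal(specificity(cm), 95)
  expect_equal(ppv(cm), 100 * 84 / 94)
  expect_equal(npv(cm), 100 * 190 / 206)

  cm <- linkenhance:::.new_confusion(5, 0, 3, 0, "era", "APDC", "Total", "all_records")
  expect_equal(sensitivity(cm), 100)
  cm <- linkenhance:::.new_confusion(0, 2, 3, 0, "era", "APDC", "Total", "all_records")
  expect_true(is.na(sensitivity(cm))) # tp + fn == 0: undefined, not 0
  cm <- linkenhance:::.new_confusion(0, 0, 3, 1, "era", "APDC", "Total", "all_records")
  expect_true(is.na(ppv(cm)))
  m <- validity_measures(cm)
  expect_true(is.na(m$f_score))
})

test_that("f_score is the harmonic mean of PPV and sensitivity", {
  expect_equal(round(f_score(84.4, 95.3), 2), 0.90)
  expect_equal(round(f_score(77.4, 94.7), 2), 0.85)
  expect_equal(f_score(100, 100), 1)
  expect_true(is.na(f_score(0, 0)))
  s <- c(50, 80)
  p <- c(100, 40)
  expect_equal(f_score(s, p), 2 * (s / 100) * (p / 100) / ((s + p) / 100))
})

test_that("evaluate_table lays out strata x methods and conserves counts", {
  sim <- simulate_cohort(small_config(4000, seed = 8))
  ds <- sim$dataset
  d <- derive_all(ds, "core")
  tbl <- evaluate_table(ds, d, "core")

  expect_equal(nrow(tbl), 25) # 4 age strata + Total, 5 core methods
  expect_equal(sum(tbl$age_group == "Total"), 5)

  # stratum record counts sum to the Total count for every method/source
  for (m in linkage_methods("core")) {
    sub <- tbl[tbl$method == m, ]
    for (src in c("apdc_n", "eddc_n")) {
      expect_equal(
        sum(sub[[src]][sub$age_group != "Total"]),
        sub[[src]][sub$age_group == "Total"]
      )
    }
  }

  # stratum confusion matrices sum to the Total matrix (independent path)
  tot <- build_confusion(ds, d, "era", "APDC")
  parts <- lapply(
    c("0-19", "20-39", "40-64", "65plus"),
    function(a) build_confusion(ds, d, "era", "APDC", stratum = a)
  )
  expect_equal(sum(vapply(parts, `[[`, 0L, "tp")), tot$tp)
  expect_equal(sum(vapply(parts, `[[`, 0L, "fn")), tot$fn)
  expect_equal(sum(vapply(parts, `[[`, 0L, "fp")), tot$fp)
  expect_equal(sum(vapply(parts, `[[`, 0L, "tn")), tot$tn)

  # the Total row agrees with the standalone confusion-matrix path
  row <- tbl[tbl$age_group == "Total" & tbl$method == "era", ]
  expect_equal(row$apdc_sensitivity, sensitivity(tot))
  expect_equal(row$apdc_ppv, ppv(tot))

  # record-level sensitivity ordering from the set inclusions
  tot_rows <- tbl[tbl$age_group == "Total", ]
  sens <- setNames(tot_rows$apdc_sensitivity, as.character(tot_rows$method))
  expect_gte(sens[["ever_reported"]], sens[["era"]])
  expect_gte(sens[["ever_reported"]], sens[["as_recorded"]])
})

test_that("degenerate datasets yield missing measures, never zeros", {
  persons <- ref_row("P1", "non_aboriginal", "40-64")
  ds <- linked_dataset(persons, rec_row("P1", "APDC", flag = "non_aboriginal"))
  d <- derive_all(ds, "core")
  tbl <- evaluate_table(ds, d, "core")
  row <- tbl[tbl$age_group == "Total" & tbl$method == "era", ]
  expect_true(is.na(row$apdc_sensitivity)) # no reference-positives
  expect_true(is.na(row$apdc_ppv)) # no predicted positives
  expect_equal(row$apdc_specificity, 100)
  expect_true(is.na(row$eddc_specificity)) # no EDDC records at all
  fmt <- format_validity_table(tbl)
  expect_equal(fmt$apdc_sensitivity[fmt$age_group == "Total" & fmt$method == "era"], "")
  expect_equal(fmt$apdc_specificity[fmt$age_group == "Total" & fmt$method == "era"], "100.0")
})
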