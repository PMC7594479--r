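options(linkenhance.verbose = FALSE)

## tiny-table builders -------------------------------------------------------

ref_row <- function(person_id, reference_status = "aboriginal", age_group = "20-39",
                    sex = NA_character_, remoteness = NA_character_) {
  tibble::tibble(
    person_id = person_id, reference_status = reference_status,
    age_group = age_group, sex = sex, remoteness = remoteness
  )
}

rec_row <- function(person_id, collection = "APDC", event_date = "2014-01-01",
                    flag = "non_aboriginal", facility_id = NULL, is_sampled = FALSE) {
  if (is.null(facility_id)) {
    facility_id <- if (collection %in% c("APDC", "EDDC")) "F001" else NA_character_
  }
  tibble::tibble(
    person_id = person_id, collection = collection,
    event_date = as.Date(event_date), facility_id = facility_id,
    flag = flag, is_sampled = is_sampled
  )
}

## one person's records from a vector of flags, one collection
flags_records <- function(flags, collection = "APDC", person_id = "P1",
                          dates = NULL, facility_id = NULL) {
  n <- length(flags)
  if (is.null(dates)) dates <- as.Date("2014-01-01") + seq_len(n) - 1
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    rec_row(person_id, collection, dates[i], flags[i], facility_id = facility_id)
  }))
}

small_config <- function(n_persons = 1000, seed = 1L, ...) {
  generator_config(n_persons = n_persons, seed = seed, ...)
}

## the full-size study-calibrated cohort, simulated and derived once and
## shared across test files (expensive at n = 130,514)
.cohort_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (!exists("sim", envir = .cohort_env)) {
    assign("sim", simulate_cohort(generator_config()), envir = .cohort_env)
  }
  get("sim", envir = .cohort_env)
}

default_derived <- function() {
  if (!exists("derived", envir = .cohort_env)) {
    assign("derived", derive_all(default_cohort()$dataset, "all"), envir = .cohort_env)
  }
  get("derived", envir = .cohort_env)
}

default_evaluation <- function() {
  if (!exists("evaluation", envir = .cohort_env)) {
    assign(
      "evaluation",
      evaluate_table(default_cohort()$dataset, default_derived(), "all"),
      envir = .cohort_env
    )
  }
  get("evaluation", envir = .cohort_env)
}

## positives of one method from a derive_all() table
positives <- function(derived, m) {
  d <- derived[derived$method == m & !is.na(derived$status), ]
  d$person_id[d$status == "aboriginal"]
}
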