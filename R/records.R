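## Domain containers: a linked dataset is a reference table (one row per
## person, carrying the self-reported standard and stratification
## attributes) plus a records table (one row per linked administrative
## record). Both are tibbles; the pair is held in a lightweight S3 object so
## invariants are checked once at construction.

.canonical_records <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c("person_id", "collection", "event_date", "facility_id", "flag", "is_sampled")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records$person_id <- as.character(records$person_id)
  records$collection <- factor(as.character(records$collection), levels = .collection_levels)
  records$event_date <- as.Date(records$event_date)
  records$facility_id <- as.character(records$facility_id)
  records$flag <- factor(tolower(as.character(records$flag)), levels = .flag_levels)
  records$is_sampled <- as.logical(records$is_sampled)
  records[required]
}

.canonical_persons <- function(persons) {
  persons <- tibble::as_tibble(persons)
  required <- c("person_id", "reference_status", "age_group")
  missing_cols <- setdiff(required, names(persons))
  if (length(missing_cols)) {
    stop("reference table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  persons$person_id <- as.character(persons$person_id)
  persons$reference_status <- factor(
    tolower(as.character(persons$reference_status)),
    levels = .status_levels
  )
  persons$age_group <- factor(as.character(persons$age_group), levels = .age_group_levels)
  if (!"sex" %in% names(persons)) persons$sex <- NA_character_
  if (!"remoteness" %in% names(persons)) persons$remoteness <- NA_character_
  persons$sex <- factor(tolower(as.character(persons$sex)), levels = .sex_levels)
  persons$remoteness <- factor(tolower(as.character(persons$remoteness)),
    levels = .remoteness_levels
  )
  persons[c("person_id", "reference_status", "age_group", "sex", "remoteness")]
}

#' Construct a validated linked dataset
#'
#' Bundles the per-person reference table and the per-record linked table and
#' enforces the structural invariants the derivation rules rely on: unique
#' person ids, no orphan records, valid enumeration codes, reference status
#' never missing, hospital records carrying a facility id, and at most one
#' sampled record per person (always an APDC or EDDC record).
#'
#' @param persons Data frame with columns `person_id`, `reference_status`
#'   (`"aboriginal"`/`"non_aboriginal"`), `age_group`
#'   (`"0-19"`, `"20-39"`, `"40-64"`, `"65plus"`), and optionally `sex` and
#'   `remoteness`.
#' @param records Data frame with columns `person_id`, `collection`
#'   (APDC, EDDC, PDC, RBDM, CODURF), `event_date` (Date), `facility_id`
#'   (`NA` for non-hospital collections), `flag`
#'   (`"aboriginal"`/`"non_aboriginal"`/`"missing"`), `is_sampled` (logical).
#' @return An object of class `linked_dataset`: a list with elements
#'   `persons` and `records`.
#' @export
linked_dataset <- function(persons, records) {
  persons <- .canonical_persons(persons)
  records <- .canonical_records(records)
  ds <- structure(list(persons = persons, records = records), class = "linked_dataset")
  validate_linked_dataset(ds)
  ds
}

#' Validate a linked dataset's invariants
#'
#' @param ds A `linked_dataset`.
#' @return `ds`, invisibly; errors describe the first violations found.
#' @export
validate_linked_dataset <- function(ds) {
  persons <- ds$persons
  records <- ds$records

  dup <- persons$person_id[duplicated(persons$person_id)]
  if (length(dup)) {
    stop("duplicate person_id in reference table: ", paste(head(dup, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(persons$reference_status)) {
    bad <- which(is.na(persons$reference_status))
    stop(
      "reference_status missing or unrecognised at reference row(s): ",
      paste(head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(persons$age_group)) {
    bad <- which(is.na(persons$age_group))
    stop("unknown age_group code at reference row(s): ", paste(head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }

  if (nrow(records)) {
    if (anyNA(records$collection)) {
      bad <- which(is.na(records$collection))
      stop("unknown collection code at records row(s): ", paste(head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
    if (anyNA(records$flag)) {
      bad <- which(is.na(records$flag))
      stop("unknown flag code at records row(s): ", paste(head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
    if (anyNA(records$event_date)) {
      bad <- which(is.na(records$event_date))
      stop("unparseable event_date at records row(s): ", paste(head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
    orphan <- !records$person_id %in% persons$person_id
    if (any(orphan)) {
      stop(
        "orphan record(s): person_id absent from reference table at records row(s): ",
        paste(head(which(orphan), 5), collapse = ", "),
        call. = FALSE
      )
    }
    no_fac <- is.na(records$facility_id) | records$facility_id == ""
    bad_fac <- no_fac & records$collection %in% .hospital_collections
    if (any(bad_fac)) {
      stop(
        "hospital (APDC/EDDC) record(s) without facility_id at records row(s): ",
        paste(head(which(bad_fac), 5), collapse = ", "),
        call. = FALSE
      )
    }
    samp <- records[records$is_sampled, , drop = FALSE]
    if (anyDuplicated(samp$person_id)) {
      stop("more than one sampled record for person(s): ",
        paste(head(unique(samp$person_id[duplicated(samp$person_id)]), 5), collapse = ", "),
        call. = FALSE
      )
    }
    if (nrow(samp) && !all(samp$collection %in% .hospital_collections)) {
      stop("sampled record(s) outside APDC/EDDC", call. = FALSE)
    }
  }
  invisible(ds)
}

#' @export
print.linked_dataset <- function(x, ...) {
  cat(
    "<linked_dataset> ", nrow(x$persons), " persons, ",
    nrow(x$records), " linked records\n",
    sep = ""
  )
  tab <- table(x$persons$reference_status)
  cat(
    "  reference: ", tab[["aboriginal"]], " aboriginal / ",
    tab[["non_aboriginal"]], " non-aboriginal\n",
    sep = ""
  )
  invisible(x)
}

## ---- readers / writers -----------------------------------------------------

.check_enum <- function(values, levels, what, file_label, transform = identity) {
  parsed <- transform(values)
  bad <- !is.na(values) & values != "" & !(parsed %in% levels)
  bad <- bad | is.na(values) | values == ""
  if (any(bad)) {
    rows <- head(which(bad), 5)
    stop(
      sprintf(
        "%s: invalid %s at data row(s) %s (e.g. %s)",
        file_label, what, paste(rows, collapse = ", "),
        paste(unique(head(values[bad], 3)), collapse = ", ")
      ),
      call. = FALSE
    )
  }
  parsed
}

#' Read a linked dataset from CSV files
#'
#' The records file has columns `person_id, collection, event_date,
#' facility_id, flag, is_sampled` (dates ISO-8601, `is_sampled` 0/1,
#' `facility_id` empty for non-hospital collections); the reference file has
#' `person_id, reference_status, age_group` and optionally `sex,
#' remoteness`. Enumeration codes are matched case-insensitively. Rows with
#' unparseable dates or unknown codes abort the read with the offending row
#' numbers; records whose `person_id` is absent from the reference table are
#' orphans and also abort.
#'
#' @param records_path,reference_path Paths to the two CSV files.
#' @return A validated [linked_dataset()].
#' @export
read_dataset <- function(records_path, reference_path) {
  for (p in c(records_path, reference_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  ref_raw <- readr::read_csv(reference_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  req <- c("person_id", "reference_status", "age_group")
  if (length(setdiff(req, names(ref_raw)))) {
    stop(
      "reference file lacks column(s): ",
      paste(setdiff(req, names(ref_raw)), collapse = ", "),
      call. = FALSE
    )
  }
  .check_enum(ref_raw$reference_status, .status_levels, "reference_status", "reference file", tolower)
  .check_enum(ref_raw$age_group, .age_group_levels, "age_group", "reference file")

  rec_raw <- readr::read_csv(records_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  req <- c("person_id", "collection", "event_date", "facility_id", "flag", "is_sampled")
  if (length(setdiff(req, names(rec_raw)))) {
    stop(
      "records file lacks column(s): ",
      paste(setdiff(req, names(rec_raw)), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(rec_raw)) {
    .check_enum(rec_raw$collection, .collection_levels, "collection", "records file", toupper)
    .check_enum(rec_raw$flag, .flag_levels, "flag", "records file", tolower)
    dates <- as.Date(rec_raw$event_date, format = "%Y-%m-%d")
    if (anyNA(dates)) {
      rows <- head(which(is.na(dates)), 5)
      stop("records file: unparseable event_date at data row(s) ",
        paste(rows, collapse = ", "),
        call. = FALSE
      )
    }
    .check_enum(rec_raw$is_sampled, c("0", "1"), "is_sampled", "records file")
    rec_raw$collection <- toupper(rec_raw$collection)
    rec_raw$event_date <- dates
    rec_raw$is_sampled <- rec_raw$is_sampled == "1"
    rec_raw$facility_id[!is.na(rec_raw$facility_id) & rec_raw$facility_id == ""] <- NA_character_
  } else {
    rec_raw$event_date <- as.Date(character())
    rec_raw$is_sampled <- logical()
  }

  ds <- linked_dataset(ref_raw, rec_raw)
  .log_msg(
    "read_dataset: ", nrow(ds$persons), " persons, ", nrow(ds$records),
    " records, 0 rows rejected"
  )
  ds
}

#' Write a linked dataset to CSV files
#'
#' Inverse of [read_dataset()]: flags and statuses are written as canonical
#' lowercase codes, dates as ISO-8601, `is_sampled` as 0/1 and absent
#' facility ids as empty fields, so that reading the files back reproduces
#' the dataset field-for-field.
#'
#' @param ds A `linked_dataset`.
#' @param records_path,reference_path Output CSV paths.
#' @return The two paths, invisibly.
#' @export
write_dataset <- function(ds, records_path, reference_path) {
  stopifnot(inherits(ds, "linked_dataset"))
  rec <- ds$records
  rec$is_sampled <- as.integer(rec$is_sampled)
  readr::write_csv(rec, records_path, na = "", progress = FALSE)
  readr::write_csv(ds$persons, reference_path, na = "", progress = FALSE)
  .log_msg(
    "write_dataset: wrote ", nrow(rec), " records and ",
    nrow(ds$persons), " reference rows"
  )
  invisible(c(records = records_path, reference = reference_path))
}

## ---- summary ---------------------------------------------------------------

#' Summarise a linked dataset
#'
#' Reproduces the descriptive tabulations of a linkage study: per
#' reference-status group the person and record counts, the distribution of
#' persons by linked-record count (0 / 1 / 2 / 3+), the count and percentage
#' of persons with no Aboriginal-flagged record (for reference-Aboriginal
#' persons this is the "never identified" group, the hard ceiling on any
#' linkage-based enhancement), and the share of records contributed by each
#' source collection.
#'
#' @param ds A `linked_dataset`.
#' @return A list of tibbles (`persons`, `record_count_dist`,
#'   `never_identified`, `collection_shares`) with class
#'   `linked_dataset_summary`.
#' @export
summarise_dataset <- function(ds) {
  stopifnot(inherits(ds, "linked_dataset"))
  persons <- ds$persons
  records <- ds$records

  per_person <- records |>
    dplyr::count(.data$person_id, name = "n_records")
  flagged <- records |>
    dplyr::filter(.data$flag == "aboriginal") |>
    dplyr::count(.data$person_id, name = "n_aboriginal_records")
  ptab <- persons |>
    dplyr::left_join(per_person, by = "person_id") |>
    dplyr::left_join(flagged, by = "person_id") |>
    dplyr::mutate(
      n_records = dplyr::coalesce(.data$n_records, 0L),
      n_aboriginal_records = dplyr::coalesce(.data$n_aboriginal_records, 0L)
    )

  by_status <- ptab |>
    dplyr::group_by(.data$reference_status) |>
    dplyr::summarise(
      n_persons = dplyr::n(),
      n_records = sum(.data$n_records),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_persons = 100 * .data$n_persons / sum(.data$n_persons))

  dist <- ptab |>
    dplyr::mutate(bucket = cut(.data$n_records,
      breaks = c(-Inf, 0, 1, 2, Inf),
      labels = c("0", "1", "2", "3+")
    )) |>
    dplyr::count(.data$reference_status, .data$bucket, .drop = FALSE, name = "n_persons") |>
    dplyr::group_by(.data$reference_status) |>
    dplyr::mutate(pct = 100 * .data$n_persons / sum(.data$n_persons)) |>
    dplyr::ungroup()

  never <- ptab |>
    dplyr::group_by(.data$reference_status) |>
    dplyr::summarise(
      n_persons = dplyr::n(),
      n_never_flagged = sum(.data$n_aboriginal_records == 0),
      pct_never_flagged = 100 * .data$n_never_flagged / .data$n_persons,
      .groups = "drop"
    )

  shares <- records |>
    dplyr::count(.data$collection, .drop = FALSE, name = "n_records") |>
    dplyr::mutate(pct = if (sum(.data$n_records) > 0) {
      100 * .data$n_records / sum(.data$n_records)
    } else {
      NA_real_
    })

  structure(
    list(
      persons = by_status,
      record_count_dist = dist,
      never_identified = never,
      collection_shares = shares
    ),
    class = "linked_dataset_summary"
  )
}

#' @export
print.linked_dataset_summary <- function(x, ...) {
  cat("Linked dataset summary\n\nPersons and records by reference status:\n")
  print(as.data.frame(x$persons), row.names = FALSE)
  cat("\nPersons by linked-record count:\n")
  print(as.data.frame(x$record_count_dist), row.names = FALSE)
  cat("\nPersons with no Aboriginal-flagged record:\n")
  print(as.data.frame(x$never_identified), row.names = FALSE)
  cat("\nRecord share by collection:\n")
  print(as.data.frame(x$collection_shares), row.names = FALSE)
  invisible(x)
}
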