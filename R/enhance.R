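## Derivation rules. Every rule consumes one person's linked records and
## returns a derived status plus the evidence counts it used. A "unit of
## information" is one linked record with a non-missing flag; missing flags
## carry no evidence for any rule. Persons with no usable evidence derive
## non-Aboriginal (the binary evaluation has no "unknown" class), except
## As-recorded, which is undefined without a usable sampled record.

#' Weight-of-evidence classification rule
#'
#' The core Enhanced Reporting of Aboriginality decision: with three or more
#' units of information, at least two must indicate the person is
#' Aboriginal; with one or two units, a single Aboriginal-indicating unit is
#' sufficient. Zero units derive non-Aboriginal.
#'
#' @param n_units Non-negative integer vector: units of information.
#' @param n_aboriginal Non-negative integer vector: Aboriginal-indicating
#'   units; must not exceed `n_units`.
#' @return Factor with levels `"aboriginal"`, `"non_aboriginal"`, recycled to
#'   the common length.
#' @examples
#' era_rule(3, 2) # aboriginal
#' era_rule(1, 1) # aboriginal
#' era_rule(5, 1) # non_aboriginal
#' @export
era_rule <- function(n_units, n_aboriginal) {
  if (any(n_units < 0) || any(n_aboriginal < 0)) {
    stop("unit counts must be non-negative", call. = FALSE)
  }
  if (any(n_aboriginal > n_units)) {
    stop("n_aboriginal exceeds n_units", call. = FALSE)
  }
  ab <- (n_units >= 3 & n_aboriginal >= 2) |
    (n_units >= 1 & n_units <= 2 & n_aboriginal >= 1)
  factor(ifelse(ab, "aboriginal", "non_aboriginal"), levels = .status_levels)
}

## Vectorised engine: derives one method for every person in `person_ids`
## given a records table (any number of persons). All per-person exported
## rules and derive_all() go through this single code path.
.derive_method <- function(records, person_ids, method,
                           majority_scope = "apdc", recency_scope = "all") {
  method <- match.arg(method, .method_levels)
  majority_scope <- match.arg(majority_scope, c("apdc", "all"))
  recency_scope <- match.arg(recency_scope, c("all", "hospital"))

  records <- .canonical_records(records)
  records$.row <- seq_len(nrow(records))
  ev <- records[records$flag != "missing", , drop = FALSE]
  ev$is_ab <- ev$flag == "aboriginal"

  counts_of <- function(x) {
    x |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(
        n_units = dplyr::n(),
        n_ab = sum(.data$is_ab),
        .groups = "drop"
      )
  }
  pick_extreme <- function(x, latest) {
    if (nrow(x) == 0L) {
      return(tibble::tibble(
        person_id = character(), n_units = integer(),
        n_ab = integer(), status = factor(character(), levels = .status_levels)
      ))
    }
    date_key <- if (latest) -as.numeric(x$event_date) else as.numeric(x$event_date)
    # ties: fixed collection priority, then Aboriginal flag first, then file order
    o <- order(x$person_id, date_key, as.integer(x$collection), !x$is_ab, x$.row)
    x <- x[o, , drop = FALSE]
    x <- x[!duplicated(x$person_id), , drop = FALSE]
    tibble::tibble(
      person_id = x$person_id, n_units = 1L, n_ab = as.integer(x$is_ab),
      status = factor(as.character(x$flag), levels = .status_levels)
    )
  }

  res <- switch(method,
    era = {
      cnt <- counts_of(ev)
      cnt$status <- era_rule(cnt$n_units, cnt$n_ab)
      cnt
    },
    msm = {
      s1 <- ev |>
        dplyr::group_by(.data$person_id, .data$collection) |>
        dplyr::summarise(n = dplyr::n(), a = sum(.data$is_ab), .groups = "drop")
      s1$coll_ab <- era_rule(s1$n, s1$a) == "aboriginal"
      s2 <- s1 |>
        dplyr::group_by(.data$person_id) |>
        dplyr::summarise(
          n_units = dplyr::n(), n_ab = sum(.data$coll_ab),
          .groups = "drop"
        )
      s2$status <- era_rule(s2$n_units, s2$n_ab)
      s2
    },
    ever_reported = {
      cnt <- counts_of(ev)
      cnt$status <- factor(
        ifelse(cnt$n_ab >= 1L, "aboriginal", "non_aboriginal"),
        levels = .status_levels
      )
      cnt
    },
    always_reported = {
      cnt <- counts_of(ev)
      cnt$status <- factor(
        ifelse(cnt$n_units >= 1L & cnt$n_ab == cnt$n_units, "aboriginal", "non_aboriginal"),
        levels = .status_levels
      )
      cnt
    },
    most_recent = {
      sub <- if (recency_scope == "hospital") {
        ev[ev$collection %in% .hospital_collections, , drop = FALSE]
      } else {
        ev
      }
      pick_extreme(sub, latest = TRUE)
    },
    index_record = {
      sub <- if (recency_scope == "hospital") {
        ev[ev$collection %in% .hospital_collections, , drop = FALSE]
      } else {
        ev
      }
      pick_extreme(sub, latest = FALSE)
    },
    majority = {
      sub <- if (majority_scope == "apdc") {
        ev[ev$collection == "APDC", , drop = FALSE]
      } else {
        ev
      }
      cnt <- counts_of(sub)
      cnt$status <- factor(
        ifelse(cnt$n_units >= 1L & cnt$n_ab / cnt$n_units >= 0.5, "aboriginal", "non_aboriginal"),
        levels = .status_levels
      )
      cnt
    },
    two_hospitals = {
      hosp <- ev[ev$collection %in% .hospital_collections, , drop = FALSE]
      cnt <- counts_of(hosp)
      fac <- hosp |>
        dplyr::filter(.data$is_ab, !is.na(.data$facility_id)) |>
        dplyr::group_by(.data$person_id) |>
        dplyr::summarise(n_fac = dplyr::n_distinct(.data$facility_id), .groups = "drop")
      cnt <- dplyr::left_join(cnt, fac, by = "person_id")
      cnt$status <- factor(
        ifelse(!is.na(cnt$n_fac) & cnt$n_fac >= 2L, "aboriginal", "non_aboriginal"),
        levels = .status_levels
      )
      cnt[c("person_id", "n_units", "n_ab", "status")]
    },
    as_recorded = {
      samp <- records[records$is_sampled & records$flag != "missing", , drop = FALSE]
      tibble::tibble(
        person_id = samp$person_id, n_units = 1L,
        n_ab = as.integer(samp$flag == "aboriginal"),
        status = factor(as.character(samp$flag), levels = .status_levels)
      )
    }
  )

  out <- tibble::tibble(person_id = as.character(person_ids)) |>
    dplyr::left_join(res, by = "person_id")
  miss <- is.na(out$n_units)
  out$n_units[miss] <- 0L
  out$n_ab[miss] <- 0L
  if (method != "as_recorded") {
    # zero-evidence persons derive non-Aboriginal for every enhancement rule
    out$status[miss] <- "non_aboriginal"
  }
  tibble::tibble(
    person_id = out$person_id,
    method = factor(method, levels = .method_levels),
    status = out$status,
    n_units = as.integer(out$n_units),
    n_aboriginal_units = as.integer(out$n_ab)
  )
}

.derive_person <- function(records, method, ...) {
  records <- .canonical_records(records)
  if (nrow(records) == 0L) stop("no records supplied", call. = FALSE)
  pid <- unique(records$person_id)
  if (length(pid) != 1L) {
    stop("records belong to more than one person", call. = FALSE)
  }
  .derive_method(records, pid, method, ...)
}

#' Derive a person's status under one rule
#'
#' Each function applies one derivation rule to a single person's linked
#' records and returns a one-row tibble (`person_id`, `method`, `status`,
#' `n_units`, `n_aboriginal_units`):
#'
#' * `derive_era()`: the [era_rule()] weight of evidence over all
#'   non-missing-flag records from all five collections.
#' * `derive_msm()`: Multi-stage median — the ERA rule within each
#'   collection, then the ERA rule again over the per-collection results.
#' * `derive_ever_reported()`: Aboriginal if any record is
#'   Aboriginal-flagged.
#' * `derive_always_reported()`: Aboriginal if at least one usable record
#'   and every usable record is Aboriginal-flagged.
#' * `derive_most_recent()` / `derive_index_record()`: the flag of the
#'   latest / earliest dated usable record; date ties break by collection
#'   priority APDC > EDDC > PDC > RBDM > CODURF, then Aboriginal flag first,
#'   then input order.
#' * `derive_majority()`: Aboriginal if at least half of the person's usable
#'   APDC (public hospital admission) records are Aboriginal-flagged
#'   (`majority_scope = "all"` widens to all records).
#' * `derive_two_hospitals()`: Aboriginal if Aboriginal-flagged hospital
#'   (APDC/EDDC) records span at least two distinct facilities.
#' * `derive_as_recorded()`: the flag of the one originally sampled survey
#'   record; errors if no sampled record with a usable flag exists.
#'
#' @param records One person's linked records (data frame in the
#'   [linked_dataset()] records layout).
#' @param majority_scope `"apdc"` (default) or `"all"`.
#' @param recency_scope `"all"` collections (default) or `"hospital"` only.
#' @return A one-row tibble.
#' @name derive_rules
NULL

#' @rdname derive_rules
#' @export
derive_era <- function(records) .derive_person(records, "era")

#' @rdname derive_rules
#' @export
derive_msm <- function(records) .derive_person(records, "msm")

#' @rdname derive_rules
#' @export
derive_ever_reported <- function(records) .derive_person(records, "ever_reported")

#' @rdname derive_rules
#' @export
derive_always_reported <- function(records) .derive_person(records, "always_reported")

#' @rdname derive_rules
#' @export
derive_most_recent <- function(records, recency_scope = "all") {
  .derive_person(records, "most_recent", recency_scope = recency_scope)
}

#' @rdname derive_rules
#' @export
derive_index_record <- function(records, recency_scope = "all") {
  .derive_person(records, "index_record", recency_scope = recency_scope)
}

#' @rdname derive_rules
#' @export
derive_majority <- function(records, majority_scope = "apdc") {
  .derive_person(records, "majority", majority_scope = majority_scope)
}

#' @rdname derive_rules
#' @export
derive_two_hospitals <- function(records) .derive_person(records, "two_hospitals")

#' @rdname derive_rules
#' @export
derive_as_recorded <- function(records) {
  out <- .derive_person(records, "as_recorded")
  if (is.na(out$status)) {
    stop("no sampled record with a usable (non-missing) flag", call. = FALSE)
  }
  out
}

#' Derive statuses for every person under a set of rules
#'
#' Applies each requested rule to every person in the dataset (including
#' persons with zero linked records, who derive non-Aboriginal under every
#' enhancement rule). Persons failing a rule's precondition — As-recorded
#' with no usable sampled record — are recorded with `status = NA`
#' (not evaluable) and logged.
#'
#' @param ds A [linked_dataset()].
#' @param methods Character vector of method codes, or `"core"` / `"all"`
#'   (see [linkage_methods()]).
#' @inheritParams derive_rules
#' @return Tibble with one row per person and method: `person_id`, `method`,
#'   `status`, `n_units`, `n_aboriginal_units`.
#' @export
derive_all <- function(ds, methods = "core", majority_scope = "apdc", recency_scope = "all") {
  stopifnot(inherits(ds, "linked_dataset"))
  methods <- .resolve_methods(methods)
  out <- lapply(methods, function(m) {
    d <- .derive_method(ds$records, ds$persons$person_id, m,
      majority_scope = majority_scope, recency_scope = recency_scope
    )
    n_na <- sum(is.na(d$status))
    if (n_na > 0) {
      .log_msg("derive_all: ", n_na, " person(s) not evaluable under ", m)
    }
    d
  })
  dplyr::bind_rows(out)
}
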