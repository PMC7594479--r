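## Record-level evaluation against the self-reported reference standard.
## Each non-missing-flag record of the chosen source (APDC or EDDC) is one
## unit in the confusion matrix: its predicted label is the person's derived
## status (or, for As-recorded in all-records mode, the record's own flag),
## its truth is the person's reference status.

.new_confusion <- function(tp, fp, tn, fn, method, source, stratum, mode) {
  structure(
    list(
      tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      method = method, source = source, stratum = stratum, mode = mode
    ),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf(
    "<confusion_matrix> %s / %s / %s / %s\n  tp=%d fp=%d tn=%d fn=%d (n=%d records)\n",
    x$method, x$source, x$stratum, x$mode, x$tp, x$fp, x$tn, x$fn,
    x$tp + x$fp + x$tn + x$fn
  ))
  invisible(x)
}

#' Build a record-level confusion matrix
#'
#' Counts true/false positives and negatives over the usable
#' (non-missing-flag) records of one source collection, optionally
#' restricted to an age stratum and, in `"sampled_only"` mode, to the
#' originally sampled survey records. For `"as_recorded"` in
#' `"all_records"` mode a record is predicted by its own flag; for every
#' other method (and for As-recorded in `"sampled_only"` mode) by the
#' person's derived status. Records of persons not evaluable under the
#' method are excluded and logged.
#'
#' @param ds A [linked_dataset()].
#' @param derived Output of [derive_all()] containing the method (may be
#'   `NULL` for As-recorded in all-records mode).
#' @param method One method code.
#' @param source `"APDC"` or `"EDDC"`.
#' @param stratum An age-group code or `"ALL"` (default).
#' @param mode `"all_records"` (default) or `"sampled_only"`.
#' @return A `confusion_matrix` object with fields `tp`, `fp`, `tn`, `fn`.
#' @export
build_confusion <- function(ds, derived = NULL, method, source,
                            stratum = "ALL", mode = c("all_records", "sampled_only")) {
  stopifnot(inherits(ds, "linked_dataset"))
  method <- match.arg(method, .method_levels)
  source <- match.arg(source, .hospital_collections)
  mode <- match.arg(mode)
  if (!identical(stratum, "ALL")) {
    stratum <- match.arg(stratum, .age_group_levels)
  }

  recs <- ds$records |>
    dplyr::filter(.data$collection == source, .data$flag != "missing")
  if (mode == "sampled_only") {
    recs <- dplyr::filter(recs, .data$is_sampled)
  }
  recs <- recs |>
    dplyr::left_join(
      ds$persons[c("person_id", "reference_status", "age_group")],
      by = "person_id"
    )
  if (!identical(stratum, "ALL")) {
    recs <- dplyr::filter(recs, .data$age_group == stratum)
  }

  if (method == "as_recorded" && mode == "all_records") {
    pred <- as.character(recs$flag)
  } else {
    if (is.null(derived)) {
      stop("derived statuses are required for method '", method, "'", call. = FALSE)
    }
    d <- derived |>
      dplyr::filter(.data$method == !!method) |>
      dplyr::select("person_id", "status")
    if (nrow(d) == 0L) {
      stop("derived table holds no rows for method '", method, "'", call. = FALSE)
    }
    recs <- dplyr::left_join(recs, d, by = "person_id")
    pred <- as.character(recs$status)
    n_excl <- sum(is.na(pred))
    if (n_excl > 0) {
      .log_msg(
        "build_confusion: excluded ", n_excl,
        " record(s) of persons not evaluable under ", method
      )
      recs <- recs[!is.na(pred), , drop = FALSE]
      pred <- pred[!is.na(pred)]
    }
  }
  truth <- recs$reference_status == "aboriginal"
  pos <- pred == "aboriginal"
  cm <- .new_confusion(
    tp = sum(pos & truth), fp = sum(pos & !truth),
    tn = sum(!pos & !truth), fn = sum(!pos & truth),
    method = method, source = source,
    stratum = if (identical(stratum, "ALL")) "Total" else stratum, mode = mode
  )
  if (cm$tp + cm$fp + cm$tn + cm$fn == 0L) {
    .log_msg(
      "build_confusion: no evaluable records for ", method, "/", source,
      "/", if (identical(stratum, "ALL")) "Total" else stratum
    )
  }
  cm
}

.rate <- function(num, den) {
  if (den == 0) NA_real_ else 100 * num / den
}

#' Accuracy measures of a confusion matrix
#'
#' Standard diagnostic-validity definitions on the percent scale:
#' sensitivity 100·tp/(tp+fn), specificity 100·tn/(tn+fp), positive
#' predictive value 100·tp/(tp+fp), negative predictive value
#' 100·tn/(tn+fn). A zero denominator yields `NA` (an undefined measure),
#' never 0 or 100.
#'
#' @param cm A `confusion_matrix`.
#' @return A single percentage, or `NA_real_` when undefined.
#' @name validity_rates
NULL

#' @rdname validity_rates
#' @export
sensitivity <- function(cm) .rate(cm$tp, cm$tp + cm$fn)

#' @rdname validity_rates
#' @export
specificity <- function(cm) .rate(cm$tn, cm$tn + cm$fp)

#' @rdname validity_rates
#' @export
ppv <- function(cm) .rate(cm$tp, cm$tp + cm$fp)

#' @rdname validity_rates
#' @export
npv <- function(cm) .rate(cm$tn, cm$tn + cm$fn)

#' F score from sensitivity and PPV
#'
#' The harmonic mean of PPV (precision) and sensitivity (recall) on the
#' unit scale, balancing a gain in sensitivity against the accompanying
#' loss in PPV. Inputs are percentages; the result is in \[0, 1\].
#'
#' @param sensitivity,ppv Percentages.
#' @return Unit-scale F score; `NA_real_` if either input is `NA` or both
#'   are zero.
#' @examples
#' f_score(84.4, 95.3) # 0.90 to 2 decimals
#' @export
f_score <- function(sensitivity, ppv) {
  out <- 2 * (ppv / 100) * (sensitivity / 100) / ((ppv + sensitivity) / 100)
  out[!is.na(ppv + sensitivity) & (ppv + sensitivity) == 0] <- NA_real_
  out
}

#' All five validity measures of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return One-row tibble: `method`, `source`, `stratum`, `mode`,
#'   `n_records`, `sensitivity`, `specificity`, `ppv`, `npv`, `f_score`
#'   (full precision; see [format_validity_table()] for display rounding).
#' @export
validity_measures <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  se <- sensitivity(cm)
  pp <- ppv(cm)
  tibble::tibble(
    method = cm$method, source = cm$source, stratum = cm$stratum, mode = cm$mode,
    n_records = cm$tp + cm$fp + cm$tn + cm$fn,
    sensitivity = se, specificity = specificity(cm),
    ppv = pp, npv = npv(cm),
    f_score = if (is.na(se) || is.na(pp)) NA_real_ else f_score(se, pp)
  )
}

## Efficient all-strata evaluation: one pass per source building per-record
## predicted labels for every method, then aggregating counts by stratum.
.evaluate_source <- function(ds, derived, methods, source, mode) {
  recs <- ds$records |>
    dplyr::filter(.data$collection == source, .data$flag != "missing")
  if (mode == "sampled_only") {
    recs <- dplyr::filter(recs, .data$is_sampled)
  }
  recs <- recs |>
    dplyr::left_join(
      ds$persons[c("person_id", "reference_status", "age_group")],
      by = "person_id"
    )
  wide <- derived |>
    dplyr::filter(.data$method %in% methods) |>
    dplyr::select("person_id", "method", "status") |>
    tidyr::pivot_wider(names_from = "method", values_from = "status")
  recs <- dplyr::left_join(recs, wide, by = "person_id")

  res <- lapply(methods, function(m) {
    pred <- if (m == "as_recorded" && mode == "all_records") {
      as.character(recs$flag)
    } else {
      as.character(recs[[m]])
    }
    keep <- !is.na(pred)
    # factor-coded cells so .drop = FALSE keeps the full stratum x cell
    # cross even when a stratum (or the whole source) has no records
    tab <- tibble::tibble(
      age_group = recs$age_group[keep],
      truth = factor(recs$reference_status[keep] == "aboriginal", levels = c(FALSE, TRUE)),
      pos = factor(pred[keep] == "aboriginal", levels = c(FALSE, TRUE))
    ) |>
      dplyr::count(.data$age_group, .data$truth, .data$pos, .drop = FALSE)
    tab$method <- m
    tab
  })
  counts <- dplyr::bind_rows(res)
  by_stratum <- counts |>
    dplyr::group_by(.data$method, stratum = as.character(.data$age_group)) |>
    dplyr::summarise(
      tp = sum(.data$n[.data$truth == "TRUE" & .data$pos == "TRUE"]),
      fp = sum(.data$n[.data$truth == "FALSE" & .data$pos == "TRUE"]),
      tn = sum(.data$n[.data$truth == "FALSE" & .data$pos == "FALSE"]),
      fn = sum(.data$n[.data$truth == "TRUE" & .data$pos == "FALSE"]),
      .groups = "drop"
    )
  totals <- by_stratum |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      stratum = "Total",
      tp = sum(.data$tp), fp = sum(.data$fp), tn = sum(.data$tn), fn = sum(.data$fn),
      .groups = "drop"
    )
  out <- dplyr::bind_rows(by_stratum, totals)
  out$source <- source
  out
}

#' Stratified validity table
#'
#' Evaluates every requested method against the reference standard for the
#' APDC and EDDC separately, overall and within each age stratum,
#' reproducing the layout of a record-level validity table: one row per
#' (age stratum or Total) and method, with sensitivity, specificity, PPV,
#' NPV and F score for each source. Measures are kept at full precision;
#' use [format_validity_table()] for display rounding. Undefined measures
#' (zero denominators) are `NA`.
#'
#' @param ds A [linked_dataset()].
#' @param derived Output of [derive_all()] covering the methods.
#' @param methods Method codes or `"core"` / `"all"`.
#' @param mode `"all_records"` (default) or `"sampled_only"`.
#' @return Tibble with columns `age_group`, `method`, then
#'   `apdc_sensitivity` ... `apdc_f_score`, `eddc_sensitivity` ...
#'   `eddc_f_score`, plus record counts `apdc_n`, `eddc_n`.
#' @export
evaluate_table <- function(ds, derived, methods = "core",
                           mode = c("all_records", "sampled_only")) {
  stopifnot(inherits(ds, "linked_dataset"))
  methods <- .resolve_methods(methods)
  mode <- match.arg(mode)

  long <- dplyr::bind_rows(lapply(
    .hospital_collections,
    function(src) .evaluate_source(ds, derived, methods, src, mode)
  ))
  long <- long |>
    dplyr::mutate(
      n = .data$tp + .data$fp + .data$tn + .data$fn,
      sensitivity = ifelse(.data$tp + .data$fn > 0, 100 * .data$tp / (.data$tp + .data$fn), NA_real_),
      specificity = ifelse(.data$tn + .data$fp > 0, 100 * .data$tn / (.data$tn + .data$fp), NA_real_),
      ppv = ifelse(.data$tp + .data$fp > 0, 100 * .data$tp / (.data$tp + .data$fp), NA_real_),
      npv = ifelse(.data$tn + .data$fn > 0, 100 * .data$tn / (.data$tn + .data$fn), NA_real_),
      f_score = ifelse(!is.na(.data$sensitivity) & !is.na(.data$ppv),
        f_score(.data$sensitivity, .data$ppv), NA_real_
      )
    )
  wide <- long |>
    dplyr::select(
      "method", "stratum", "source", "n",
      "sensitivity", "specificity", "ppv", "npv", "f_score"
    ) |>
    tidyr::pivot_wider(
      names_from = "source",
      values_from = c("n", "sensitivity", "specificity", "ppv", "npv", "f_score"),
      names_glue = "{tolower(source)}_{.value}"
    ) |>
    dplyr::rename(age_group = "stratum")
  wide$age_group <- factor(wide$age_group, levels = c(.age_group_levels, "Total"))
  wide$method <- factor(wide$method, levels = methods)
  wide |>
    dplyr::arrange(.data$age_group, .data$method) |>
    dplyr::select(
      "age_group", "method",
      "apdc_sensitivity", "apdc_specificity", "apdc_ppv", "apdc_npv", "apdc_f_score",
      "eddc_sensitivity", "eddc_specificity", "eddc_ppv", "eddc_npv", "eddc_f_score",
      "apdc_n", "eddc_n"
    )
}

#' Format a validity table for display
#'
#' Applies the conventional display rounding — rates to one decimal percent,
#' F scores to two decimals (ties away from zero) — and renders undefined
#' measures as empty cells.
#'
#' @param tbl Output of [evaluate_table()].
#' @return A tibble of character columns.
#' @export
format_validity_table <- function(tbl) {
  fmt <- function(x, digits) {
    out <- ifelse(is.na(x), "", formatC(.round_half_up(x, digits), format = "f", digits = digits))
    out
  }
  out <- tbl
  for (nm in names(tbl)) {
    if (grepl("_f_score$", nm)) {
      out[[nm]] <- fmt(tbl[[nm]], 2)
    } else if (grepl("_(sensitivity|specificity|ppv|npv)$", nm)) {
      out[[nm]] <- fmt(tbl[[nm]], 1)
    }
  }
  out
}
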