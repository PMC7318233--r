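#' Validate a binary symptom cohort
#'
#' Checks a data frame of dichotomous symptom indicators (1 = present,
#' 0 = absent) and returns a validated `symptom_matrix` tibble. Rows with
#' any missing or non-binary value in a symptom column are dropped listwise
#' and the number of dropped rows is reported, mirroring the complete-case
#' requirement of symptom-profile network studies.
#'
#' @param data A data frame with one column per symptom item plus optional
#'   categorical subgroup columns (e.g. geographic region, income class).
#' @param items Character vector of symptom column names. Defaults to the
#'   columns matching the ICD-10 codes of [icd10_items()] when at least two
#'   are present, otherwise to all non-subgroup columns.
#' @param subgroups Character vector of subgroup label column names
#'   (optional).
#' @param quiet Suppress the dropped-row message.
#'
#' @return A tibble of class `symptom_matrix` with integer 0/1 item columns,
#'   attributes `items`, `subgroups` and `n_dropped`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 50, prevalences = rep(0.4, 3)),
#'                           seed = 1)
#' as_symptom_matrix(cohort)
as_symptom_matrix <- function(data, items = NULL, subgroups = NULL,
                              quiet = FALSE) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (is.null(subgroups)) {
    subgroups <- attr(data, "subgroups")
  }
  if (!is.null(subgroups)) {
    missing_sub <- setdiff(subgroups, names(data))
    if (length(missing_sub) > 0) {
      abort(paste0("subgroup column(s) not found: ",
                   paste(missing_sub, collapse = ", ")))
    }
  }
  if (is.null(items)) {
    items <- attr(data, "items")
  }
  if (is.null(items)) {
    known <- intersect(icd10_items()$code, names(data))
    items <- if (length(known) >= 2) known else setdiff(names(data), subgroups)
  } else {
    missing_it <- setdiff(items, names(data))
    if (length(missing_it) > 0) {
      abort(paste0("item column(s) not found: ",
                   paste(missing_it, collapse = ", ")))
    }
  }
  if (anyDuplicated(items)) abort("item codes must be unique")
  if (length(items) < 2) {
    abort("a symptom matrix needs at least 2 item columns")
  }

  vals <- data[items]
  ok_cell <- vapply(vals, function(v) {
    v <- suppressWarnings(as.numeric(v))
    !is.na(v) & (v == 0 | v == 1)
  }, logical(nrow(data)))
  ok_cell <- matrix(ok_cell, nrow = nrow(data))
  keep <- rowSums(ok_cell) == length(items)
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    warn(paste0(n_dropped, " row(s) with missing or non-binary symptom ",
                "values dropped"))
  }
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 1) abort("no valid rows remain after validation")
  for (it in items) data[[it]] <- as.integer(as.numeric(data[[it]]))
  out <- data[c(items, subgroups)]
  structure(out,
            items = items, subgroups = subgroups, n_dropped = n_dropped,
            class = c("symptom_matrix", class(out)))
}

#' Read a symptom cohort from CSV
#'
#' @param path Path to a comma-separated file with a header row of item
#'   codes and optional subgroup label columns.
#' @inheritParams as_symptom_matrix
#' @return A validated `symptom_matrix` tibble; see [as_symptom_matrix()].
#' @export
read_symptom_matrix <- function(path, items = NULL, subgroups = NULL,
                                quiet = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) abort("CSV must contain at least 2 item columns")
  as_symptom_matrix(raw, items = items, subgroups = subgroups, quiet = quiet)
}

#' Write a symptom cohort to CSV
#'
#' @param data A `symptom_matrix` (or plain data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_symptom_matrix <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

symptom_items <- function(data, items = NULL) {
  items %||% attr(data, "items") %||% attr(as_symptom_matrix(data), "items")
}

#' Symptom prevalence table
#'
#' Per-item counts of symptom presence and percentages rounded to one
#' decimal (half away from zero), overall or within levels of a subgroup
#' label, with the subgroup size as denominator.
#'
#' @param data A `symptom_matrix` or data frame of 0/1 indicators.
#' @param by Optional name of a subgroup column; one table per level is
#'   returned in addition to nothing else (denominator = level size).
#' @param level Optional single level of `by` to restrict to.
#' @param items Symptom columns (defaults to the validated attribute).
#' @return A tibble with columns `cohort`, `n`, `item`, `count`, `percent`.
#' @export
#' @examples
#' x <- simulate_cohort(reap_cohort_spec(), seed = 7)
#' prevalence(x)
#' prevalence(x, by = "region")
prevalence <- function(data, by = NULL, level = NULL, items = NULL) {
  x <- as_symptom_matrix(data, items = items, quiet = TRUE)
  items <- attr(x, "items")
  tab_one <- function(rows, label) {
    n <- length(rows)
    counts <- vapply(items, function(it) sum(x[[it]][rows]), integer(1))
    tibble::tibble(cohort = label, n = n, item = items,
                   count = unname(counts),
                   percent = round_half_up(100 * unname(counts) / n, 1))
  }
  if (is.null(by)) return(tab_one(seq_len(nrow(x)), "overall"))
  if (!by %in% names(x)) abort(paste0("unknown subgroup column: ", by))
  levs <- sort(unique(as.character(x[[by]])))
  if (!is.null(level)) {
    if (!level %in% levs) {
      abort(paste0("unknown level '", level, "' of subgroup '", by, "'"))
    }
    levs <- level
  }
  purrr::map_dfr(levs, function(l) tab_one(which(x[[by]] == l), l))
}
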