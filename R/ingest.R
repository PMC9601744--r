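#' Read a delimited cohort table, keeping only required columns
#'
#' Reads a comma-separated table with a header row, checks that every
#' required column is present, and returns only those columns in file order.
#' Empty strings are read as missing values.
#'
#' @param path Path to a CSV file.
#' @param required_columns Character vector of column names that must exist;
#'   the returned tibble is restricted to them.
#' @return A tibble with the required columns, rows in file order.
#' @export
read_cohort_table <- function(path, required_columns) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "cogprog_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  missing_cols <- setdiff(required_columns, names(tbl))
  if (length(missing_cols) > 0) {
    rlang::abort(
      sprintf(
        "missing required column(s): %s",
        paste(missing_cols, collapse = ", ")
      ),
      class = "cogprog_schema_error"
    )
  }
  message(sprintf("read %d rows from %s", nrow(tbl), basename(path)))
  tbl[, required_columns, drop = FALSE]
}

#' Drop rows with missing mandatory fields
#'
#' Removes every row with a missing value (NA or empty string) in any of the
#' mandatory fields, reporting removal counts per field. Incomplete
#' observations are removed rather than imputed.
#'
#' @param data A data frame.
#' @param mandatory_fields Columns that must be non-missing.
#' @return A tibble of complete rows; the per-field removal counts are
#'   attached as attribute `"removed"`.
#' @export
drop_incomplete <- function(data, mandatory_fields = names(data)) {
  data <- tibble::as_tibble(data)
  mandatory_fields <- intersect(mandatory_fields, names(data))
  miss <- vapply(
    data[mandatory_fields],
    function(x) is_missing_cell(x),
    logical(nrow(data))
  )
  if (nrow(data) == 0) {
    return(structure(data, removed = stats::setNames(
      integer(length(mandatory_fields)), mandatory_fields
    )))
  }
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = nrow(data))
  removed <- colSums(miss)
  names(removed) <- mandatory_fields
  keep <- rowSums(miss) == 0
  if (sum(keep) == 0) {
    rlang::warn("all rows removed: every row had a missing mandatory field")
  }
  for (f in mandatory_fields[removed > 0]) {
    message(sprintf("drop_incomplete: %d row(s) missing %s", removed[[f]], f))
  }
  structure(data[keep, , drop = FALSE], removed = removed)
}

#' Integrate diagnosis and assessment tables into visit records
#'
#' Inner-joins the ADNIMERGE-style table and the ADAS-style table on patient
#' ID and visit code (`VISCODE` and `VISCODE2` are the same key under two
#' names; codes are harmonised by lower-casing and month parsing before the
#' join). Visits present in only one table are dropped and counted — no
#' merging occurs for a visit at which the assessment was not administered.
#'
#' @param merge_data Cleansed ADNIMERGE-style tibble with columns RID,
#'   VISCODE, DX, AGE, PTGEN, PTEDUCAT, PTRACCAT, PTMARRY.
#' @param adas_data Cleansed ADAS-style tibble with columns RID, VISCODE2 and
#'   the 13 item columns.
#' @return A tibble of visit records with lower-case key columns
#'   (`rid`, `viscode`, `month`, `dx`, demographics, 13 items), sorted by
#'   patient and visit month. Unmatched-row counts are attached as attribute
#'   `"unmatched"`.
#' @export
integrate_visits <- function(merge_data, adas_data) {
  merge_data <- tibble::as_tibble(merge_data)
  adas_data <- tibble::as_tibble(adas_data)

  m <- merge_data |>
    dplyr::mutate(.month = viscode_to_month(.data$VISCODE))
  a <- adas_data |>
    dplyr::mutate(.month = viscode_to_month(.data$VISCODE2))

  check_dupes <- function(tbl, label) {
    d <- tbl |>
      dplyr::count(.data$RID, .data$.month) |>
      dplyr::filter(.data$n > 1)
    if (nrow(d) > 0) {
      rlang::abort(
        sprintf(
          "duplicate (RID, visit) key(s) in %s table: %s",
          label,
          paste(sprintf("(%s, m%d)", d$RID, d$.month), collapse = ", ")
        ),
        class = "cogprog_integrity_error"
      )
    }
  }
  check_dupes(m, "merge")
  check_dupes(a, "adas")

  joined <- dplyr::inner_join(
    m, dplyr::select(a, -"VISCODE2"),
    by = c("RID", ".month")
  )
  unmatched <- c(
    merge = nrow(m) - nrow(joined),
    adas = nrow(a) - nrow(joined)
  )
  if (nrow(joined) == 0) {
    rlang::warn("integrate_visits: no (RID, visit) keys in common; empty result")
  }
  message(sprintf(
    "integrated %d visit record(s); unmatched: %d merge, %d adas",
    nrow(joined), unmatched[["merge"]], unmatched[["adas"]]
  ))

  out <- joined |>
    dplyr::transmute(
      rid = .data$RID,
      viscode = tolower(.data$VISCODE),
      month = .data$.month,
      dx = .data$DX,
      age = .data$AGE,
      ptgen = .data$PTGEN,
      pteducat = .data$PTEDUCAT,
      ptraccat = .data$PTRACCAT,
      ptmarry = .data$PTMARRY,
      dplyr::across(dplyr::any_of(adas_items()))
    ) |>
    dplyr::arrange(.data$rid, .data$month)
  structure(out, unmatched = unmatched)
}
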