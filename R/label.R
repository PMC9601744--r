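#' Map diagnosis labels to ordinal stage digits
#'
#' Encodes the three diagnostic stages as ordered integers: CN = 1, MCI = 2,
#' AD = 3. A synonym map handles alternative spellings found in real extracts
#' (e.g. "Dementia" for AD).
#'
#' @param dx Character vector of diagnosis labels.
#' @param synonyms Named character vector mapping alternative labels to
#'   canonical ones; set `NULL` to accept only CN/MCI/AD.
#' @return Integer vector of stage digits in {1, 2, 3}.
#' @examples
#' map_dx_digit(c("CN", "MCI", "AD"))
#' map_dx_digit("Dementia")
#' @export
map_dx_digit <- function(dx, synonyms = c(Dementia = "AD")) {
  x <- trimws(as.character(dx))
  if (!is.null(synonyms)) {
    hit <- x %in% names(synonyms)
    x[hit] <- synonyms[x[hit]]
  }
  digits <- c(CN = 1L, MCI = 2L, AD = 3L)
  unknown <- !(x %in% names(digits)) & !is.na(x)
  if (any(unknown)) {
    rlang::abort(
      sprintf(
        "unknown diagnosis label(s): %s",
        paste(unique(x[unknown]), collapse = ", ")
      ),
      class = "cogprog_label_error"
    )
  }
  unname(digits[x])
}

#' Derive the per-visit progression label
#'
#' For each patient, visits are ordered by month and each visit's stage digit
#' is compared with the immediately preceding visit's: an increase is labelled
#' 1 (progression), no change 0, and a decrease -1 (regression, removed by
#' [drop_regressions()]). Every patient's first visit is labelled 0 so that no
#' label models an observation from a different patient. Two-stage jumps
#' (CN to AD between consecutive visits) are labelled 1 and counted
#' separately.
#'
#' @param data Visit records from [integrate_visits()] (columns `rid`,
#'   `month`, `dx`; one row per patient-visit).
#' @param synonyms Passed to [map_dx_digit()].
#' @return The input with `dx_digit` and `dx_progress` columns appended,
#'   sorted by (`rid`, `month`). The number of two-stage jumps is attached as
#'   attribute `"two_stage_jumps"`.
#' @export
derive_progress <- function(data, synonyms = c(Dementia = "AD")) {
  data <- tibble::as_tibble(data)
  dup <- data |>
    dplyr::count(.data$rid, .data$month) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort("one row per (rid, visit) required", class = "cogprog_integrity_error")
  }
  out <- data |>
    dplyr::mutate(dx_digit = map_dx_digit(.data$dx, synonyms)) |>
    dplyr::arrange(.data$rid, .data$month) |>
    dplyr::group_by(.data$rid) |>
    dplyr::mutate(
      dx_progress = dplyr::if_else(
        dplyr::row_number() == 1L,
        0L,
        sign(.data$dx_digit - dplyr::lag(.data$dx_digit))
      )
    ) |>
    dplyr::ungroup()
  jumps <- out |>
    dplyr::group_by(.data$rid) |>
    dplyr::summarise(
      n = sum((.data$dx_digit - dplyr::lag(.data$dx_digit)) >= 2, na.rm = TRUE)
    ) |>
    dplyr::pull(.data$n) |>
    sum()
  if (jumps > 0) {
    message(sprintf("derive_progress: %d two-stage jump(s) labelled as progression", jumps))
  }
  structure(out, two_stage_jumps = jumps)
}

#' Remove regression visits
#'
#' Drops visit rows labelled -1 (a stage decrease relative to the previous
#' visit), leaving a binary progression class: 1 = the stage advanced at this
#' visit, 0 = no advancement.
#'
#' @param data Output of [derive_progress()].
#' @return The input restricted to rows with `dx_progress` in {0, 1}; the
#'   removed-row count is attached as attribute `"regressions_removed"`.
#' @export
drop_regressions <- function(data) {
  stopifnot("dx_progress" %in% names(data))
  n0 <- nrow(data)
  out <- dplyr::filter(data, .data$dx_progress >= 0)
  removed <- n0 - nrow(out)
  if (removed > 0) {
    message(sprintf("drop_regressions: removed %d regression row(s)", removed))
  }
  structure(out, regressions_removed = removed)
}

#' Label progression in one step
#'
#' Convenience wrapper: [derive_progress()] then [drop_regressions()].
#'
#' @inheritParams derive_progress
#' @return A labeled tibble with binary `dx_progress`.
#' @export
label_progression <- function(data, synonyms = c(Dementia = "AD")) {
  drop_regressions(derive_progress(data, synonyms))
}
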