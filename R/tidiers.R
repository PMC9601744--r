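#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a feature-score table into long form
#'
#' @param x A `cog_score_table` from [score_features()].
#' @param ... Unused.
#' @return A tibble with one row per item and scoring method: `item`,
#'   `method` (`ig`, `cst`, `relieff`), `raw`, `normalized`, `avg_score`.
#' @export
tidy.cog_score_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = -c("item", "avg_score"),
      names_to = c("method", ".value"),
      names_pattern = "(ig|cst|relieff)_(raw|norm)"
    ) |>
    dplyr::rename(raw = "raw", normalized = "norm")
}

#' Tidy a ranked/clustered item table
#'
#' @param x A `cog_rank_table`.
#' @param ... Unused.
#' @return The underlying tibble (already one row per ranked item).
#' @export
tidy.cog_rank_table <- function(x, ...) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' One-row summary of a ranked/clustered item table
#'
#' @param x A `cog_rank_table` with clusters assigned.
#' @param ... Unused.
#' @return A tibble with `n_items`, `n_clusters`, `top_item`, `top_score`
#'   and `max_drop_pct`.
#' @export
glance.cog_rank_table <- function(x, ...) {
  tibble::tibble(
    n_items = nrow(x),
    n_clusters = if ("cluster" %in% names(x)) max(x$cluster) else NA_integer_,
    top_item = x$item[x$rank == 1],
    top_score = x$avg_score[x$rank == 1],
    max_drop_pct = max(x$drop_pct, na.rm = TRUE)
  )
}

#' Tidy cross-validation results into long form
#'
#' @param x A `cog_eval` from [cross_validate()] or [evaluate_subsets()].
#' @param ... Unused.
#' @return A tibble with one row per run and metric: identifying columns,
#'   `metric` (`accuracy`, `sensitivity`, `specificity`) and `value` in
#'   percent.
#' @export
tidy.cog_eval <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = c("accuracy", "sensitivity", "specificity"),
      names_to = "metric", values_to = "value"
    )
}

#' One-row summary of cross-validation results
#'
#' @param x A `cog_eval`.
#' @param ... Unused.
#' @return A tibble with the number of runs, the pooled dataset size per run,
#'   and the best accuracy with its classifier.
#' @export
glance.cog_eval <- function(x, ...) {
  best <- which.max(x$accuracy)
  tibble::tibble(
    n_runs = nrow(x),
    n_observations = x$tp[1] + x$fp[1] + x$tn[1] + x$fn[1],
    best_accuracy = x$accuracy[best],
    best_classifier = x$classifier[best]
  )
}
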