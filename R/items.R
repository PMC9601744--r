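#' The ADAS-Cog-13 item schema
#'
#' The 13-item Alzheimer's Disease Assessment Scale - Cognitive subscale
#' (ADAS-Cog-13) scores thirteen cognitive tasks; higher scores indicate more
#' impairment. Per-item maxima follow the standard ADAS-Cog-13 scoring
#' (word-list recall and delayed recall 0-10, word recognition 0-12,
#' orientation 0-8, all remaining tasks 0-5), so the total ranges 0-85.
#'
#' @return A tibble with one row per item: `item` (identifier), `min_score`,
#'   `max_score` (integer score bounds) and `memory_item` (`TRUE` for the
#'   three word-memory tasks: word recall, delayed word recall, word
#'   recognition).
#' @examples
#' adas_item_schema()
#' sum(adas_item_schema()$max_score) # 85
#' @export
adas_item_schema <- function() {
  tibble::tibble(
    item = c(
      "WORDRECALL", "COMMAND", "CONSTRUCT", "DELAYWORD", "NAMING",
      "IDEATIONAL", "ORIENT", "WORDRECOG", "RMBRTESTINSTR", "LANGUAGE",
      "WORDFIND", "SPOKENLG", "NUMBERCANCEL"
    ),
    min_score = 0L,
    max_score = c(10L, 5L, 5L, 10L, 5L, 5L, 8L, 12L, 5L, 5L, 5L, 5L, 5L),
    memory_item = item %in% c("WORDRECALL", "DELAYWORD", "WORDRECOG")
  )
}

#' Names of the 13 ADAS-Cog-13 items
#'
#' @return Character vector of the 13 item identifiers, in schema order.
#' @export
adas_items <- function() adas_item_schema()$item

#' DSM-5 cognitive-domain annotation sheet
#'
#' Informational mapping from ADAS-Cog-13 items to the six DSM-5
#' neurocognitive domains (learning and memory; language; executive function;
#' perceptual-motor; complex attention; social cognition). Only associations
#' that are well established for the word-memory, orientation, command and
#' word-finding tasks are filled in; the remaining items are deliberately left
#' unannotated rather than guessed, and the sheet is flagged as partially
#' inferred. Intended as an editable clinician-facing annotation, not an
#' analysis input.
#'
#' @return A tibble with columns `item`, `domains` (list-column of character
#'   vectors, possibly empty) and `inferred` (logical; `TRUE` where the
#'   mapping is an editorial inference rather than a stated association).
#' @export
adas_domain_annotation <- function() {
  memory <- c("learning and memory", "language")
  cluster2 <- c("executive function", "perceptual-motor")
  schema <- adas_item_schema()
  tibble::tibble(
    item = schema$item,
    domains = purrr::map(schema$item, function(it) {
      if (it %in% c("WORDRECALL", "DELAYWORD", "WORDRECOG")) memory
      else if (it %in% c("ORIENT", "COMMAND", "WORDFIND")) cluster2
      else character(0)
    }),
    inferred = schema$item %in% c("ORIENT", "COMMAND", "WORDFIND")
  )
}

#' Reference feature-selection scores for the 13 items
#'
#' A worked example shipped with the package: raw and normalized information
#' gain (IG), chi-squared (CST) and ReliefF scores for the 13 ADAS-Cog-13
#' items as obtained in a published ADNI-based progression analysis, printed
#' to three decimals. Used by the package's validation suite to exercise the
#' normalize-average-rank-cluster stage against known output.
#'
#' @return A tibble with columns `item`, `ig_raw`, `ig_norm`, `cst_raw`,
#'   `cst_norm`, `relieff_raw`, `relieff_norm`, `avg_score`.
#' @examples
#' adas_reference_scores()
#' @export
adas_reference_scores <- function() {
  path <- system.file("extdata", "adas_reference_scores.csv",
    package = "cogprog", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE)
}
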