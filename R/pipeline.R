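#' Read a pipeline run configuration
#'
#' Reads a single YAML document with optional sections `cohort` (see
#' [cohort_config()]), `balance` (`k_neighbors`, `target_minority_ratio`,
#' `seed`), `eval` (`n_folds`, `classifiers`, `seed`), and top-level
#' `drop_threshold_pct` (default 30), `correlation_cutoff` (default 0.6) and
#' `fs_on_balanced` (default `TRUE`: feature scores computed on the balanced
#' dataset). Omitted fields fall back to package defaults.
#'
#' @param path Path to a YAML file, or a named list with the same structure.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path = NULL) {
  raw <- if (is.null(path)) {
    list()
  } else if (is.character(path)) {
    yaml::read_yaml(path)
  } else {
    path
  }
  cfg <- list(
    cohort = do.call(cohort_config, raw$cohort %||% list()),
    balance = utils::modifyList(
      list(k_neighbors = 5, target_minority_ratio = 0.5, seed = 1L),
      raw$balance %||% list()
    ),
    eval = utils::modifyList(
      list(n_folds = 10, classifiers = available_classifiers(), seed = 1L),
      raw$eval %||% list()
    ),
    drop_threshold_pct = raw$drop_threshold_pct %||% 30,
    correlation_cutoff = raw$correlation_cutoff %||% 0.6,
    fs_on_balanced = raw$fs_on_balanced %||% TRUE
  )
  if (!(cfg$drop_threshold_pct > 0 && cfg$drop_threshold_pct <= 100)) {
    abort_config("drop_threshold_pct", "must be in (0, 100]")
  }
  if (!(cfg$correlation_cutoff > 0 && cfg$correlation_cutoff <= 1)) {
    abort_config("correlation_cutoff", "must be in (0, 1]")
  }
  if (cfg$eval$n_folds < 2) abort_config("n_folds", "must be >= 2")
  if (length(cfg$eval$classifiers) == 0) {
    abort_config("classifiers", "must be non-empty")
  }
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> ingest -> label -> balance -> rank -> evaluate as
#' one reproducible run: generates (or reads) the two cohort tables, cleans
#' and integrates them, constructs the binary progression label, balances
#' with SMOTE and shuffles, scores and clusters the items, applies the
#' correlation filter, derives the five subsets, and evaluates them under
#' stratified cross-validation in both demographic phases. All artifacts are
#' written under `output_dir` together with a manifest recording seeds and
#' the row counts at every stage.
#'
#' @param config A [run_config()] (or YAML path / list accepted by it).
#' @param output_dir Directory for the run artifacts.
#' @return Invisibly, a list with the stage outputs (`labeled`, `balanced`,
#'   `rank_table`, `subsets`, `evaluation`, `manifest`).
#' @export
run_pipeline <- function(config = run_config(), output_dir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  items <- adas_items()
  manifest <- list(
    package_version = as.character(utils::packageVersion("cogprog")),
    seeds = list(
      cohort = config$cohort$seed,
      balance = config$balance$seed,
      eval = config$eval$seed
    ),
    counts = list()
  )
  count <- function(name, value) manifest$counts[[name]] <<- value

  # simulate
  cohort <- generate_cohort(config$cohort)
  paths <- write_cohort(cohort, file.path(output_dir, "cohort"))
  count("merge_rows_written", nrow(cohort$merge))
  count("adas_rows_written", nrow(cohort$adas))

  # ingest + integrate
  merge_tbl <- read_cohort_table(
    paths["merge"],
    c("RID", "VISCODE", "DX", "AGE", "PTGEN", "PTEDUCAT", "PTRACCAT", "PTMARRY")
  )
  adas_tbl <- read_cohort_table(paths["adas"], c("RID", "VISCODE2", items))
  merge_tbl <- drop_incomplete(merge_tbl, c("RID", "VISCODE", "DX"))
  adas_tbl <- drop_incomplete(adas_tbl)
  count("merge_rows_clean", nrow(merge_tbl))
  count("adas_rows_clean", nrow(adas_tbl))
  visits <- integrate_visits(merge_tbl, adas_tbl)
  count("joined_rows", nrow(visits))

  # label
  labeled <- label_progression(visits)
  count("regressions_removed", attr(labeled, "regressions_removed"))
  count("labeled_rows", nrow(labeled))
  count("progression_rows", sum(labeled$dx_progress == 1))
  readr::write_csv(labeled, file.path(output_dir, "labeled.csv"), na = "")

  # balance
  encoded <- labeled |>
    dplyr::select(dplyr::all_of(c(
      items, "age", "pteducat", "ptgen", "ptraccat", "ptmarry", "dx_progress"
    ))) |>
    encode_demographics()
  balanced <- smote_oversample(
    encoded,
    class_col = "dx_progress",
    k_neighbors = config$balance$k_neighbors,
    target_minority_ratio = config$balance$target_minority_ratio,
    seed = config$balance$seed
  )
  count("synthetic_added", attr(balanced, "n_synthetic"))
  balanced <- shuffle_rows(balanced, seed = config$balance$seed)
  count("balanced_rows", nrow(balanced))
  readr::write_csv(balanced, file.path(output_dir, "balanced.csv"), na = "")

  # rank
  fs_data <- if (isTRUE(config$fs_on_balanced)) balanced else encoded
  scores <- score_features(fs_data,
    items = items,
    seed = config$balance$seed
  )
  ranked <- assign_clusters(
    rank_and_drops(scores),
    threshold_pct = config$drop_threshold_pct
  )
  removed <- correlation_filter(
    pearson_matrix(fs_data, items),
    cutoff = config$correlation_cutoff
  )
  subsets <- derive_subsets(ranked, removed, scores)
  rank_out <- dplyr::left_join(
    ranked, dplyr::select(scores, -"avg_score"),
    by = "item"
  )
  readr::write_csv(rank_out, file.path(output_dir, "rank_table.csv"), na = "")
  jsonlite::write_json(
    purrr::map(
      stats::setNames(seq_len(nrow(subsets)), subsets$subset),
      function(i) {
        list(items = subsets$items[[i]], criterion = subsets$criterion[i])
      }
    ),
    file.path(output_dir, "subsets.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  # evaluate
  evaluation <- evaluate_subsets(
    balanced, subsets,
    classifiers = config$eval$classifiers,
    n_folds = config$eval$n_folds,
    seed = config$eval$seed
  )
  report <- report_table(evaluation, file.path(output_dir, "table7.csv"))

  # annotation sheet + manifest
  annotation <- adas_domain_annotation() |>
    dplyr::mutate(domains = purrr::map_chr(
      .data$domains, paste, collapse = "; "
    ))
  readr::write_csv(annotation, file.path(output_dir, "annotation.csv"))
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))

  invisible(list(
    labeled = labeled, balanced = balanced, rank_table = ranked,
    removed = removed, subsets = subsets, evaluation = evaluation,
    report = report, manifest = manifest
  ))
}
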