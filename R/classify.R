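#' Stratified cross-validation fold assignment
#'
#' Assigns each row to one of `n_folds` folds so that per-fold class
#' proportions match the global proportions up to integer rounding: within
#' each class, rows are shuffled (seeded) and dealt round-robin across folds.
#'
#' @param labels Class labels (both classes must be present).
#' @param n_folds Number of folds (default 10); must not exceed the minority
#'   class count.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:n_folds`, one per row.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2) {
    rlang::abort("both classes must be present", class = "cogprog_cv_error")
  }
  if (n_folds < 2 || n_folds > min(counts)) {
    rlang::abort(
      sprintf(
        "cannot build %d stratified folds: smallest class has %d row(s)",
        n_folds, min(counts)
      ),
      class = "cogprog_cv_error"
    )
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

classifier_registry <- function() {
  list(
    bayes_net = list(
      fit = function(x, y) e1071::naiveBayes(x, y),
      predict = function(fit, x) stats::predict(fit, x)
    ),
    logistic_regression = list(
      fit = function(x, y) {
        df <- data.frame(x, .y = y, check.names = TRUE)
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(fit, x) {
        p <- suppressWarnings(
          stats::predict(fit, newdata = data.frame(x, check.names = TRUE),
                         type = "response")
        )
        factor(ifelse(p > 0.5, "1", "0"), levels = c("0", "1"))
      }
    ),
    decision_tree = list(
      fit = function(x, y) {
        df <- data.frame(x, .y = y, check.names = TRUE)
        rpart::rpart(.y ~ .,
          data = df, method = "class",
          parms = list(split = "information")
        )
      },
      predict = function(fit, x) {
        stats::predict(fit,
          newdata = data.frame(x, check.names = TRUE),
          type = "class"
        )
      }
    )
  )
}

#' Names of the available classifier families
#'
#' `bayes_net` (naive Bayes), `logistic_regression` (unregularized logistic
#' regression) and `decision_tree` (information-split decision tree with
#' complexity pruning) — counterparts of the Bayesian-network, logistic and
#' C4.5 learners commonly used for this task.
#'
#' @return Character vector of classifier names.
#' @export
available_classifiers <- function() names(classifier_registry())

confusion_metrics <- function(tp, fp, tn, fn) {
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp)
  )
}

#' Cross-validated evaluation of an item subset
#'
#' Trains each requested classifier on `n_folds - 1` stratified folds and
#' predicts the held-out fold, pooling the confusion counts over folds
#' (micro-average). The progression class `"1"` is the positive class.
#' Accuracy, sensitivity and specificity are reported in percent.
#'
#' @param data Balanced, labeled dataset (e.g. after [smote_oversample()] and
#'   [shuffle_rows()]).
#' @param items Feature columns to train on.
#' @param class_col Binary class column (default `"dx_progress"`).
#' @param classifiers Subset of [available_classifiers()].
#' @param n_folds,seed Passed to [stratified_folds()].
#' @param include_demographics If `TRUE`, demographic columns present in
#'   `data` (age, pteducat and any `ptgen_`/`ptraccat_`/`ptmarry_`
#'   indicators, or the raw categorical columns) are added to the features.
#' @return A `cog_eval` tibble: one row per classifier with pooled confusion
#'   counts and the three metrics.
#' @export
cross_validate <- function(data, items, class_col = "dx_progress",
                           classifiers = available_classifiers(),
                           n_folds = 10, seed = 1L,
                           include_demographics = FALSE) {
  data <- tibble::as_tibble(data)
  registry <- classifier_registry()
  unknown <- setdiff(classifiers, names(registry))
  if (length(unknown) > 0) {
    rlang::abort(
      sprintf("unknown classifier(s): %s", paste(unknown, collapse = ", ")),
      class = "cogprog_cv_error"
    )
  }
  feats <- items
  if (include_demographics) {
    demo <- c(
      "age", "pteducat",
      grep("^(ptgen|ptraccat|ptmarry)", names(data), value = TRUE)
    )
    feats <- c(feats, intersect(demo, names(data)))
  }
  stopifnot(all(feats %in% names(data)), class_col %in% names(data))
  y <- factor(as.character(data[[class_col]]), levels = c("0", "1"))
  if (anyNA(y)) {
    rlang::abort("class column must be binary 0/1", class = "cogprog_cv_error")
  }
  x <- data[, feats, drop = FALSE]
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.character), factor))
  fold <- stratified_folds(y, n_folds = n_folds, seed = seed)

  results <- purrr::map(classifiers, function(name) {
    cls <- registry[[name]]
    tp <- fp <- tn <- fn <- 0L
    for (f in seq_len(n_folds)) {
      train <- fold != f
      if (length(unique(y[train])) < 2) {
        rlang::abort(
          sprintf("fold %d: training data contains a single class", f),
          class = "cogprog_cv_error"
        )
      }
      fit <- cls$fit(x[train, , drop = FALSE], y[train])
      pred <- cls$predict(fit, x[!train, , drop = FALSE])
      truth <- y[!train]
      tp <- tp + sum(pred == "1" & truth == "1")
      fp <- fp + sum(pred == "1" & truth == "0")
      tn <- tn + sum(pred == "0" & truth == "0")
      fn <- fn + sum(pred == "0" & truth == "1")
    }
    dplyr::bind_cols(
      tibble::tibble(classifier = name),
      confusion_metrics(tp, fp, tn, fn)
    )
  })
  out <- purrr::list_rbind(results)
  class(out) <- c("cog_eval", class(out))
  out
}

#' Evaluate every derived subset, with and without demographics
#'
#' Runs [cross_validate()] for each non-duplicate subset in both phases
#' (cognitive items only; items plus demographics) and stacks the results.
#'
#' @param data Balanced, labeled dataset.
#' @param subsets A [derive_subsets()] result.
#' @param skip_duplicates Skip subsets flagged `duplicate_of` (default TRUE,
#'   as re-evaluating an identical item list is redundant).
#' @inheritParams cross_validate
#' @return A `cog_eval` tibble with `subset`, `phase`
#'   (`"no_demographics"` / `"with_demographics"`) and per-classifier
#'   metrics.
#' @export
evaluate_subsets <- function(data, subsets,
                             classifiers = available_classifiers(),
                             class_col = "dx_progress",
                             n_folds = 10, seed = 1L,
                             skip_duplicates = TRUE) {
  stopifnot(inherits(subsets, "cog_subsets") ||
    all(c("subset", "items") %in% names(subsets)))
  rows <- subsets
  if (skip_duplicates && "duplicate_of" %in% names(rows)) {
    rows <- dplyr::filter(rows, is.na(.data$duplicate_of))
  }
  grid <- tidyr::expand_grid(
    i = seq_len(nrow(rows)),
    phase = c("no_demographics", "with_demographics")
  )
  out <- purrr::pmap(grid, function(i, phase) {
    cross_validate(
      data,
      items = rows$items[[i]], class_col = class_col,
      classifiers = classifiers, n_folds = n_folds, seed = seed,
      include_demographics = phase == "with_demographics"
    ) |>
      dplyr::mutate(subset = rows$subset[i], phase = phase, .before = 1)
  }) |>
    purrr::list_rbind()
  class(out) <- c("cog_eval", class(out))
  out
}

#' Arrange evaluation results as a report table
#'
#' Pivots a [evaluate_subsets()] result into the conventional report layout:
#' one row per subset and classifier, metric columns grouped by phase
#' (without / with demographics), percentages rounded to two decimals.
#' Missing runs render as `NA` with a warning.
#'
#' @param results A `cog_eval` tibble with `subset`, `phase`, `classifier`
#'   and metric columns.
#' @param path Optional CSV path to write the table to.
#' @return A wide tibble with columns
#'   `accuracy_no_demo`, `sensitivity_no_demo`, `specificity_no_demo`,
#'   `accuracy_demo`, `sensitivity_demo`, `specificity_demo`.
#' @export
report_table <- function(results, path = NULL) {
  results <- tibble::as_tibble(results)
  wide <- results |>
    dplyr::mutate(
      phase = dplyr::recode(.data$phase,
        no_demographics = "no_demo", with_demographics = "demo"
      )
    ) |>
    dplyr::select(
      "subset", "classifier", "phase",
      "accuracy", "sensitivity", "specificity"
    ) |>
    dplyr::mutate(dplyr::across(
      c("accuracy", "sensitivity", "specificity"), ~ round(.x, 2)
    )) |>
    tidyr::pivot_wider(
      names_from = "phase",
      values_from = c("accuracy", "sensitivity", "specificity"),
      names_glue = "{.value}_{phase}"
    )
  if (anyNA(wide)) rlang::warn("report_table: missing run(s) rendered as NA")
  if (!is.null(path)) readr::write_csv(wide, path, na = "NA")
  wide
}
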