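#' One-hot encode categorical demographic columns
#'
#' Replaces the categorical demographics (`ptgen`, `ptraccat`, `ptmarry`)
#' with 0/1 indicator columns so the full feature matrix is numeric — a
#' prerequisite for SMOTE's Euclidean neighbour search. Numeric demographics
#' (`age`, `pteducat`) pass through unchanged.
#'
#' @param data A data frame.
#' @param cols Character vector of categorical columns to encode (only those
#'   present are used).
#' @return A tibble with each encoded column replaced by indicators named
#'   `<col>_<level>`.
#' @export
encode_demographics <- function(data, cols = c("ptgen", "ptraccat", "ptmarry")) {
  data <- tibble::as_tibble(data)
  for (col in intersect(cols, names(data))) {
    v <- factor(data[[col]])
    ind <- stats::model.matrix(~ v - 1)
    colnames(ind) <- paste(col, levels(v), sep = "_")
    colnames(ind) <- gsub("[^[:alnum:]_]+", "_", colnames(ind))
    data <- dplyr::bind_cols(
      dplyr::select(data, -dplyr::all_of(col)),
      tibble::as_tibble(ind)
    )
  }
  data
}

#' SMOTE oversampling of the minority class
#'
#' Standard SMOTE: each synthetic observation is a convex combination
#' `x + u (z - x)`, `u ~ Uniform(0, 1)`, of a random minority point `x` and
#' one of its `k_neighbors` nearest minority neighbours `z` under Euclidean
#' distance. Enough synthetic rows are added to bring the minority fraction
#' within one sample of `target_minority_ratio`; original rows are preserved
#' unchanged. Because SMOTE interpolates, synthetic item scores may be
#' fractional; downstream scoring bins them back to the integer grid.
#'
#' @param data A data frame whose feature columns are numeric.
#' @param class_col Name of the binary class column (default `"dx_progress"`).
#' @param feature_cols Feature columns used for the neighbour search and
#'   interpolation; defaults to every numeric column except `class_col`.
#'   Non-feature, non-class columns are filled with `NA` in synthetic rows.
#' @param k_neighbors Number of minority nearest neighbours (default 5).
#' @param target_minority_ratio Desired minority fraction of the balanced
#'   dataset, in (0, 0.5] (default 0.5).
#' @param seed Integer seed; fixed seed gives an identical synthetic set.
#' @return A tibble: the original rows followed by the synthetic minority
#'   rows. Attributes: `"n_synthetic"`, `"minority_label"`.
#' @export
smote_oversample <- function(data, class_col = "dx_progress",
                             feature_cols = NULL, k_neighbors = 5,
                             target_minority_ratio = 0.5, seed = 1L) {
  data <- tibble::as_tibble(data)
  stopifnot(class_col %in% names(data))
  if (!(target_minority_ratio > 0 && target_minority_ratio <= 0.5)) {
    abort_config("target_minority_ratio", "must be in (0, 0.5]")
  }
  if (k_neighbors < 1) abort_config("k_neighbors", "must be >= 1")
  y <- data[[class_col]]
  tab <- sort(table(y))
  if (length(tab) != 2) {
    rlang::abort("class column must be binary", class = "cogprog_balance_error")
  }
  minority <- names(tab)[1]
  n_min <- tab[[1]]
  n_maj <- tab[[2]]
  if (n_min < k_neighbors + 1) {
    rlang::abort(
      sprintf(
        "minority class too small for SMOTE: %d minority row(s), need >= %d (k_neighbors + 1)",
        n_min, k_neighbors + 1
      ),
      class = "cogprog_balance_error"
    )
  }
  if (is.null(feature_cols)) {
    feature_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, class_col)
  }
  n_syn <- round(
    target_minority_ratio / (1 - target_minority_ratio) * n_maj
  ) - n_min
  if (n_syn <= 0) {
    message("smote_oversample: classes already at target ratio; nothing added")
    return(structure(data, n_synthetic = 0L, minority_label = minority))
  }

  set.seed(seed)
  x_min <- as.matrix(data[y == minority, feature_cols, drop = FALSE])
  d <- as.matrix(stats::dist(x_min))
  diag(d) <- Inf
  # k nearest minority neighbours of each minority point, stable order
  nn <- apply(d, 1, function(row) order(row)[seq_len(k_neighbors)])
  nn <- if (is.matrix(nn)) t(nn) else matrix(nn, ncol = 1L)

  base_idx <- sample.int(n_min, n_syn, replace = TRUE)
  nb_pick <- sample.int(k_neighbors, n_syn, replace = TRUE)
  u <- stats::runif(n_syn)
  nb_idx <- nn[cbind(base_idx, nb_pick)]
  syn <- x_min[base_idx, , drop = FALSE] +
    u * (x_min[nb_idx, , drop = FALSE] - x_min[base_idx, , drop = FALSE])

  syn_tbl <- tibble::as_tibble(as.data.frame(syn))
  syn_tbl[[class_col]] <- rep(
    data[[class_col]][y == minority][1], n_syn
  )
  out <- dplyr::bind_rows(data, syn_tbl)
  message(sprintf(
    "smote_oversample: added %d synthetic minority row(s) (%s -> %d of %d)",
    n_syn, minority, n_min + n_syn, nrow(out)
  ))
  structure(out, n_synthetic = n_syn, minority_label = minority)
}

#' Seeded row shuffle
#'
#' Uniformly permutes the rows of a dataset so that synthetic minority rows
#' added at the end of the table do not concentrate in particular
#' cross-validation folds. The row multiset is unchanged.
#'
#' @param data A data frame.
#' @param seed Integer seed.
#' @return The row-permuted tibble.
#' @export
shuffle_rows <- function(data, seed = 1L) {
  data <- tibble::as_tibble(data)
  set.seed(seed)
  data[sample.int(nrow(data)), , drop = FALSE]
}
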