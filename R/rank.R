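#' Information gain of a discrete feature about a class
#'
#' Reduction in class entropy given the feature, in bits:
#' `H(class) - H(class | feature)`. Item scores are ordinal integers;
#' fractional values (e.g. SMOTE-interpolated scores) are binned to the
#' nearest integer grid point before counting, mirroring how discretizing
#' filter implementations treat them.
#'
#' @param x Feature values (treated as categories after integer binning when
#'   numeric).
#' @param y Class labels.
#' @return Information gain in bits (>= 0, <= H(class)).
#' @examples
#' info_gain(c(0, 0, 1, 1, 2, 2), c(0, 0, 0, 1, 1, 1)) # 2/3 bit
#' @export
info_gain <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("empty input", class = "cogprog_fs_error")
  }
  stopifnot(length(x) == length(y))
  if (is.numeric(x)) x <- round(x)
  entropy <- function(v) {
    p <- table(v) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h_y <- entropy(y)
  cond <- vapply(
    split(seq_along(x), as.character(x)),
    function(idx) length(idx) / length(x) * entropy(y[idx]),
    numeric(1)
  )
  max(h_y - sum(cond), 0)
}

#' Pearson chi-squared statistic of a feature against a class
#'
#' The chi-squared statistic of the feature-by-class contingency table
#' (no continuity correction). Fractional feature values are binned to the
#' nearest integer first, as in [info_gain()].
#'
#' @inheritParams info_gain
#' @return The chi-squared statistic (>= 0); 0 with a warning for a
#'   degenerate table (a single class or a single feature level).
#' @export
chi_squared <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    rlang::abort("empty input", class = "cogprog_fs_error")
  }
  if (is.numeric(x)) x <- round(x)
  tab <- table(x, y)
  if (any(dim(tab) < 2)) {
    rlang::warn("degenerate contingency table; chi-squared statistic set to 0")
    return(0)
  }
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

#' ReliefF feature weights
#'
#' Instance-based feature weighting (Kononenko's ReliefF): for each sampled
#' instance, each feature's weight increases with its mean range-normalized
#' difference to the instance's `k_neighbors` nearest misses (other class)
#' and decreases with the mean difference to its nearest hits (same class).
#' Neighbours are found under Manhattan distance over range-normalized
#' features; weights are averaged over the sampled instances and lie in
#' \[-1, 1\]. Weights are invariant under affine rescaling of any feature.
#'
#' @param x Numeric feature matrix or data frame (instances in rows).
#' @param y Binary class labels (length `nrow(x)`).
#' @param k_neighbors Neighbours per class (default 10); must not exceed
#'   either class count minus one.
#' @param m_samples `"all"` (default) to use every instance, or an integer
#'   number of instances to sample.
#' @param seed Seed for the instance sample (only used when
#'   `m_samples != "all"`).
#' @return Named numeric vector of feature weights.
#' @export
relieff <- function(x, y, k_neighbors = 10, m_samples = "all", seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(length(y) == n)
  y <- as.character(y)
  counts <- table(y)
  if (length(counts) != 2) {
    rlang::abort("binary class required", class = "cogprog_fs_error")
  }
  if (k_neighbors > min(counts) - 1) {
    rlang::abort(
      sprintf(
        "k_neighbors = %d too large: smallest class has %d instance(s)",
        k_neighbors, min(counts)
      ),
      class = "cogprog_fs_error"
    )
  }
  rng <- apply(x, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1 # constant feature: all diffs 0, weight stays 0
  xn <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")

  if (identical(m_samples, "all")) {
    sampled <- seq_len(n)
  } else {
    set.seed(seed)
    sampled <- sample.int(n, min(as.integer(m_samples), n))
  }
  m <- length(sampled)
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  idx_by_class <- split(seq_len(n), y)

  w <- numeric(ncol(x))
  for (i in sampled) {
    hits <- idx_by_class[[y[i]]]
    hits <- hits[hits != i]
    misses <- idx_by_class[[setdiff(names(idx_by_class), y[i])]]
    nh <- hits[order(d[i, hits])[seq_len(k_neighbors)]]
    nm <- misses[order(d[i, misses])[seq_len(k_neighbors)]]
    diff_h <- abs(xn[nh, , drop = FALSE] -
      matrix(xn[i, ], k_neighbors, ncol(x), byrow = TRUE))
    diff_m <- abs(xn[nm, , drop = FALSE] -
      matrix(xn[i, ], k_neighbors, ncol(x), byrow = TRUE))
    w <- w + colSums(diff_m) - colSums(diff_h)
  }
  w <- w / (m * k_neighbors)
  names(w) <- colnames(x)
  w
}

#' Min-max normalization to \[0, 1\]
#'
#' `(s - min) / (max - min)` over a vector of raw scores; each scoring
#' method's column is normalized independently so the three methods share a
#' common scale before averaging.
#'
#' @param x Numeric vector (>= 2 values).
#' @return Normalized vector; all zeros with a warning when `max == min`.
#' @export
minmax_normalize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) {
    rlang::warn("degenerate range (max == min); normalized scores set to 0")
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Composite average of the three normalized method scores
#'
#' Adds `avg_score`, the unweighted mean of `ig_norm`, `cst_norm` and
#' `relieff_norm`, to a feature-score table.
#'
#' @param scores A data frame with columns `ig_norm`, `cst_norm`,
#'   `relieff_norm`.
#' @return The input tibble with an `avg_score` column.
#' @export
ensemble_average <- function(scores) {
  scores <- tibble::as_tibble(scores)
  need <- c("ig_norm", "cst_norm", "relieff_norm")
  stopifnot(all(need %in% names(scores)))
  dplyr::mutate(
    scores,
    avg_score = (.data$ig_norm + .data$cst_norm + .data$relieff_norm) / 3
  )
}

#' Score the 13 items with the three-method ensemble
#'
#' Computes raw information-gain, chi-squared and ReliefF scores for each
#' item against the binary progression class, min-max normalizes each
#' method's column across items, and averages the normalized scores into a
#' composite.
#'
#' @param data Labeled (optionally balanced) dataset.
#' @param items Item columns to score (default the 13 ADAS-Cog-13 items).
#' @param class_col Binary class column (default `"dx_progress"`).
#' @param relieff_k,relieff_m,seed Passed to [relieff()].
#' @return A `cog_score_table` tibble: `item`, `ig_raw`, `cst_raw`,
#'   `relieff_raw`, `ig_norm`, `cst_norm`, `relieff_norm`, `avg_score`.
#' @export
score_features <- function(data, items = adas_items(),
                           class_col = "dx_progress",
                           relieff_k = 10, relieff_m = "all", seed = 1L) {
  data <- tibble::as_tibble(data)
  stopifnot(all(items %in% names(data)), class_col %in% names(data))
  y <- data[[class_col]]
  x <- as.matrix(data[, items, drop = FALSE])
  rf <- relieff(x, y, k_neighbors = relieff_k, m_samples = relieff_m, seed = seed)
  out <- tibble::tibble(
    item = items,
    ig_raw = vapply(items, function(it) info_gain(data[[it]], y), numeric(1)),
    cst_raw = vapply(items, function(it) chi_squared(data[[it]], y), numeric(1)),
    relieff_raw = unname(rf[items])
  ) |>
    dplyr::mutate(
      ig_norm = minmax_normalize(.data$ig_raw),
      cst_norm = minmax_normalize(.data$cst_raw),
      relieff_norm = minmax_normalize(.data$relieff_raw)
    ) |>
    ensemble_average()
  class(out) <- c("cog_score_table", class(out))
  out
}

#' Rank items and compute successive score drops
#'
#' Sorts items by descending composite score (ties broken by item-schema
#' order, deterministically) and computes the relative drop between
#' successive ranked scores, `(S_i - S_(i+1)) / S_i * 100` percent.
#'
#' @param scores A data frame with columns `item` and `avg_score` (e.g. a
#'   [score_features()] result).
#' @return A `cog_rank_table` tibble: `item`, `avg_score`, `rank`,
#'   `drop_pct` (`NA` for rank 1; 0 with a warning where the predecessor
#'   score is 0).
#' @export
rank_and_drops <- function(scores) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("item", "avg_score") %in% names(scores)))
  schema_order <- match(scores$item, adas_items())
  schema_order[is.na(schema_order)] <- length(adas_items()) + seq_len(sum(is.na(schema_order)))
  out <- scores |>
    dplyr::select("item", "avg_score") |>
    dplyr::arrange(dplyr::desc(.data$avg_score), schema_order) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      drop_pct = dplyr::if_else(
        .data$rank == 1L,
        NA_real_,
        (dplyr::lag(.data$avg_score) - .data$avg_score) /
          dplyr::lag(.data$avg_score) * 100
      )
    )
  bad <- !is.na(out$drop_pct) & !is.finite(out$drop_pct)
  zero_pred <- which(out$rank > 1 & dplyr::lag(out$avg_score) == 0)
  if (any(bad) || length(zero_pred) > 0) {
    rlang::warn("zero predecessor score; drop defined as 0")
    out$drop_pct[bad] <- 0
    out$drop_pct[zero_pred] <- 0
  }
  class(out) <- c("cog_rank_table", class(out))
  out
}

#' Cluster ranked items by the score-drop rule
#'
#' Walks the ranking from the top: the first item opens cluster 1, and each
#' subsequent item opens a new cluster exactly when its drop from the
#' predecessor exceeds `threshold_pct`, otherwise it joins the predecessor's
#' cluster. A larger threshold can only merge clusters, never split them.
#'
#' @param ranked A [rank_and_drops()] result.
#' @param threshold_pct Drop threshold in percent (default 30).
#' @return The input tibble with an integer `cluster` column.
#' @export
assign_clusters <- function(ranked, threshold_pct = 30) {
  ranked <- tibble::as_tibble(ranked)
  stopifnot(all(c("item", "avg_score", "drop_pct") %in% names(ranked)))
  new_cluster <- !is.na(ranked$drop_pct) & ranked$drop_pct > threshold_pct
  out <- dplyr::mutate(ranked, cluster = 1L + cumsum(new_cluster))
  class(out) <- c("cog_rank_table", class(out))
  out
}

#' Pearson correlation matrix of item columns
#'
#' Feature-to-feature Pearson correlations, excluding the class attribute.
#' Zero-variance features yield undefined correlations, which are set to 0
#' with a warning (diagonal stays 1).
#'
#' @param data A data frame.
#' @param cols Columns to correlate (default the 13 items present in `data`).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(data, cols = intersect(adas_items(), names(data))) {
  data <- tibble::as_tibble(data)
  stopifnot(length(cols) >= 1, nrow(data) >= 2)
  r <- suppressWarnings(stats::cor(as.matrix(data[, cols, drop = FALSE])))
  if (anyNA(r)) {
    rlang::warn("zero-variance feature(s); undefined correlations set to 0")
    r[is.na(r)] <- 0
    diag(r) <- 1
  }
  r
}

#' Correlation-based redundancy filter
#'
#' Iteratively removes redundant features: while any feature pair has
#' `|r| > cutoff` (pairs visited in decreasing `|r|`), the member of the pair
#' with the larger mean absolute correlation to all remaining features is
#' discarded. Removed features are returned in removal order.
#'
#' @param cor_mat A correlation matrix (e.g. from [pearson_matrix()]).
#' @param cutoff Absolute-correlation cutoff (default 0.60).
#' @return Character vector of removed feature names (possibly empty).
#' @export
correlation_filter <- function(cor_mat, cutoff = 0.60) {
  stopifnot(is.matrix(cor_mat), nrow(cor_mat) == ncol(cor_mat))
  keep <- colnames(cor_mat)
  removed <- character(0)
  repeat {
    r <- abs(cor_mat[keep, keep, drop = FALSE])
    diag(r) <- 0
    if (length(keep) < 2 || max(r) <= cutoff) break
    pair <- which(r == max(r), arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(r) * length(keep) / (length(keep) - 1)
    i <- keep[pair[["row"]]]
    j <- keep[pair[["col"]]]
    drop <- if (mean_abs[[i]] >= mean_abs[[j]]) i else j
    removed <- c(removed, drop)
    keep <- setdiff(keep, drop)
  }
  removed
}

#' Derive the five item subsets
#'
#' From a clustered ranking, a correlation-filter removal list, and the
#' per-method raw scores, derives:
#' * `subset1` — all items (baseline);
#' * `subset2` — all items minus the correlation-filter removals;
#' * `subset3` — the items of cluster 1;
#' * `subset4` — the items of clusters 1 and 2;
#' * `subset5` — items in the top `top_n` of every scoring method
#'   (`"strict"` mode) or of a majority of methods (`"frequency"` mode).
#'
#' Subsets identical to an earlier subset are flagged in `duplicate_of`
#' (evaluating them again would be redundant).
#'
#' @param ranked A clustered [assign_clusters()] result.
#' @param removed Removal list from [correlation_filter()].
#' @param scores Optional [score_features()] table, needed for `subset5`.
#' @param subset5_mode `"strict"` (default) or `"frequency"`.
#' @param top_n Per-method ranking depth for `subset5` (default 3).
#' @return A `cog_subsets` tibble: `subset`, `items` (list-column),
#'   `n_items`, `criterion`, `duplicate_of`.
#' @export
derive_subsets <- function(ranked, removed = character(0), scores = NULL,
                           subset5_mode = c("strict", "frequency"), top_n = 3) {
  subset5_mode <- match.arg(subset5_mode)
  ranked <- tibble::as_tibble(ranked)
  stopifnot("cluster" %in% names(ranked))
  all_items <- ranked$item

  subsets <- list(
    subset1 = all_items,
    subset2 = setdiff(all_items, removed),
    subset3 = ranked$item[ranked$cluster == 1L],
    subset4 = ranked$item[ranked$cluster %in% c(1L, 2L)]
  )
  criteria <- c(
    subset1 = "all items (baseline)",
    subset2 = "correlation filter: removed highly correlated items",
    subset3 = "cluster 1 of the score-drop clustering",
    subset4 = "clusters 1 and 2 of the score-drop clustering",
    subset5 = sprintf(
      "items in the per-method top %d (%s mode)", top_n, subset5_mode
    )
  )
  if (!is.null(scores)) {
    method_tops <- purrr::map(
      c(ig = "ig_raw", cst = "cst_raw", relieff = "relieff_raw"),
      function(col) {
        ord <- order(-scores[[col]], match(scores$item, adas_items()))
        scores$item[ord][seq_len(min(top_n, nrow(scores)))]
      }
    )
    s5 <- if (subset5_mode == "strict") {
      Reduce(intersect, method_tops)
    } else {
      freq <- table(unlist(method_tops))
      names(freq)[freq >= ceiling(length(method_tops) / 2 + 0.5)]
    }
    s5 <- all_items[all_items %in% s5] # stable order
    if (length(s5) == 0) {
      rlang::warn(
        "subset5 empty: no item is common to the methods' top ranks; omitted"
      )
    } else {
      subsets$subset5 <- s5
    }
  }

  out <- tibble::tibble(
    subset = names(subsets),
    items = unname(purrr::map(subsets, identity)),
    n_items = lengths(subsets),
    criterion = unname(criteria[names(subsets)])
  )
  out$duplicate_of <- NA_character_
  for (i in seq_len(nrow(out))[-1]) {
    for (j in seq_len(i - 1)) {
      if (setequal(out$items[[i]], out$items[[j]])) {
        out$duplicate_of[i] <- out$subset[j]
        break
      }
    }
  }
  class(out) <- c("cog_subsets", class(out))
  out
}
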