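# independent oracles, deliberately using different decompositions than the
# implementation: IG via H(X) + H(Y) - H(X, Y); chi-squared via explicit
# expected-count loops.
oracle_ig <- function(x, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  ent(x) + ent(y) - ent(paste(x, y))
}
oracle_chisq <- function(x, y) {
  tab <- table(x, y)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

test_that("information gain matches hand-computed values", {
  # perfectly predictive feature on a balanced class: the full bit
  expect_equal(info_gain(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # feature independent of the class
  expect_equal(info_gain(c(0, 1, 0, 1), c(0, 0, 1, 1)), 0)
  # three-level feature where only the middle level is uninformative
  expect_equal(info_gain(c(0, 0, 1, 1, 2, 2), c(0, 0, 0, 1, 1, 1)), 2 / 3)
  expect_error(info_gain(numeric(0), numeric(0)), class = "cogprog_fs_error")
})

test_that("chi-squared matches the closed form on 2x2 tables", {
  # counts [[10,0],[0,10]]: n(ad-bc)^2 / row/col products = 20
  x <- rep(c(0, 1), each = 10)
  y <- rep(c(0, 1), each = 10)
  expect_equal(chi_squared(x, y), 20)
  # uniform 2x2 table
  expect_equal(chi_squared(rep(c(0, 1), 10), rep(c(0, 0, 1, 1), 5)), 0)
  expect_warning(res <- chi_squared(rep(1, 5), c(0, 0, 1, 1, 0)), "degenerate")
  expect_equal(res, 0)
})

test_that("IG and chi-squared agree with brute-force oracles on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    x <- sample(0:2, 6, replace = TRUE)
    y <- sample(0:1, 6, replace = TRUE)
    expect_equal(info_gain(x, y), max(oracle_ig(x, y), 0), tolerance = 1e-12)
    if (length(unique(x)) > 1 && length(unique(y)) > 1) {
      expect_equal(chi_squared(x, y), oracle_chisq(x, y), tolerance = 1e-12)
    }
  }
})

test_that("relieff weights behave at the boundary cases", {
  # constant feature: zero weight
  x <- cbind(f1 = rep(1, 20), f2 = c(rep(0, 10), rep(1, 10)))
  y <- rep(c(0, 1), each = 10)
  w <- relieff(x, y, k_neighbors = 1)
  expect_equal(w[["f1"]], 0)
  # perfectly separated 1-D feature: every miss-diff 1, every hit-diff 0
  expect_equal(w[["f2"]], 1)
})

test_that("relieff of a pure-noise feature is near zero", {
  set.seed(55)
  n <- 500
  x <- cbind(noise = stats::rnorm(n))
  y <- sample(rep(c(0, 1), each = n / 2))
  w <- relieff(x, y, k_neighbors = 10)
  expect_lt(abs(w[["noise"]]), 0.05)
})

test_that("relieff weights are invariant under affine feature rescaling", {
  set.seed(77)
  x <- cbind(a = stats::rnorm(60), b = stats::runif(60))
  y <- rep(c(0, 1), each = 30)
  w1 <- relieff(x, y, k_neighbors = 5)
  x2 <- x
  x2[, "a"] <- 100 + 7 * x2[, "a"]
  w2 <- relieff(x2, y, k_neighbors = 5)
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("relieff rejects k larger than a class allows", {
  x <- cbind(a = stats::rnorm(10))
  y <- rep(c(0, 1), c(7, 3))
  expect_error(relieff(x, y, k_neighbors = 5), class = "cogprog_fs_error")
})

test_that("min-max normalization hits both extremes and warns when degenerate", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(c(5, 5, 5)), "degenerate")
  expect_equal(z, c(0, 0, 0))
})

test_that("ensemble averaging is the unweighted mean of the three methods", {
  tbl <- tibble::tibble(
    item = c("A", "B"),
    ig_norm = c(0.246, 0), cst_norm = c(0.242, 0), relieff_norm = c(0.100, 0)
  )
  out <- ensemble_average(tbl)
  expect_equal(out$avg_score, c((0.246 + 0.242 + 0.100) / 3, 0))
})

test_that("ranking computes successive relative drops", {
  tbl <- tibble::tibble(item = c("A", "B", "C"), avg_score = c(1.0, 0.5, 0.5))
  rk <- rank_and_drops(tbl)
  expect_equal(rk$drop_pct, c(NA, 50, 0))
  # zero predecessor: drop defined as 0 with a warning
  tbl0 <- tibble::tibble(item = c("A", "B"), avg_score = c(0, 0))
  expect_warning(rk0 <- rank_and_drops(tbl0), "zero predecessor")
  expect_equal(rk0$drop_pct, c(NA, 0))
})

test_that("clustering opens a new cluster exactly at drops above threshold", {
  tbl <- tibble::tibble(
    item = LETTERS[1:4], avg_score = c(1.0, 0.8, 0.4, 0.35)
  )
  rk <- assign_clusters(rank_and_drops(tbl), threshold_pct = 30)
  expect_equal(rk$cluster, c(1L, 1L, 2L, 2L))
  # unreachable threshold: a single cluster
  rk2 <- assign_clusters(rank_and_drops(tbl), threshold_pct = 101)
  expect_equal(unique(rk2$cluster), 1L)
})

test_that("raising the threshold never increases the number of clusters", {
  set.seed(31)
  for (rep in 1:10) {
    tbl <- tibble::tibble(
      item = paste0("f", 1:8),
      avg_score = sort(stats::runif(8), decreasing = TRUE)
    )
    rk <- rank_and_drops(tbl)
    n_prev <- Inf
    for (thr in c(5, 15, 30, 60, 101)) {
      n <- max(assign_clusters(rk, thr)$cluster)
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("pearson matrix is symmetric with unit diagonal", {
  df <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 4), z = -c(1, 2, 3))
  r <- pearson_matrix(df, cols = c("x", "y", "z"))
  expect_equal(r, t(r))
  expect_equal(diag(r), c(x = 1, y = 1, z = 1))
  expect_equal(r["x", "y"], 0.981980506, tolerance = 1e-8)
  expect_equal(r["x", "z"], -1)
  dfc <- dplyr::mutate(df, w = 1)
  expect_warning(r2 <- pearson_matrix(dfc, cols = names(dfc)), "zero-variance")
  expect_equal(r2["w", "x"], 0)
})

test_that("correlation filter removes the member with larger mean |r|", {
  # f1 == f2 (r = 1); f2 slightly more correlated with f3 than f1 is
  r <- diag(3)
  dimnames(r) <- list(c("f1", "f2", "f3"), c("f1", "f2", "f3"))
  r["f1", "f2"] <- r["f2", "f1"] <- 1
  r["f2", "f3"] <- r["f3", "f2"] <- 0.30
  r["f1", "f3"] <- r["f3", "f1"] <- 0.20
  expect_equal(correlation_filter(r, cutoff = 0.60), "f2")
  # nothing above the cutoff
  expect_equal(correlation_filter(diag(3), cutoff = 0.6), character(0))
})

test_that("correlation filter matches the caret reference on single-pair cases", {
  # with exactly one pair above the cutoff both procedures must discard the
  # same member (the one with the larger mean absolute correlation)
  skip_if_not_installed("caret")
  set.seed(19)
  for (rep in 1:10) {
    n <- 80
    base <- stats::rnorm(n)
    df <- tibble::tibble(
      a = base + stats::rnorm(n, sd = 0.4),
      b = base + stats::rnorm(n, sd = 0.4),
      c = stats::rnorm(n),
      d = stats::rnorm(n)
    )
    r <- stats::cor(as.matrix(df))
    if (sum(abs(r[upper.tri(r)]) > 0.6) != 1) next
    mine <- correlation_filter(r, cutoff = 0.6)
    ref <- colnames(r)[caret::findCorrelation(r, cutoff = 0.6, exact = TRUE)]
    expect_equal(sort(mine), sort(ref))
  }
})

test_that("no remaining pair exceeds the cutoff after filtering", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 50
    base <- stats::rnorm(n)
    x <- sapply(1:6, function(i) base * stats::runif(1) + stats::rnorm(n))
    colnames(x) <- paste0("f", 1:6)
    r <- stats::cor(x)
    removed <- correlation_filter(r, cutoff = 0.6)
    keep <- setdiff(colnames(r), removed)
    rk <- abs(r[keep, keep, drop = FALSE])
    diag(rk) <- 0
    expect_lte(max(rk), 0.6)
    # every removal was necessary: it participated in a pair above cutoff
    expect_true(all(removed %in% colnames(r)))
  }
})

test_that("subsets are derived from clusters, removals and per-method tops", {
  ref <- adas_reference_scores()
  ranked <- assign_clusters(rank_and_drops(ref), threshold_pct = 30)
  subsets <- derive_subsets(
    ranked,
    removed = c("WORDRECALL", "WORDFIND", "LANGUAGE"),
    scores = ref
  )
  get <- function(name) subsets$items[[which(subsets$subset == name)]]
  expect_setequal(get("subset1"), adas_items())
  expect_setequal(get("subset2"), setdiff(adas_items(), c("WORDRECALL", "WORDFIND", "LANGUAGE")))
  expect_setequal(get("subset3"), memory_items)
  expect_setequal(get("subset4"), c(memory_items, "ORIENT", "COMMAND", "WORDFIND"))
  expect_setequal(get("subset5"), memory_items)
  expect_equal(
    subsets$duplicate_of[subsets$subset == "subset5"], "subset3"
  )
})

test_that("a single-cluster ranking makes subsets 3 and 4 the full item list", {
  tbl <- tibble::tibble(item = adas_items(), avg_score = seq(1, 0.9, length.out = 13))
  ranked <- assign_clusters(rank_and_drops(tbl), threshold_pct = 30)
  subsets <- derive_subsets(ranked)
  expect_setequal(subsets$items[[which(subsets$subset == "subset3")]], adas_items())
  expect_setequal(subsets$items[[which(subsets$subset == "subset4")]], adas_items())
})
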