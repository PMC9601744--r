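test_that("stratified folds balance classes exactly when divisible", {
  y <- rep(c(0, 1), each = 50)
  fold <- stratified_folds(y, n_folds = 10, seed = 1)
  tab <- table(fold, y)
  expect_true(all(tab == 5))
  expect_equal(sort(unique(fold)), 1:10)
})

test_that("infeasible stratification is an error", {
  y <- rep(c(0, 1), c(6, 5))
  expect_error(stratified_folds(y, n_folds = 10), class = "cogprog_cv_error")
  expect_error(stratified_folds(rep(0, 20), n_folds = 5), class = "cogprog_cv_error")
})

test_that("per-fold class proportions deviate at most one row per fold", {
  set.seed(21)
  y <- sample(c(0, 1), 1000, replace = TRUE, prob = c(0.7, 0.3))
  fold <- stratified_folds(y, n_folds = 10, seed = 3)
  global <- mean(y == 1)
  for (f in 1:10) {
    in_fold <- y[fold == f]
    expect_lte(abs(mean(in_fold == 1) - global), 1 / length(in_fold))
  }
})

make_separable <- function(n = 200, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  tibble::tibble(
    f1 = y * 10 + stats::rnorm(n, sd = 0.1),
    f2 = stats::rnorm(n),
    dx_progress = y
  )
}

test_that("all classifiers are near-perfect on linearly separable data", {
  df <- make_separable()
  res <- cross_validate(df, items = c("f1", "f2"), n_folds = 10, seed = 2)
  expect_setequal(res$classifier, available_classifiers())
  expect_true(all(res$accuracy >= 99))
})

test_that("metric identities hold against the pooled confusion counts", {
  df <- make_separable()
  res <- cross_validate(df, items = c("f1", "f2"), n_folds = 5, seed = 2)
  with(res, {
    expect_equal(accuracy, 100 * (tp + tn) / (tp + tn + fp + fn), tolerance = 1e-9)
    expect_equal(sensitivity, 100 * tp / (tp + fn), tolerance = 1e-9)
    expect_equal(specificity, 100 * tn / (tn + fp), tolerance = 1e-9)
  })
  # pooled counts account for every row, in every run
  expect_true(all(res$tp + res$fp + res$tn + res$fn == nrow(df)))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
})

test_that("evaluation is deterministic given seed, data and config", {
  df <- make_separable(n = 100)
  r1 <- cross_validate(df, items = c("f1", "f2"), n_folds = 5, seed = 7)
  r2 <- cross_validate(df, items = c("f1", "f2"), n_folds = 5, seed = 7)
  expect_identical(r1, r2)
})

test_that("a class too small for the fold count aborts the run", {
  df <- make_separable(n = 12)
  df$dx_progress <- rep(c(0L, 1L), c(9, 3))
  expect_error(
    cross_validate(df, items = c("f1", "f2"), n_folds = 10, seed = 1,
                   classifiers = "decision_tree"),
    class = "cogprog_cv_error"
  )
  expect_error(
    cross_validate(df, items = c("f1", "f2"), classifiers = "svm"),
    class = "cogprog_cv_error"
  )
})

test_that("report table has one metric triple per subset, classifier and phase", {
  grid <- tidyr::expand_grid(
    subset = paste0("subset", 1:4),
    classifier = available_classifiers(),
    phase = c("no_demographics", "with_demographics")
  )
  res <- dplyr::mutate(grid,
    tp = 5, fp = 5, tn = 5, fn = 5,
    accuracy = 50.123, sensitivity = 50.567, specificity = 50
  )
  wide <- report_table(res)
  expect_equal(nrow(wide), 12) # 4 subsets x 3 classifiers
  metric_cols <- setdiff(names(wide), c("subset", "classifier"))
  expect_length(metric_cols, 6) # 3 metrics x 2 phases = 24 triples over rows
  # values round to two decimals and survive a CSV round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  report_table(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$accuracy_no_demo, rep(50.12, 12))
  # missing run renders NA with a warning
  expect_warning(report_table(res[-1, ]), "NA")
})

test_that("pooled 50/50 confusion counts give 50% on all three metrics", {
  m <- cogprog:::confusion_metrics(5, 5, 5, 5)
  expect_equal(m$accuracy, 50)
  expect_equal(m$sensitivity, 50)
  expect_equal(m$specificity, 50)
})
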