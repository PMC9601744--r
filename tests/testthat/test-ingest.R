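write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}

test_that("read_cohort_table restricts to required columns and checks schema", {
  df <- tibble::tibble(
    RID = 1:3, VISCODE = c("bl", "m06", "m12"), DX = "CN", EXTRA = 9
  )
  path <- write_temp_csv(df)
  out <- suppressMessages(read_cohort_table(path, c("RID", "VISCODE", "DX")))
  expect_equal(nrow(out), 3)
  expect_named(out, c("RID", "VISCODE", "DX"))
  expect_error(
    suppressMessages(read_cohort_table(path, c("RID", "DX2"))),
    "DX2",
    class = "cogprog_schema_error"
  )
  expect_error(
    read_cohort_table(file.path(tempdir(), "nope.csv"), "RID"),
    class = "cogprog_io_error"
  )
})

test_that("drop_incomplete removes rows with missing mandatory fields", {
  df <- tibble::tibble(
    RID = 1:5, DX = c("CN", NA, "MCI", "", "AD"), AGE = 70
  )
  out <- suppressMessages(drop_incomplete(df, c("RID", "DX")))
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "removed")[["DX"]], 2)
  # empty input passes through
  expect_equal(nrow(suppressMessages(drop_incomplete(df[0, ], "DX"))), 0)
})

test_that("integration inner-joins on patient and harmonised visit code", {
  m <- tibble::tibble(
    RID = c(1L, 1L), VISCODE = c("bl", "m06"), DX = "CN", AGE = 70,
    PTGEN = "Female", PTEDUCAT = 16L, PTRACCAT = "White", PTMARRY = "Married"
  )
  a <- tibble::tibble(RID = 1L, VISCODE2 = "BL") # case-insensitive key
  for (it in adas_items()) a[[it]] <- 1
  out <- suppressMessages(integrate_visits(m, a))
  expect_equal(nrow(out), 1)
  expect_equal(out$viscode, "bl")
  expect_equal(attr(out, "unmatched")[["merge"]], 1)

  # disjoint keys -> empty result with a warning
  a2 <- dplyr::mutate(a, RID = 2L)
  expect_warning(
    out2 <- suppressMessages(integrate_visits(m, a2)),
    "no .RID, visit. keys"
  )
  expect_equal(nrow(out2), 0)
})

test_that("duplicate (rid, viscode) keys are an integrity error", {
  m <- tibble::tibble(
    RID = c(1L, 1L), VISCODE = c("bl", "bl"), DX = "CN", AGE = 70,
    PTGEN = "Male", PTEDUCAT = 12L, PTRACCAT = "White", PTMARRY = "Married"
  )
  a <- tibble::tibble(RID = 1L, VISCODE2 = "bl")
  for (it in adas_items()) a[[it]] <- 1
  expect_error(
    suppressMessages(integrate_visits(m, a)),
    class = "cogprog_integrity_error"
  )
})

test_that("join bookkeeping matches direct key counting under attrition", {
  co <- generate_cohort(cohort_config(
    n_patients = 80, seed = 3,
    missing_dx_rate = 0, missing_item_rate = 0, adas_attrition = 0.1
  ))
  joined <- suppressMessages(integrate_visits(co$merge, co$adas))
  key <- function(tbl, vis) paste(tbl$RID, viscode_to_month(tbl[[vis]]))
  shared <- intersect(key(co$merge, "VISCODE"), key(co$adas, "VISCODE2"))
  expect_equal(nrow(joined), length(shared))
  expect_equal(nrow(joined), nrow(co$adas)) # adas keys are a subset
  # every output key exists in both inputs
  out_key <- paste(joined$rid, joined$month)
  expect_true(all(out_key %in% shared))
})
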