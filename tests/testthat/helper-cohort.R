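# Shared fixtures, built in code at test time.

memory_items <- c("WORDRECALL", "DELAYWORD", "WORDRECOG")

# full simulate -> ingest -> label chain on a small cohort
labeled_cohort <- function(seed, n_patients = 150, ...) {
  co <- generate_cohort(
    cohort_config(n_patients = n_patients, seed = seed, ...)
  )
  suppressMessages({
    merge_tbl <- drop_incomplete(co$merge, c("RID", "VISCODE", "DX"))
    adas_tbl <- drop_incomplete(co$adas)
    label_progression(integrate_visits(merge_tbl, adas_tbl))
  })
}

# labeled -> balanced item matrix (items + class only)
balanced_items <- function(labeled, seed) {
  dat <- dplyr::select(
    labeled,
    dplyr::all_of(c(adas_items(), "dx_progress"))
  )
  shuffle_rows(suppressMessages(smote_oversample(dat, seed = seed)), seed)
}

# a tiny hand-checkable visit-record table
toy_visits <- function(dx_by_patient) {
  purrr::imap(dx_by_patient, function(dxs, rid) {
    month <- 6L * (seq_along(dxs) - 1L)
    tibble::tibble(
      rid = as.integer(rid),
      viscode = ifelse(month == 0L, "bl", sprintf("m%02d", month)),
      month = month,
      dx = dxs
    )
  }) |>
    purrr::list_rbind()
}

# independent brute-force oracle for the progression-label rule
label_oracle <- function(digits) {
  out <- integer(length(digits))
  out[1] <- 0L
  if (length(digits) > 1) {
    for (i in 2:length(digits)) {
      out[i] <- sign(digits[i] - digits[i - 1])
    }
  }
  out
}
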