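#' Parse ADNI-style visit codes to months
#'
#' Visit codes follow the ADNI convention: `"bl"` for the baseline visit and
#' `"m<NN>"` for month-NN follow-ups (`"m06"`, `"m12"`, ...). Ordering visits
#' by parsed month (not lexicographically — `"m12"` sorts before `"m6"` as
#' text) is what keeps per-patient trajectories in temporal order.
#'
#' @param viscode Character vector of visit codes.
#' @return Integer vector of months since baseline; `NA` for unparseable codes.
#' @examples
#' viscode_to_month(c("bl", "m06", "m12"))
#' @export
viscode_to_month <- function(viscode) {
  v <- tolower(trimws(as.character(viscode)))
  out <- rep(NA_integer_, length(v))
  out[v == "bl"] <- 0L
  m <- grepl("^m[0-9]+$", v)
  out[m] <- as.integer(sub("^m", "", v[m]))
  out
}

month_to_viscode <- function(month) {
  ifelse(month == 0L, "bl", sprintf("m%02d", month))
}

abort_config <- function(field, msg) {
  rlang::abort(
    sprintf("invalid configuration: field `%s` %s", field, msg),
    class = "cogprog_config_error"
  )
}

# shared missing-value predicate: NA or empty string marks a missing cell
is_missing_cell <- function(x) {
  is.na(x) | (is.character(x) & trimws(as.character(x)) == "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
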