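#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a longitudinal
#' ADNI-style cohort visited at 6-month intervals, whose diagnosis (DX) moves
#' over the stages CN -> MCI -> AD as a Markov chain with rare progression
#' events, and whose 13 ADAS-Cog-13 item scores rise with disease stage —
#' most strongly for the three word-memory items. Defaults are calibrated so
#' that, after integration and progression labeling, roughly 5% of retained
#' visit rows carry a progression label, matching the class imbalance typical
#' of ADNI-derived progression datasets.
#'
#' @param n_patients Number of patients (>= 1).
#' @param max_visits Maximum visits per patient (>= 1); each patient receives
#'   a uniform random number of visits in `1:max_visits`, emulating study
#'   attrition.
#' @param visit_interval_months Months between successive visits (default 6).
#' @param p_progress_per_visit Probability that a CN or MCI patient advances
#'   one stage at each follow-up visit.
#' @param p_regress_per_visit Probability of a one-stage regression per
#'   follow-up visit.
#' @param missing_dx_rate,missing_item_rate Probabilities that a DX cell or an
#'   individual item score is recorded missing.
#' @param adas_attrition Fraction of assessment rows withheld from the ADAS
#'   table, emulating visits at which the assessment was not administered
#'   (these rows fail to join downstream).
#' @param item_effect_sizes Named numeric vector (all 13 items): mean score
#'   shift per disease stage. By default the three memory items
#'   (WORDRECALL, DELAYWORD, WORDRECOG) carry the largest shifts.
#' @param noise_sd Standard deviation of the Gaussian score noise, on the raw
#'   score scale, before rounding to the integer grid.
#' @param demographic_effect Multiplier on the small demographic shift applied
#'   to patients whose trajectory ever progresses (older age, slightly higher
#'   education); set 0 to remove any demographic signal.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   tables.
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_patients = 600,
                          max_visits = 8,
                          visit_interval_months = 6,
                          p_progress_per_visit = 0.09,
                          p_regress_per_visit = 0.02,
                          missing_dx_rate = 0.05,
                          missing_item_rate = 0.01,
                          adas_attrition = 0.10,
                          item_effect_sizes = default_item_effects(),
                          noise_sd = 1.5,
                          demographic_effect = 1,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, max_visits = max_visits,
    visit_interval_months = visit_interval_months,
    p_progress_per_visit = p_progress_per_visit,
    p_regress_per_visit = p_regress_per_visit,
    missing_dx_rate = missing_dx_rate,
    missing_item_rate = missing_item_rate,
    adas_attrition = adas_attrition,
    item_effect_sizes = item_effect_sizes,
    noise_sd = noise_sd,
    demographic_effect = demographic_effect,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Default per-stage item effect sizes
#'
#' Mean score shift per disease stage for each of the 13 items. The three
#' word-memory items dominate (shift 3 points per stage), followed by
#' orientation, command and word finding; the remaining tasks carry weak
#' shifts. This reproduces the qualitative structure observed in ADNI item
#' scores, where class association concentrates in the memory items.
#'
#' @return Named numeric vector over the 13 items.
#' @export
default_item_effects <- function() {
  c(
    WORDRECALL = 3.0, COMMAND = 0.6, CONSTRUCT = 0.4, DELAYWORD = 3.0,
    NAMING = 0.4, IDEATIONAL = 0.4, ORIENT = 0.7, WORDRECOG = 3.0,
    RMBRTESTINSTR = 0.15, LANGUAGE = 0.25, WORDFIND = 0.6, SPOKENLG = 0.25,
    NUMBERCANCEL = 0.4
  )
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(x, f) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
      abort_config(f, "must be a single integer >= 1")
    }
  }
  chk_prob <- function(x, f) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort_config(f, "must be a probability in [0, 1]")
    }
  }
  chk_count(cfg$n_patients, "n_patients")
  chk_count(cfg$max_visits, "max_visits")
  chk_count(cfg$visit_interval_months, "visit_interval_months")
  for (f in c(
    "p_progress_per_visit", "p_regress_per_visit",
    "missing_dx_rate", "missing_item_rate", "adas_attrition"
  )) {
    chk_prob(cfg[[f]], f)
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    abort_config("noise_sd", "must be a non-negative number")
  }
  eff <- cfg$item_effect_sizes
  items <- adas_items()
  if (!is.numeric(eff) || !setequal(names(eff), items)) {
    abort_config("item_effect_sizes", "must be a numeric vector named by the 13 items")
  }
  if (any(eff < 0)) abort_config("item_effect_sizes", "must be non-negative")
  if (!is.numeric(cfg$demographic_effect) || length(cfg$demographic_effect) != 1) {
    abort_config("demographic_effect", "must be a single number")
  }
  invisible(cfg)
}

dx_stages <- c("CN", "MCI", "AD")

# one Markov trajectory over stages 1..3
simulate_trajectory <- function(n_visits, p_up, p_down) {
  stage <- sample.int(3L, 1L, prob = c(0.4, 0.4, 0.2))
  out <- integer(n_visits)
  out[1L] <- stage
  for (v in seq_len(n_visits - 1L)) {
    u <- stats::runif(1)
    if (u < p_up && stage < 3L) {
      stage <- stage + 1L
    } else if (u >= p_up && u < p_up + p_down && stage > 1L) {
      stage <- stage - 1L
    }
    out[v + 1L] <- stage
  }
  out
}

#' Generate a synthetic ADNI-style cohort
#'
#' Produces two tables mirroring the shape of an ADNIMERGE extract (patient
#' ID, visit code, diagnosis, demographics) and an ADAS-Cog-13 extract
#' (patient ID, visit code, 13 item scores). Diagnosis trajectories follow a
#' Markov chain over CN/MCI/AD; item scores are a stage-dependent mean plus
#' rounded Gaussian noise, clipped to each item's score range; missing values
#' and assessment attrition are injected at the configured rates.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cog_cohort`: a list with tibbles `merge`
#'   (columns RID, VISCODE, DX, AGE, PTGEN, PTEDUCAT, PTRACCAT, PTMARRY) and
#'   `adas` (RID, VISCODE2, one column per item), plus the `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 42))
#' head(cohort$merge)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  set.seed(config$seed)
  schema <- adas_item_schema()
  eff <- config$item_effect_sizes[schema$item]
  base <- 0.1 * schema$max_score

  patients <- purrr::map(seq_len(config$n_patients), function(rid) {
    n_visits <- sample.int(config$max_visits, 1L)
    stages <- simulate_trajectory(
      n_visits, config$p_progress_per_visit, config$p_regress_per_visit
    )
    months <- (seq_len(n_visits) - 1L) * config$visit_interval_months
    progressed <- any(diff(stages) > 0)

    age <- round(stats::rnorm(1, 73, 6), 1) +
      3 * config$demographic_effect * progressed
    age <- min(max(age, 55), 95)
    educat <- sample(8:20, 1L, prob = stats::dnorm(8:20, 15, 3)) +
      round(config$demographic_effect * progressed)
    educat <- min(educat, 20L)

    scores <- vapply(seq_along(schema$item), function(j) {
      mu <- base[j] + (stages - 1L) * eff[j]
      s <- round(mu + stats::rnorm(n_visits, 0, config$noise_sd))
      pmin(pmax(s, schema$min_score[j]), schema$max_score[j])
    }, numeric(n_visits) + 0)
    if (n_visits == 1L) scores <- matrix(scores, nrow = 1L)
    colnames(scores) <- schema$item

    list(
      merge = tibble::tibble(
        RID = rid,
        VISCODE = month_to_viscode(months),
        DX = dx_stages[stages],
        AGE = age,
        PTGEN = sample(c("Male", "Female"), 1L),
        PTEDUCAT = educat,
        PTRACCAT = sample(
          c("White", "Black", "Asian", "More than one", "Unknown"), 1L,
          prob = c(0.85, 0.06, 0.04, 0.03, 0.02)
        ),
        PTMARRY = sample(
          c("Married", "Widowed", "Divorced", "Never married"), 1L,
          prob = c(0.65, 0.15, 0.12, 0.08)
        )
      ),
      adas = tibble::tibble(
        RID = rid,
        VISCODE2 = month_to_viscode(months)
      ) |> dplyr::bind_cols(tibble::as_tibble(scores))
    )
  })

  merge_tbl <- purrr::list_rbind(purrr::map(patients, "merge"))
  adas_tbl <- purrr::list_rbind(purrr::map(patients, "adas"))

  # missingness injection
  if (config$missing_dx_rate > 0) {
    miss <- stats::runif(nrow(merge_tbl)) < config$missing_dx_rate
    merge_tbl$DX[miss] <- NA_character_
  }
  if (config$missing_item_rate > 0) {
    for (it in schema$item) {
      miss <- stats::runif(nrow(adas_tbl)) < config$missing_item_rate
      adas_tbl[[it]][miss] <- NA_real_
    }
  }
  # withhold assessment rows: visits at which the test was not administered
  if (config$adas_attrition > 0) {
    n_drop <- floor(config$adas_attrition * nrow(adas_tbl))
    if (n_drop > 0) {
      adas_tbl <- adas_tbl[-sample.int(nrow(adas_tbl), n_drop), , drop = FALSE]
    }
  }

  structure(
    list(merge = merge_tbl, adas = adas_tbl, config = config),
    class = "cog_cohort"
  )
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `merge.csv` and `adas.csv` under `dir`, with a header row and empty
#' strings for missing values (the on-disk convention the ingestion stage
#' expects).
#'
#' @param cohort A `cog_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cog_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    merge = file.path(dir, "merge.csv"),
    adas = file.path(dir, "adas.csv")
  )
  readr::write_csv(cohort$merge, paths["merge"], na = "")
  readr::write_csv(cohort$adas, paths["adas"], na = "")
  invisible(paths)
}
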