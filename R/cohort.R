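race_levels <- c("caucasian", "african_american")
diagnosis_levels <- c("NC", "MCI", "AD")

# Cell sizes and female counts of the emulated two-race, three-diagnosis
# cohort (post-QC sample, n = 137).
default_cells <- function() {
  tibble::tribble(
    ~race,              ~diagnosis, ~n,  ~n_female,
    "caucasian",        "NC",       31L, 19L,
    "caucasian",        "MCI",      25L, 15L,
    "caucasian",        "AD",       16L, 9L,
    "african_american", "NC",       27L, 17L,
    "african_american", "MCI",      28L, 12L,
    "african_american", "AD",       10L, 6L
  )
}

# Per race x diagnosis (mean, sd) of the continuous subject variables:
# age (years), education (years), WMH volume (mm^3), CSF Abeta42 / t-Tau /
# p-Tau181 (pg/mL), and a generic cardiovascular risk score.
default_biomarker_params <- function() {
  tibble::tribble(
    ~race,              ~diagnosis, ~variable,      ~mean,    ~sd,
    "caucasian",        "NC",  "age",          71.65,     8.39,
    "caucasian",        "MCI", "age",          71.52,     5.82,
    "caucasian",        "AD",  "age",          68.50,     9.41,
    "african_american", "NC",  "age",          67.48,     6.17,
    "african_american", "MCI", "age",          70.07,     7.74,
    "african_american", "AD",  "age",          71.40,     9.65,
    "caucasian",        "NC",  "education",    16.81,     2.69,
    "caucasian",        "MCI", "education",    17.08,     2.58,
    "caucasian",        "AD",  "education",    14.19,     1.94,
    "african_american", "NC",  "education",    15.78,     2.66,
    "african_american", "MCI", "education",    16.29,     2.81,
    "african_american", "AD",  "education",    16.80,     3.55,
    "caucasian",        "NC",  "wmh_volume",   3306.81, 3337.32,
    "caucasian",        "MCI", "wmh_volume",   4018.66, 4080.03,
    "caucasian",        "AD",  "wmh_volume",   5243.68, 5333.14,
    "african_american", "NC",  "wmh_volume",   2440.93, 2576.15,
    "african_american", "MCI", "wmh_volume",   4313.70, 5330.60,
    "african_american", "AD",  "wmh_volume",   6730.21, 7607.48,
    "caucasian",        "NC",  "abeta42",      199.93,   132.30,
    "caucasian",        "MCI", "abeta42",      199.11,   141.02,
    "caucasian",        "AD",  "abeta42",      77.65,     47.39,
    "african_american", "NC",  "abeta42",      165.27,    89.80,
    "african_american", "MCI", "abeta42",      134.69,    90.99,
    "african_american", "AD",  "abeta42",      133.55,   140.71,
    "caucasian",        "NC",  "ttau",         51.68,     30.96,
    "caucasian",        "MCI", "ttau",         63.99,     33.71,
    "caucasian",        "AD",  "ttau",         108.48,    77.43,
    "african_american", "NC",  "ttau",         36.04,     11.63,
    "african_american", "MCI", "ttau",         35.44,     13.67,
    "african_american", "AD",  "ttau",         75.80,     33.52,
    "caucasian",        "NC",  "ptau181",      23.47,      9.71,
    "caucasian",        "MCI", "ptau181",      25.01,     13.42,
    "caucasian",        "AD",  "ptau181",      33.53,     14.64,
    "african_american", "NC",  "ptau181",      14.05,      5.07,
    "african_american", "MCI", "ptau181",      17.74,      7.21,
    "african_american", "AD",  "ptau181",      24.54,     10.27,
    "caucasian",        "NC",  "cardio_score", 14.0,       6.0,
    "caucasian",        "MCI", "cardio_score", 14.0,       6.0,
    "caucasian",        "AD",  "cardio_score", 14.0,       6.0,
    "african_american", "NC",  "cardio_score", 18.0,       6.0,
    "african_american", "MCI", "cardio_score", 18.0,       6.0,
    "african_american", "AD",  "cardio_score", 18.0,       6.0
  )
}

# Carrier / risk-factor prevalences per race.
default_prevalences <- function() {
  tibble::tribble(
    ~race,              ~variable,      ~p,
    "caucasian",        "apoe_e4",      0.30,
    "african_american", "apoe_e4",      0.37,
    "caucasian",        "abca7_risk",   0.2367,
    "african_american", "abca7_risk",   0.4310,
    "caucasian",        "hypertension", 0.4583,
    "african_american", "hypertension", 0.7231,
    "caucasian",        "diabetes",     0.0567,
    "african_american", "diabetes",     0.3380
  )
}

# Composite cognitive Z by diagnosis: ordered NC > MCI > AD in expectation.
default_cognition_params <- function() {
  tibble::tibble(
    diagnosis = diagnosis_levels,
    mean = c(0, -0.8, -2.3),
    sd = 0.7
  )
}

#' Default 11x11 component correlation structure
#'
#' Baseline population correlation among the 11 DMN component time courses:
#' 0.4 within a subsystem, 0.15 between subsystems, unit diagonal. The block
#' structure is positive definite by construction (it is a sum of
#' positive-semidefinite block constants plus `0.6 I`).
#'
#' @param map a subsystem map, see [dmn_nodes()].
#' @param intra,inter within- and between-subsystem correlations.
#' @return a correlation matrix with abbreviation dimnames, node-id order.
#' @export
default_base_correlation <- function(map = dmn_nodes(), intra = 0.4, inter = 0.15) {
  map <- map[order(map$node_id), ]
  same <- outer(map$subsystem, map$subsystem, "==")
  base <- ifelse(same, intra, inter)
  diag(base) <- 1
  dimnames(base) <- list(map$abbreviation, map$abbreviation)
  base
}

#' Configure the synthetic cohort generator
#'
#' Bundles every distributional parameter of the emulated study cohort:
#' race x diagnosis cell sizes (default 31/25/16 Caucasian and 27/28/10
#' African American across NC/MCI/AD, n = 137 total), per-cell means and SDs
#' for the continuous subject variables, risk-factor prevalences per race,
#' cognitive-Z parameters per diagnosis, head-motion distribution, scan
#' geometry (124 volumes at TR 3 s, first 10 discarded) and the baseline
#' component correlation structure. Continuous biomarkers are drawn from
#' normals truncated at zero so the configured mean/SD parameterization
#' matches how cohort tables report them.
#'
#' @param cells tibble of cell sizes (`race`, `diagnosis`, `n`, `n_female`).
#' @param biomarkers tibble (`race`, `diagnosis`, `variable`, `mean`, `sd`).
#' @param prevalence tibble (`race`, `variable`, `p`) of 0/1 trait rates.
#' @param cognition tibble (`diagnosis`, `mean`, `sd`) for composite Z.
#' @param motion list with `mean`, `sd`, `min` (mm) for mean framewise
#'   displacement.
#' @param n_volumes,tr_seconds,discard_volumes scan geometry.
#' @param base_correlation 11x11 baseline correlation matrix.
#' @param map subsystem map the correlation structure refers to.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(cells = NULL, biomarkers = NULL, prevalence = NULL,
                          cognition = NULL, motion = NULL,
                          n_volumes = 124L, tr_seconds = 3,
                          discard_volumes = 10L,
                          base_correlation = NULL, map = dmn_nodes()) {
  cfg <- structure(list(
    cells = cells %||% default_cells(),
    biomarkers = biomarkers %||% default_biomarker_params(),
    prevalence = prevalence %||% default_prevalences(),
    cognition = cognition %||% default_cognition_params(),
    motion = modifyList(list(mean = 0.30, sd = 0.15, min = 0.02),
                        motion %||% list()),
    n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds,
    discard_volumes = as.integer(discard_volumes),
    base_correlation = base_correlation %||% default_base_correlation(map),
    map = map
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  if (!inherits(config, "cohort_config")) abort("not a cohort_config")
  if (any(config$cells$n < 0)) abort("cell counts must be non-negative")
  if (any(config$cells$n_female > config$cells$n)) {
    abort("n_female cannot exceed cell size")
  }
  if (any(config$biomarkers$sd < 0) || any(config$cognition$sd < 0)) {
    abort("standard deviations must be >= 0")
  }
  if (any(config$prevalence$p < 0 | config$prevalence$p > 1)) {
    abort("prevalences must lie in [0, 1]")
  }
  if (config$n_volumes <= config$discard_volumes) {
    abort("n_volumes must exceed discard_volumes")
  }
  b <- config$base_correlation
  if (!isTRUE(all.equal(b, t(b))) || any(abs(diag(b) - 1) > 1e-12)) {
    abort("base_correlation must be symmetric with unit diagonal")
  }
  if (min(eigen(b, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort("base_correlation must be positive definite")
  }
  invisible(config)
}

#' Generate a synthetic subject cohort
#'
#' Draws one subject record per configured cell slot: continuous variables
#' from zero-truncated normals with the cell-specific (mean, SD), binary
#' risk traits as Bernoulli draws at the race-specific prevalence, composite
#' cognitive Z from the per-diagnosis normal, sex assigned to match the
#' configured female count per cell, and mean framewise displacement from a
#' truncated normal. The result is a pure function of `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed.
#' @return a tibble with one row per subject: `subject_id`, `race`,
#'   `diagnosis`, `age`, `sex`, `education`, `apoe_e4`, `abca7_risk`,
#'   `hypertension`, `diabetes`, `wmh_volume`, `abeta42`, `ttau`, `ptau181`,
#'   `cardio_score`, `cognitive_z`, `mfwd`.
#' @examples
#' cohort <- generate_cohort(seed = 7)
#' nrow(cohort)          # 137
#' dplyr::count(cohort, race)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  with_seed_(seed, {
    rows <- purrr::pmap_dfr(config$cells, function(race, diagnosis, n, n_female) {
      if (n == 0L) return(tibble::tibble())
      bm <- dplyr::filter(config$biomarkers,
                          .data$race == !!race, .data$diagnosis == !!diagnosis)
      draw <- function(variable) {
        par <- bm[bm$variable == variable, ]
        if (nrow(par) != 1L) abort(paste0("missing biomarker params: ", variable))
        rtrunc_norm(n, par$mean, par$sd)
      }
      prev <- function(variable) {
        p <- config$prevalence$p[config$prevalence$race == race &
                                   config$prevalence$variable == variable]
        if (length(p) != 1L) abort(paste0("missing prevalence: ", variable))
        rbinom(n, 1L, p)
      }
      cg <- config$cognition[config$cognition$diagnosis == diagnosis, ]
      sex <- sample(rep(c("female", "male"), c(n_female, n - n_female)))
      tibble::tibble(
        race = race, diagnosis = diagnosis,
        age = draw("age"),
        sex = sex,
        education = draw("education"),
        apoe_e4 = prev("apoe_e4"),
        abca7_risk = prev("abca7_risk"),
        hypertension = prev("hypertension"),
        diabetes = prev("diabetes"),
        wmh_volume = draw("wmh_volume"),
        abeta42 = draw("abeta42"),
        ttau = draw("ttau"),
        ptau181 = draw("ptau181"),
        cardio_score = draw("cardio_score"),
        cognitive_z = rnorm(n, cg$mean, cg$sd),
        mfwd = rtrunc_norm(n, config$motion$mean, config$motion$sd,
                           lower = config$motion$min)
      )
    })
    rows <- dplyr::mutate(
      rows,
      subject_id = sprintf("S%03d", dplyr::row_number()),
      race = factor(.data$race, levels = race_levels),
      diagnosis = factor(.data$diagnosis, levels = diagnosis_levels),
      sex = factor(.data$sex, levels = c("female", "male")),
      .before = 1
    )
    dplyr::relocate(rows, "subject_id", "race", "diagnosis")
  })
}
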