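#' Read and write the pipeline's file formats
#'
#' The synthetic generator emits the same plain-text formats the
#' real-data path consumes: a subjects CSV, one time-course TSV per
#' subject (volumes x components with a header row of node abbreviations)
#' and one motion TSV per subject (six columns, SPM realignment
#' convention: three translations in mm then three rotations in rad).
#'
#' @param path file path.
#' @name dmn_io
NULL

#' @rdname dmn_io
#' @export
read_timecourse_tsv <- function(path) {
  as.matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname dmn_io
#' @param tc time-course matrix with abbreviation column names.
#' @export
write_timecourse_tsv <- function(tc, path) {
  readr::write_tsv(tibble::as_tibble(tc), path)
  invisible(path)
}

#' @rdname dmn_io
#' @export
read_motion_tsv <- function(path) {
  as.matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname dmn_io
#' @param motion volumes x 6 motion trace.
#' @export
write_motion_tsv <- function(motion, path) {
  readr::write_tsv(tibble::as_tibble(motion), path)
  invisible(path)
}

#' @rdname dmn_io
#' @export
read_subjects_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::mutate(
    out,
    race = factor(.data$race, levels = race_levels),
    diagnosis = factor(.data$diagnosis, levels = diagnosis_levels),
    sex = factor(.data$sex, levels = c("female", "male"))
  )
}

#' Write a synthetic cohort to disk in the real-data layout
#'
#' Emits `subjects.csv`, `timecourses/<id>.tsv` and `motion/<id>.tsv`
#' under `dir`, using per-subject targets with any planted effects.
#'
#' @param cohort subject tibble.
#' @param dir output directory (created if needed).
#' @param config a [cohort_config()].
#' @param effects optional effects tibble.
#' @param seed RNG seed.
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(cohort, dir, config = cohort_config(),
                               effects = NULL, seed = 1L) {
  dir.create(file.path(dir, "timecourses"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort, file.path(dir, "subjects.csv"))
  base <- config$base_correlation
  with_seed_(seed, {
    for (i in seq_len(nrow(cohort))) {
      target <- target_correlation_matrix(cohort[i, ], effects, base, config$map)
      tc <- generate_timecourses(target, config$n_volumes)
      write_timecourse_tsv(tc, file.path(dir, "timecourses",
                                         paste0(cohort$subject_id[i], ".tsv")))
      mt <- generate_motion_trace(cohort$mfwd[i], config$n_volumes)
      write_motion_tsv(mt, file.path(dir, "motion",
                                     paste0(cohort$subject_id[i], ".tsv")))
    }
  })
  invisible(dir)
}

#' Compute a cohort connectivity table from time-course files
#'
#' Applies the preprocessing chain (discard initial volumes, band-pass) and
#' pairwise correlation to each subject's time-course TSV.
#'
#' @param subjects subject tibble with `subject_id`.
#' @param dir directory holding `timecourses/<id>.tsv`.
#' @param config a [cohort_config()] (TR, discard count).
#' @param map subsystem map.
#' @return connectivity tibble, one row per subject.
#' @export
connectivity_from_files <- function(subjects, dir, config = cohort_config(),
                                    map = dmn_nodes()) {
  pairs <- dmn_node_pairs(map)
  out <- matrix(NA_real_, nrow(subjects), nrow(pairs),
                dimnames = list(NULL, pairs$pair))
  for (i in seq_len(nrow(subjects))) {
    tc <- read_timecourse_tsv(file.path(dir, "timecourses",
                                        paste0(subjects$subject_id[i], ".tsv")))
    tc <- discard_initial_volumes(tc, config$discard_volumes)
    tc <- bandpass(tc, config$tr_seconds)
    out[i, ] <- pairwise_connectivity(tc, map)
  }
  dplyr::bind_cols(tibble::tibble(subject_id = subjects$subject_id),
                   tibble::as_tibble(out))
}
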