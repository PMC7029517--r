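cognitive_domains <- c("memory", "executive", "language", "visuospatial")

#' Standardize a raw subtest score against its norm
#'
#' @param raw raw subtest score(s).
#' @param norm_mean,norm_sd normative mean and standard deviation
#'   (`norm_sd > 0`).
#' @return the Z-score `(raw - norm_mean) / norm_sd`.
#' @export
subtest_z <- function(raw, norm_mean, norm_sd) {
  if (any(norm_sd <= 0)) abort("norm_sd must be positive")
  (raw - norm_mean) / norm_sd
}

#' Apply a (subtest, race)-specific norms table
#'
#' Norms may differ by race (e.g. locally derived norms for selected
#' subtests); the table supplies one `(norm_mean, norm_sd)` row per
#' subtest and race.
#'
#' @param scores tibble with columns `subtest`, `domain`, `raw` and `race`.
#' @param norms tibble with columns `subtest`, `race`, `norm_mean`,
#'   `norm_sd`.
#' @return `scores` with a `z` column appended.
#' @export
apply_norms <- function(scores, norms) {
  out <- dplyr::left_join(scores, norms, by = c("subtest", "race"))
  if (anyNA(out$norm_mean) || anyNA(out$norm_sd)) {
    missing <- unique(out$subtest[is.na(out$norm_mean)])
    abort(paste0("no norm for subtest(s): ", paste(missing, collapse = ", ")))
  }
  out$z <- subtest_z(out$raw, out$norm_mean, out$norm_sd)
  dplyr::select(out, -"norm_mean", -"norm_sd")
}

#' Domain Z-scores from subtest Z-scores
#'
#' Domain-specific scores are the arithmetic mean of the subtest Z-scores
#' within each of the four cognitive domains (memory, executive, language,
#' visuospatial).
#'
#' @param subtests tibble with columns `domain` and `z`.
#' @return tibble with one `z` per `domain` present.
#' @export
domain_z <- function(subtests) {
  if (!all(subtests$domain %in% cognitive_domains)) {
    abort(paste0("unknown domain(s): ",
                 paste(setdiff(subtests$domain, cognitive_domains), collapse = ", ")))
  }
  if (nrow(subtests) == 0L) abort("no subtest scores supplied")
  if (anyNA(subtests$z) || any(!is.finite(subtests$z))) {
    abort("subtest Z-scores must be finite")
  }
  dplyr::summarise(dplyr::group_by(subtests, .data$domain),
                   z = mean(.data$z), .groups = "drop")
}

#' Composite cognitive Z-score
#'
#' The unweighted mean of the four domain means. All four domains must be
#' present: a missing domain is an error, never silently reweighted.
#'
#' @param subtests tibble with columns `domain` and `z` (subtest level).
#' @return the composite Z (scalar).
#' @examples
#' scores <- tibble::tibble(
#'   domain = rep(c("memory", "executive", "language", "visuospatial"), 2),
#'   z = c(0.1, -0.9, -0.7, -0.5, 0.1, -0.9, -0.7, -0.5)
#' )
#' composite_z(scores) # -0.5
#' @export
composite_z <- function(subtests) {
  dz <- domain_z(subtests)
  missing <- setdiff(cognitive_domains, dz$domain)
  if (length(missing) > 0L) {
    abort(paste0("missing cognitive domain(s): ", paste(missing, collapse = ", ")))
  }
  mean(dz$z)
}
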