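biomarker_levels <- c("cognition", "abeta42", "ttau")

# Column of the subject record carrying each biomarker.
biomarker_column <- c(cognition = "cognitive_z", abeta42 = "abeta42", ttau = "ttau")

#' Specify a plantable moderation effect on one node pair
#'
#' An effect row describes how one node pair's population correlation
#' depends on a subject's biomarker and race. Effects act on the Fisher
#' (atanh) scale and are mapped back by tanh, so target correlations stay in
#' (-1, 1) while remaining nearly linear at the moderate magnitudes typical
#' of connectivity coefficients:
#'
#' `r = tanh(atanh(r0) + beta_main * x + beta_race * I + beta_interaction * I * x)`
#'
#' where `x` is the subject's biomarker value, `I` indicates the indexed
#' race (African American), and `r0` is `baseline_r` (or the base matrix
#' entry when `baseline_r` is `NA`). Betas are per raw biomarker unit
#' (Z units for cognition, pg/mL for the CSF markers), the same scale on
#' which the moderation regressions estimate them.
#'
#' @param pair node-pair key, e.g. `"PCU-vlTC"` (order normalized).
#' @param biomarker `"cognition"`, `"abeta42"`, `"ttau"`, or `"none"` for a
#'   pure race offset.
#' @param beta_main slope per biomarker unit shared by both races.
#' @param beta_race connectivity offset for the indexed race.
#' @param beta_interaction additional slope per biomarker unit in the
#'   indexed race.
#' @param baseline_r target correlation absent any effect (`NA` = keep the
#'   base matrix entry).
#' @param map subsystem map used to normalize the pair key.
#' @return a one-row effects tibble; rows can be combined with
#'   [dplyr::bind_rows()]. Multiple rows on the same pair add on the atanh
#'   scale.
#' @export
effect_spec <- function(pair, biomarker = "none", beta_main = 0,
                        beta_race = 0, beta_interaction = 0,
                        baseline_r = NA_real_, map = dmn_nodes()) {
  biomarker <- match.arg(biomarker, c(biomarker_levels, "none"))
  if (!is.na(baseline_r) && abs(baseline_r) >= 1) {
    abort("baseline_r must lie strictly inside (-1, 1)")
  }
  if (biomarker == "none" && (beta_main != 0 || beta_interaction != 0)) {
    abort("biomarker-dependent betas require a biomarker")
  }
  tibble::tibble(
    pair = normalize_pair_key(pair, map),
    biomarker = biomarker,
    beta_main = beta_main,
    beta_race = beta_race,
    beta_interaction = beta_interaction,
    baseline_r = baseline_r
  )
}

#' Effect set calibrated to the reported cohort-level coefficients
#'
#' The default planted-effects table: baseline race offsets on three node
#' pairs (controls-level contrasts) and race x biomarker interactions
#' concentrated in the midline-core/dorsomedial block, with one medial
#' temporal-midline pair, at the magnitudes reported for the emulated
#' cohort. One printed t-Tau interaction (0.02 on vlTC-PCU) contradicts its
#' own confidence interval and is planted at 0.003, the magnitude of the
#' other t-Tau interactions.
#'
#' @param map subsystem map.
#' @return an effects tibble (see [effect_spec()]).
#' @export
default_effects <- function(map = dmn_nodes()) {
  dplyr::bind_rows(
    effect_spec("TP-HIP", beta_race = -0.19, map = map),
    effect_spec("vlTC-PCU", beta_race = -0.31, map = map),
    effect_spec("pIPL-pHG", beta_race = -0.15, map = map),
    effect_spec("dmPFC-PCU", "cognition", beta_interaction = -0.14, map = map),
    effect_spec("vlTC-PCU", "cognition", beta_interaction = 0.18, map = map),
    effect_spec("vlTC-PCU", "ttau", beta_interaction = 0.003, map = map),
    effect_spec("dmPFC-PCC", "cognition", beta_race = 0.29,
                beta_interaction = 0.18, map = map),
    effect_spec("TP-PCU", "abeta42", beta_interaction = -0.001, map = map),
    effect_spec("TP-PCU", "ttau", beta_interaction = 0.003, map = map),
    effect_spec("dlTC-PCU", "abeta42", beta_interaction = -0.002, map = map),
    effect_spec("dlTC-PCU", "ttau", beta_interaction = 0.004, map = map),
    effect_spec("dlTC-PCU", "cognition", beta_interaction = 0.20, map = map),
    effect_spec("PCC-HIP", "ttau", beta_interaction = 0.003, map = map)
  )
}

#' Repair a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping at `eps` followed by rescaling to unit diagonal.
#' Deterministic; returns the input untouched when it is already positive
#' definite.
#'
#' @param x symmetric matrix with unit diagonal intent.
#' @param eps smallest admissible eigenvalue.
#' @return a positive-definite correlation matrix.
#' @export
repair_correlation <- function(x, eps = 1e-6) {
  e <- eigen((x + t(x)) / 2, symmetric = TRUE)
  if (min(e$values) >= eps) return(x)
  v <- pmax(e$values, eps)
  y <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(y))
  y <- y / tcrossprod(d)
  diag(y) <- 1
  dimnames(y) <- dimnames(x)
  y
}

#' Per-subject target correlation matrix with planted effects
#'
#' Applies every effect row to the base correlation structure for one
#' subject: planted entries follow the bounded-transform model described in
#' [effect_spec()]; all other entries are copied from `base`. If planting
#' breaks positive definiteness the matrix is repaired deterministically by
#' eigenvalue clipping ([repair_correlation()]).
#'
#' @param subject one-row subject tibble (see [generate_cohort()]).
#' @param effects effects tibble, or `NULL` for no effects.
#' @param base base correlation matrix, default
#'   [default_base_correlation()].
#' @param map subsystem map.
#' @return an 11x11 (for the canonical map) correlation matrix.
#' @export
target_correlation_matrix <- function(subject, effects = NULL,
                                      base = default_base_correlation(map),
                                      map = dmn_nodes()) {
  if (min(eigen(base, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    abort("base correlation matrix must be positive definite")
  }
  if (is.null(effects) || nrow(effects) == 0L) return(base)
  stopifnot(nrow(subject) == 1L)
  out <- base
  aa <- as.integer(subject$race == "african_american")
  for (key in unique(effects$pair)) {
    rows <- effects[effects$pair == key, ]
    nodes <- strsplit(key, "-", fixed = TRUE)[[1]]
    r0 <- rows$baseline_r[!is.na(rows$baseline_r)]
    r0 <- if (length(r0) > 0L) r0[1L] else base[nodes[1L], nodes[2L]]
    delta <- 0
    for (i in seq_len(nrow(rows))) {
      x <- if (rows$biomarker[i] == "none") 0 else
        subject[[biomarker_column[[rows$biomarker[i]]]]]
      delta <- delta + rows$beta_main[i] * x + rows$beta_race[i] * aa +
        rows$beta_interaction[i] * aa * x
    }
    # delta == 0 leaves the target at r0 exactly (no atanh/tanh round trip)
    r_new <- if (delta == 0) r0 else inv_fisher_z(fisher_z(r0) + delta)
    out[nodes[1L], nodes[2L]] <- out[nodes[2L], nodes[1L]] <- r_new
  }
  repair_correlation(out)
}
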