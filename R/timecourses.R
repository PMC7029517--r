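#' Simulate component time courses with a target correlation
#'
#' Rows are i.i.d. draws from a zero-mean unit-variance multivariate normal
#' with the requested correlation, realized by applying the Cholesky factor
#' of `target` to independent standard normals. This emulates the component
#' time courses an ICA decomposition would output for one subject.
#'
#' @param target positive-definite correlation matrix (columns define the
#'   component order; dimnames are carried over).
#' @param n_volumes number of volumes (rows), default 124.
#' @param seed optional RNG seed; when `NULL` the current RNG stream is
#'   used.
#' @return numeric matrix, `n_volumes` x `ncol(target)`.
#' @export
generate_timecourses <- function(target, n_volumes = 124L, seed = NULL) {
  if (n_volumes < 30L) abort("n_volumes must be at least 30")
  ch <- tryCatch(chol(target),
                 error = function(e) abort("target correlation matrix is not positive definite"))
  draw <- function() {
    z <- matrix(rnorm(n_volumes * ncol(target)), n_volumes)
    out <- z %*% ch
    colnames(out) <- colnames(target)
    out
  }
  if (is.null(seed)) draw() else with_seed_(seed, draw())
}

#' Simulate a six-parameter rigid-body motion trace
#'
#' Random-walk translations (mm) and rotations (rad) whose increments are
#' rescaled so the trace's mean framewise displacement equals the requested
#' value exactly (SPM realignment-parameter convention: three translations
#' then three rotations). `mfwd = 0` yields a constant trace.
#'
#' @param mfwd requested mean framewise displacement (mm).
#' @param n_volumes number of volumes.
#' @param head_radius_mm rotation radius used in the displacement formula.
#' @param seed optional RNG seed.
#' @return numeric matrix, `n_volumes` x 6, columns `trans_x`..`rot_z`.
#' @export
generate_motion_trace <- function(mfwd, n_volumes = 124L, head_radius_mm = 50,
                                  seed = NULL) {
  if (mfwd < 0) abort("mfwd must be non-negative")
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (mfwd == 0) {
    return(matrix(0, n_volumes, 6L, dimnames = list(NULL, cols)))
  }
  draw <- function() {
    inc <- cbind(matrix(rnorm((n_volumes - 1L) * 3L), ncol = 3L),
                 matrix(rnorm((n_volumes - 1L) * 3L, sd = 1 / head_radius_mm),
                        ncol = 3L))
    fd <- rowSums(abs(inc[, 1:3, drop = FALSE])) +
      head_radius_mm * rowSums(abs(inc[, 4:6, drop = FALSE]))
    inc <- inc * (mfwd / mean(fd))
    out <- rbind(0, apply(inc, 2L, cumsum))
    colnames(out) <- cols
    out
  }
  if (is.null(seed)) draw() else with_seed_(seed, draw())
}

#' Simulate per-subject connectivity for a whole cohort
#'
#' Runs the full forward model for every subject: per-subject target
#' correlation (base structure plus planted effects), simulated component
#' time courses, initial-volume discarding, band-pass filtering and
#' pairwise Pearson correlation. This is the one-call generator the
#' statistical stages are tested against.
#'
#' @param cohort subject tibble from [generate_cohort()].
#' @param config a [cohort_config()] (scan geometry, base correlation).
#' @param effects optional effects tibble ([effect_spec()]).
#' @param seed RNG seed for the time-course draws.
#' @param keep_timecourses if `TRUE`, the preprocessed per-subject matrices
#'   are attached as attribute `"timecourses"` (a named list).
#' @return connectivity tibble: `subject_id` plus one column per node-pair
#'   key, rows aligned with `cohort`.
#' @export
simulate_connectivity <- function(cohort, config = cohort_config(),
                                  effects = NULL, seed = 1L,
                                  keep_timecourses = FALSE) {
  validate_cohort_config(config)
  map <- config$map
  base <- config$base_correlation
  pairs <- dmn_node_pairs(map)
  n <- nrow(cohort)
  targets <- planted_targets(cohort, effects, base, map)
  ch_base <- chol(base)
  # index of each canonical pair inside the correlation matrix
  pair_idx <- cbind(pairs$a + 1L, pairs$b + 1L)
  tcs <- if (keep_timecourses) vector("list", n) else NULL
  with_seed_(seed, {
    out <- matrix(NA_real_, n, nrow(pairs), dimnames = list(NULL, pairs$pair))
    for (i in seq_len(n)) {
      ch <- if (is.null(targets)) ch_base else chol(targets[[i]])
      z <- matrix(rnorm(config$n_volumes * ncol(base)), config$n_volumes)
      tc <- z %*% ch
      tc <- tc[-seq_len(config$discard_volumes), , drop = FALSE]
      tc <- bandpass(tc, config$tr_seconds)
      if (keep_timecourses) {
        colnames(tc) <- colnames(base)
        tcs[[i]] <- tc
      }
      out[i, ] <- cor(tc)[pair_idx]
    }
    conn <- tibble::as_tibble(out)
    conn <- dplyr::bind_cols(tibble::tibble(subject_id = cohort$subject_id), conn)
    if (keep_timecourses) {
      names(tcs) <- cohort$subject_id
      attr(conn, "timecourses") <- tcs
    }
    conn
  })
}

# Per-subject target matrices with all effect contributions computed
# vectorized over subjects; NULL when there is nothing to plant.
planted_targets <- function(cohort, effects, base, map) {
  if (is.null(effects) || nrow(effects) == 0L) return(NULL)
  n <- nrow(cohort)
  aa <- as.numeric(cohort$race == "african_american")
  keys <- unique(effects$pair)
  entry <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  for (key in keys) {
    rows <- effects[effects$pair == key, ]
    nodes <- strsplit(key, "-", fixed = TRUE)[[1]]
    r0 <- rows$baseline_r[!is.na(rows$baseline_r)]
    r0 <- if (length(r0) > 0L) r0[1L] else base[nodes[1L], nodes[2L]]
    delta <- rep(0, n)
    for (i in seq_len(nrow(rows))) {
      x <- if (rows$biomarker[i] == "none") 0 else
        cohort[[biomarker_column[[rows$biomarker[i]]]]]
      delta <- delta + rows$beta_main[i] * x + rows$beta_race[i] * aa +
        rows$beta_interaction[i] * aa * x
    }
    entry[, key] <- ifelse(delta == 0, r0, inv_fisher_z(fisher_z(r0) + delta))
  }
  node_idx <- lapply(strsplit(keys, "-", fixed = TRUE),
                     function(p) match(p, colnames(base)))
  lapply(seq_len(n), function(i) {
    m <- base
    for (k in seq_along(keys)) {
      ij <- node_idx[[k]]
      m[ij[1L], ij[2L]] <- m[ij[2L], ij[1L]] <- entry[i, k]
    }
    repair_correlation(m)
  })
}
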