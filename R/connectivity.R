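#' Discard initial volumes of a component time course
#'
#' Drops the first `k` rows (default 10) of a volumes x components matrix,
#' the usual allowance for the scanner magnetization to reach dynamic
#' equilibrium. Remaining rows are unaltered and keep their order.
#'
#' @param tc numeric matrix, volumes x components.
#' @param k number of leading volumes to drop.
#' @return the trimmed matrix.
#' @export
discard_initial_volumes <- function(tc, k = 10L) {
  stopifnot(is.matrix(tc), k >= 0)
  if (k >= nrow(tc)) abort("k must be smaller than the number of volumes")
  if (k == 0L) return(tc)
  tc[-seq_len(k), , drop = FALSE]
}

#' Ideal band-pass filter for component time courses
#'
#' Frequency-domain rectangular filter: discrete Fourier coefficients whose
#' frequency falls outside `[low_hz, high_hz]` are zeroed (including DC) and
#' the series is inverse-transformed. Output columns are therefore exactly
#' zero-mean, and the operation is idempotent to numerical precision. The
#' default 0.01-0.08 Hz band isolates the low-frequency BOLD fluctuations
#' of interest at TR = 3 s (Nyquist 1/6 Hz).
#'
#' @param tc numeric matrix, volumes x components.
#' @param tr_seconds sampling interval in seconds.
#' @param low_hz,high_hz pass-band edges in Hz (inclusive).
#' @return filtered matrix of the same shape.
#' @export
bandpass <- function(tc, tr_seconds = 3, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(is.matrix(tc), tr_seconds > 0)
  if (low_hz >= high_hz) abort("low_hz must be below high_hz")
  nyquist <- 1 / (2 * tr_seconds)
  if (high_hz >= nyquist) {
    abort(sprintf("high_hz must be below the Nyquist frequency (%.4f Hz)", nyquist))
  }
  n <- nrow(tc)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) / (n * tr_seconds)   # folded DFT bin frequencies
  keep <- freq >= low_hz & freq <= high_hz
  if (!any(keep)) abort("empty pass band at this series length and TR")
  x <- mvfft(tc)
  x[!keep, ] <- 0
  out <- Re(mvfft(x, inverse = TRUE)) / n
  dimnames(out) <- dimnames(tc)
  out
}

#' Pairwise Pearson connectivity for one subject
#'
#' Product-moment correlation between every enumerated node pair of a
#' preprocessed (discarded + band-passed) component time course.
#'
#' @param tc numeric matrix, volumes x components; columns named by node
#'   abbreviation and matching `map`.
#' @param map subsystem map.
#' @return named numeric vector, one entry per pair of [dmn_node_pairs()],
#'   in canonical order.
#' @examples
#' tc <- matrix(rnorm(11 * 40), 40, 11)
#' r <- pairwise_connectivity(tc)
#' length(r) # 55
#' @export
pairwise_connectivity <- function(tc, map = dmn_nodes()) {
  validate_subsystem_map(map)
  abbr <- map$abbreviation[order(map$node_id)]
  if (is.null(colnames(tc))) {
    if (ncol(tc) != nrow(map)) abort("time course has wrong number of components")
    colnames(tc) <- abbr
  }
  if (!all(abbr %in% colnames(tc))) {
    abort("time course columns do not match the subsystem map")
  }
  tc <- tc[, abbr, drop = FALSE]
  sds <- apply(tc, 2L, sd)
  if (any(sds == 0)) {
    abort(paste0("undefined correlation: zero-variance component(s) ",
                 paste(abbr[sds == 0], collapse = ", ")))
  }
  cm <- cor(tc)
  pairs <- dmn_node_pairs(map)
  setNames(cm[cbind(pairs$a + 1L, pairs$b + 1L)], pairs$pair)
}

#' Mean framewise displacement of a motion trace
#'
#' Framewise displacement at volume t is the sum of absolute
#' volume-to-volume changes of the six rigid-body parameters, with the
#' three rotations (radians) converted to millimetres of arc on a sphere of
#' `head_radius_mm`. Returns the mean over t = 2..T.
#'
#' @param motion numeric matrix, volumes x 6 (translations mm, then
#'   rotations rad).
#' @param head_radius_mm rotation-to-displacement radius.
#' @return mean framewise displacement in mm.
#' @export
mean_framewise_displacement <- function(motion, head_radius_mm = 50) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L)
  if (nrow(motion) < 2L) abort("framewise displacement needs at least 2 volumes")
  d <- abs(diff(motion))
  mean(rowSums(d[, 1:3, drop = FALSE]) +
         head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Motion quality-control filter
#'
#' Splits subjects on the mean-framewise-displacement exclusion rule: a
#' subject with `mfwd >= threshold_mm` (inclusive, i.e. 3.0 mm is excluded)
#' fails quality control.
#'
#' @param subjects tibble with an `mfwd` column (mm).
#' @param threshold_mm exclusion threshold, default 3 mm.
#' @return list with tibbles `retained` and `excluded`; `excluded` carries
#'   a `qc_reason` column.
#' @export
qc_filter <- function(subjects, threshold_mm = 3.0) {
  if (!"mfwd" %in% names(subjects) || anyNA(subjects$mfwd)) {
    abort("every subject needs a finite mfwd for quality control")
  }
  out <- subjects$mfwd >= threshold_mm
  excluded <- subjects[out, , drop = FALSE]
  if (nrow(excluded) > 0L) {
    excluded$qc_reason <- sprintf("mean framewise displacement %.3f mm >= %.2f mm",
                                  excluded$mfwd, threshold_mm)
  } else {
    excluded$qc_reason <- character(0)
  }
  list(retained = subjects[!out, , drop = FALSE], excluded = excluded)
}

#' Mean inter-subsystem connectivity per subject
#'
#' Arithmetic mean, for each subject, of all node-pair connectivity entries
#' between two subsystems (15 pairs for midline-dorsomedial, 9 for
#' midline-temporal, 15 for dorsomedial-temporal).
#'
#' @param connectivity connectivity tibble (one row per subject, one column
#'   per pair key) or a single named vector.
#' @param A,B the two subsystems (must differ).
#' @param map subsystem map.
#' @return numeric vector of per-subject block means (a scalar for a single
#'   connectivity vector).
#' @export
mean_subsystem_connectivity <- function(connectivity, A, B, map = dmn_nodes()) {
  keys <- inter_block_pairs(A, B, map)$pair
  if (is.data.frame(connectivity)) {
    missing <- setdiff(keys, names(connectivity))
    if (length(missing) > 0L) {
      abort(paste0("incomplete connectivity vector; missing pair(s): ",
                   paste(missing, collapse = ", ")))
    }
    rowMeans(as.matrix(connectivity[, keys, drop = FALSE]))
  } else {
    missing <- setdiff(keys, names(connectivity))
    if (length(missing) > 0L) {
      abort(paste0("incomplete connectivity vector; missing pair(s): ",
                   paste(missing, collapse = ", ")))
    }
    mean(connectivity[keys])
  }
}
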