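#' Pool interaction p-values across biomarker scans
#'
#' Collects the per-pair interaction p-values of one or more scans into a
#' single pool tagged by (pair, biomarker): three complete scans over the
#' canonical map give the 165-value (55 x 3) global pool. Failed pairs are
#' excluded and their count recorded in attribute `"n_excluded"`.
#'
#' @param scans a `dmn_scan` or list of `dmn_scan` objects.
#' @return tibble with columns `pair`, `block`, `biomarker`, `p`.
#' @export
pool_pvalues <- function(scans) {
  if (inherits(scans, "dmn_scan")) scans <- list(scans)
  pool <- purrr::map_dfr(scans, function(s) {
    stopifnot(inherits(s, "dmn_scan"))
    tibble::tibble(pair = s$results$pair, block = s$results$block,
                   biomarker = s$biomarker %||% "none",
                   p = s$results$p.value)
  })
  if (anyDuplicated(pool[, c("pair", "biomarker")])) {
    abort("duplicate (pair, biomarker) entries in the p-value pool")
  }
  n_excluded <- sum(is.na(pool$p))
  pool <- pool[!is.na(pool$p), , drop = FALSE]
  structure(pool, n_excluded = n_excluded)
}

#' Restrict a p-value pool to one subsystem block
#'
#' For the midline-dorsomedial block and three complete scans this is the
#' 45-value pool (15 pairs x 3 biomarkers).
#'
#' @param pool output of [pool_pvalues()].
#' @param block block label.
#' @return the filtered pool tibble.
#' @export
block_pool <- function(pool, block = "dm_midline") {
  out <- dplyr::filter(pool, .data$block == !!block)
  if (nrow(out) == 0L) abort(paste0("empty block pool: ", block))
  out
}

#' Count bootstrap matrices with enough significant entries
#'
#' Draws `cells_per_matrix` p-values uniformly with replacement from the
#' pool, `n_matrices` times (default 1500 simulated 3 x 5 matrices), and
#' counts how many matrices contain at least `min_significant` entries
#' below `alpha`.
#'
#' @param pool p-value pool (tibble from [pool_pvalues()] or a bare numeric
#'   vector).
#' @param n_matrices number of simulated matrices.
#' @param cells_per_matrix entries drawn per matrix (15 = the 3 x 5
#'   midline-dorsomedial block size).
#' @param min_significant matrix-level counting rule (>= 3 by default).
#' @param alpha per-entry significance threshold.
#' @param seed optional RNG seed for reproducible counts.
#' @return integer count in `[0, n_matrices]`.
#' @export
bootstrap_count <- function(pool, n_matrices = 1500L, cells_per_matrix = 15L,
                            min_significant = 3L, alpha = 0.05, seed = NULL) {
  p <- if (is.data.frame(pool)) pool$p else pool
  if (length(p) == 0L) abort("cannot bootstrap from an empty pool")
  if (min_significant < 1L || min_significant > cells_per_matrix) {
    abort("need cells_per_matrix >= min_significant >= 1")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  draw <- function() {
    sig <- matrix(sample(p, n_matrices * cells_per_matrix, replace = TRUE) < alpha,
                  nrow = n_matrices)
    sum(rowSums(sig) >= min_significant)
  }
  if (is.null(seed)) draw() else with_seed_(seed, draw())
}

#' Closed-form expectation for the bootstrap counting rule
#'
#' Because matrix cells are i.i.d. draws with replacement, the probability
#' that a matrix holds at least `min_significant` significant entries is
#' binomial in the pool's significant fraction `f`:
#' `1 - sum_(j < min) C(cells, j) f^j (1-f)^(cells-j)`. Used as the
#' analytic oracle for [bootstrap_count()].
#'
#' @param f significant fraction(s) in `[0, 1]`.
#' @param cells_per_matrix,min_significant counting rule.
#' @return probability vector.
#' @export
binomial_expectation <- function(f, cells_per_matrix = 15L, min_significant = 3L) {
  stopifnot(all(f >= 0 & f <= 1))
  1 - pbinom(min_significant - 1L, cells_per_matrix, f)
}

#' Compare two bootstrap counts with a Pearson chi-squared test
#'
#' Textbook 2 x 2 Pearson test on
#' `((count_a, n - count_a), (count_b, n - count_b))`, df = 1, no
#' continuity correction. A zero-margin table (both counts 0 or both n)
#' returns the degenerate result chi-squared = 0, p = 1.
#'
#' @param count_a,count_b matrix counts from the two pools.
#' @param n_matrices matrices per bootstrap.
#' @return one-row tibble: `statistic`, `df`, `p.value`.
#' @export
compare_counts <- function(count_a, count_b, n_matrices = 1500L) {
  stopifnot(count_a >= 0, count_b >= 0,
            count_a <= n_matrices, count_b <= n_matrices)
  a <- as.double(count_a); b <- as.double(n_matrices - count_a)
  c_ <- as.double(count_b); d <- as.double(n_matrices - count_b)
  N <- 2 * n_matrices
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (denom == 0) {
    return(tibble::tibble(statistic = 0, df = 1L, p.value = 1))
  }
  chi2 <- N * (a * d - b * c_)^2 / denom
  tibble::tibble(statistic = chi2, df = 1L,
                 p.value = pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Bootstrap enrichment test for a subsystem block
#'
#' The concentration test: are significant race x biomarker interactions
#' over-represented in one inter-subsystem block relative to chance across
#' the whole network? Two bootstraps of `n_matrices` simulated matrices are
#' drawn — one sampling only the block's pooled interaction p-values, one
#' sampling the global pool — with independent RNG streams derived from
#' `seed`, and their `>= min_significant` counts are compared with the
#' Pearson chi-squared test.
#'
#' @param scans list of `dmn_scan` objects (typically
#'   [scan_all_biomarkers()] output).
#' @param block block label to test for enrichment.
#' @inheritParams bootstrap_count
#' @param seed master seed; the two pools get sub-seeds derived from it.
#' @return a `dmn_enrichment` object with the counts, pools, significant
#'   fractions, chi-squared statistic and p-value. `tidy()` gives one row
#'   per pool, `glance()` the test summary.
#' @export
run_enrichment <- function(scans, block = "dm_midline", n_matrices = 1500L,
                           cells_per_matrix = 15L, min_significant = 3L,
                           alpha = 0.05, seed = 1L) {
  global <- pool_pvalues(scans)
  blk <- block_pool(global, block)
  seeds <- c(block = derive_seed(seed, 1L), global = derive_seed(seed, 2L))
  count_block <- bootstrap_count(blk, n_matrices, cells_per_matrix,
                                 min_significant, alpha, seed = seeds[["block"]])
  count_global <- bootstrap_count(global, n_matrices, cells_per_matrix,
                                  min_significant, alpha, seed = seeds[["global"]])
  test <- compare_counts(count_block, count_global, n_matrices)
  structure(list(
    block = block,
    count_block = count_block,
    count_global = count_global,
    n_matrices = n_matrices,
    cells_per_matrix = cells_per_matrix,
    min_significant = min_significant,
    alpha = alpha,
    f_block = mean(blk$p < alpha),
    f_global = mean(global$p < alpha),
    pool_sizes = c(block = nrow(blk), global = nrow(global)),
    n_excluded = attr(global, "n_excluded"),
    statistic = test$statistic,
    df = test$df,
    p.value = test$p.value,
    seeds = seeds
  ), class = "dmn_enrichment")
}
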