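#' @method tidy pair_model
#' @export
tidy.pair_model <- function(x, ...) x$terms

#' @method glance pair_model
#' @export
glance.pair_model <- function(x, ...) {
  tibble::tibble(pair = x$pair, block = x$block, n_used = x$n_used,
                 df_residual = x$df_residual, sigma = x$sigma,
                 r.squared = x$r_squared)
}

#' @method print pair_model
#' @export
print.pair_model <- function(x, ...) {
  cat(sprintf("Node-pair moderation model: %s (%s), n = %d\n",
              x$pair, x$block, x$n_used))
  print(x$terms)
  invisible(x)
}

#' @method tidy dmn_scan
#' @export
tidy.dmn_scan <- function(x, ...) x$results

#' @method glance dmn_scan
#' @export
glance.dmn_scan <- function(x, ...) {
  tibble::tibble(
    term = x$term,
    biomarker = x$biomarker %||% NA_character_,
    subset = x$subset,
    n_used = x$n_used,
    n_pairs = nrow(x$results),
    n_failed = length(x$failed),
    n_nominal = sum(x$results$p.value < 0.05, na.rm = TRUE),
    n_bh_rejected = sum(x$results$bh_rejected, na.rm = TRUE),
    pi0 = x$pi0,
    q = x$q
  )
}

#' @method print dmn_scan
#' @export
print.dmn_scan <- function(x, ...) {
  cat(sprintf("DMN node-pair scan of term '%s' (%d pairs, subset: %s)\n",
              x$term, nrow(x$results), x$subset))
  print(glance(x))
  cat("Top pairs by unadjusted p:\n")
  print(head(dplyr::arrange(x$results, .data$p.value), 5L))
  invisible(x)
}

#' @method tidy dmn_enrichment
#' @export
tidy.dmn_enrichment <- function(x, ...) {
  tibble::tibble(
    pool = c("block", "global"),
    block = c(x$block, "all"),
    pool_size = unname(x$pool_sizes),
    significant_fraction = c(x$f_block, x$f_global),
    count = c(x$count_block, x$count_global),
    n_matrices = x$n_matrices,
    proportion = c(x$count_block, x$count_global) / x$n_matrices,
    binomial_expectation = binomial_expectation(
      c(x$f_block, x$f_global), x$cells_per_matrix, x$min_significant)
  )
}

#' @method glance dmn_enrichment
#' @export
glance.dmn_enrichment <- function(x, ...) {
  tibble::tibble(block = x$block, count_block = x$count_block,
                 count_global = x$count_global, n_matrices = x$n_matrices,
                 statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' @method print dmn_enrichment
#' @export
print.dmn_enrichment <- function(x, ...) {
  cat(sprintf("Bootstrap enrichment of block '%s'\n", x$block))
  cat(sprintf("  block pool (%d values):  %d/%d matrices with >= %d of %d entries p < %.2f\n",
              x$pool_sizes[["block"]], x$count_block, x$n_matrices,
              x$min_significant, x$cells_per_matrix, x$alpha))
  cat(sprintf("  global pool (%d values): %d/%d\n",
              x$pool_sizes[["global"]], x$count_global, x$n_matrices))
  cat(sprintf("  Pearson chi-squared(%d) = %.2f, p = %.3g\n",
              x$df, x$statistic, x$p.value))
  invisible(x)
}
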