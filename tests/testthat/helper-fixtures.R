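# Shared fixtures, all generated in code.

# A reduced cohort configuration for fast structural tests: same six cells,
# smaller counts, shorter (but still valid) scans.
small_config <- function(n_volumes = 124L, motion = NULL) {
  cells <- default_cells()
  cells$n <- c(8L, 7L, 5L, 8L, 7L, 5L)
  cells$n_female <- c(4L, 4L, 2L, 4L, 3L, 3L)
  cohort_config(cells = cells, n_volumes = n_volumes, motion = motion)
}

# Subjects joined with their simulated connectivity.
simulated_data <- function(config = cohort_config(), effects = NULL, seed = 1L) {
  cohort <- generate_cohort(config, seed = derive_seed(seed, 1L))
  conn <- simulate_connectivity(cohort, config, effects,
                                seed = derive_seed(seed, 2L))
  dplyr::inner_join(cohort, conn, by = "subject_id")
}

# Minimal dmn_scan stand-in for pool plumbing tests.
fake_scan <- function(p, biomarker = "cognition", map = dmn_nodes()) {
  pairs <- dmn_node_pairs(map)
  stopifnot(length(p) == nrow(pairs))
  structure(list(
    results = tibble::tibble(pair = pairs$pair, block = pairs$block,
                             p.value = p),
    biomarker = biomarker, subset = "all", term = paste0("race:", biomarker)
  ), class = "dmn_scan")
}

# Direct O(n^2) discrete-Fourier band-pass, written independently of the
# implementation (explicit basis sums, no FFT), as the filtering oracle.
dft_bandpass_oracle <- function(x, tr, low, high) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  X <- as.vector(W %*% x)
  folded <- pmin(k, n - k) / (n * tr)
  X[!(folded >= low & folded <= high)] <- 0
  Re(as.vector(Conj(W) %*% X)) / n
}
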