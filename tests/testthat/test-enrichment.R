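test_that("pooling three scans gives 165 tagged p-values, block pools 45/27", {
  withr::with_seed(51, {
    scans <- list(fake_scan(runif(55), "cognition"),
                  fake_scan(runif(55), "abeta42"),
                  fake_scan(runif(55), "ttau"))
    pool <- pool_pvalues(scans)
    expect_identical(nrow(pool), 165L)
    expect_identical(attr(pool, "n_excluded"), 0L)
    expect_identical(nrow(block_pool(pool, "dm_midline")), 45L)
    expect_identical(nrow(block_pool(pool, "mtl_midline")), 27L)
    expect_identical(nrow(pool_pvalues(scans[[1]])), 55L)
    expect_identical(nrow(block_pool(pool_pvalues(scans[[1]]), "dm_midline")), 15L)
  })
})

test_that("failed pairs are excluded from the pool with a recorded count", {
  withr::with_seed(52, {
    s1 <- fake_scan(runif(55), "cognition")
    s2 <- fake_scan(runif(55), "abeta42")
    s1$results$p.value[7] <- NA
    s2$results$p.value[31] <- NA
    pool <- pool_pvalues(list(s1, s2))
    expect_identical(nrow(pool), 108L)
    expect_identical(attr(pool, "n_excluded"), 2L)
    # duplicated (pair, biomarker) entries are a pooling error
    expect_error(pool_pvalues(list(s1, s1)), "duplicate")
  })
})

test_that("bootstrap counts hit the degenerate extremes", {
  all_sig <- rep(0.001, 20)
  expect_identical(bootstrap_count(all_sig, seed = 1), 1500L)
  none_sig <- rep(0.9, 20)
  expect_identical(bootstrap_count(none_sig, seed = 1), 0L)
  expect_error(bootstrap_count(numeric(0)), "empty pool")
  expect_error(bootstrap_count(all_sig, min_significant = 20), ">=")
})

test_that("bootstrap counts are reproducible and monotone in the counting rule", {
  withr::with_seed(53, pool <- runif(165)^2)
  expect_identical(bootstrap_count(pool, seed = 99),
                   bootstrap_count(pool, seed = 99))
  counts <- vapply(1:15, function(k) {
    bootstrap_count(pool, min_significant = k, seed = 7)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("binomial expectation matches the explicit binomial sum", {
  expect_identical(binomial_expectation(0), 0)
  expect_identical(binomial_expectation(1), 1)
  f <- 0.2
  by_hand <- 1 - (0.8^15 + 15 * f * 0.8^14 + 105 * f^2 * 0.8^13)
  expect_equal(binomial_expectation(0.2), by_hand, tolerance = 1e-12)
})

test_that("count/n converges to the binomial expectation for i.i.d. cells", {
  for (f in c(0.05, 0.2, 0.5)) {
    pool <- c(rep(0.001, round(f * 200)), rep(0.5, round((1 - f) * 200)))
    count <- bootstrap_count(pool, seed = round(1000 * f))
    expected <- binomial_expectation(f)
    se <- sqrt(expected * (1 - expected) / 1500)
    expect_lt(abs(count / 1500 - expected), 3 * se + 1e-12)
  }
})

test_that("the 2x2 chi-squared matches its closed form and stats::chisq.test", {
  expect_equal(compare_counts(100, 100, 1500)$statistic, 0)
  got <- compare_counts(20, 0, 20)
  expect_equal(got$statistic, 40)
  expect_identical(got$df, 1L)
  # row swap leaves the statistic unchanged
  expect_equal(compare_counts(0, 20, 20)$statistic, 40)
  # independent oracle on a generic table
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(791, 709, 192, 1308), 2, byrow = TRUE),
                      correct = FALSE))
  got2 <- compare_counts(791, 192, 1500)
  expect_equal(got2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got2$p.value, ref$p.value, tolerance = 1e-10)
  # zero-margin degeneracy
  degen <- compare_counts(0, 0, 100)
  expect_identical(degen$statistic, 0)
  expect_identical(degen$p.value, 1)
})

test_that("run_enrichment is deterministic and direction-invariant", {
  withr::with_seed(54, {
    # low p-values planted on the dm_midline pairs of the first scan
    dm <- dmn_node_pairs()$block == "dm_midline"
    p1 <- runif(55)
    p1[dm] <- runif(15, 0, 0.04)
    scans <- list(fake_scan(p1, "cognition"),
                  fake_scan(runif(55), "abeta42"),
                  fake_scan(runif(55), "ttau"))
  })
  e1 <- run_enrichment(scans, seed = 5)
  e2 <- run_enrichment(scans, seed = 5)
  expect_identical(glance(e1), glance(e2))
  expect_gt(e1$count_block, e1$count_global)
  # swapping which pool is labelled "block" negates the difference only
  swapped <- compare_counts(e1$count_global, e1$count_block, e1$n_matrices)
  expect_equal(swapped$statistic, e1$statistic, tolerance = 1e-12)
  expect_identical(nrow(tidy(e1)), 2L)
})
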