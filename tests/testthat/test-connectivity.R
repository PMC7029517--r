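test_that("initial-volume discarding trims exactly k leading rows", {
  tc <- matrix(seq_len(124 * 2), 124, 2)
  out <- discard_initial_volumes(tc, 10)
  expect_identical(nrow(out), 114L)
  expect_identical(out[1, ], tc[11, ])
  expect_identical(discard_initial_volumes(tc, 0), tc)
  short <- matrix(rnorm(22), 11, 2)
  expect_identical(nrow(discard_initial_volumes(short, 10)), 1L)
  expect_error(discard_initial_volumes(short, 11), "smaller")
})

test_that("band-pass matches an independently written DFT oracle", {
  withr::with_seed(31, {
    x <- matrix(rnorm(114 * 3), 114, 3)
    got <- bandpass(x, tr_seconds = 3)
    oracle <- apply(x, 2, dft_bandpass_oracle, tr = 3, low = 0.01, high = 0.08)
    expect_equal(got, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  })
})

test_that("band-pass passes in-band sinusoids and kills stop-band ones", {
  t <- (0:113) * 3
  pass <- matrix(sin(2 * pi * 0.04 * t), ncol = 1)
  out <- bandpass(pass, 3)
  expect_gt(cor(out[, 1], pass[, 1] - mean(pass[, 1])), 0.99)
  stop_band <- matrix(sin(2 * pi * 0.15 * t), ncol = 1)
  out2 <- bandpass(stop_band, 3)
  expect_lt(var(out2[, 1]), 0.01 * var(stop_band[, 1]))
  # constant column is pure DC and is removed entirely
  expect_equal(bandpass(matrix(5, 114, 1), 3), matrix(0, 114, 1),
               tolerance = 1e-12)
})

test_that("band-pass is idempotent and scales white-noise variance by band width", {
  withr::with_seed(32, {
    x <- matrix(rnorm(114 * 11), 114, 11)
    once <- bandpass(x, 3)
    twice <- bandpass(once, 3)
    expect_equal(once, twice, tolerance = 1e-10)
    # kept bins / total bins at n = 114, TR = 3, band 0.01-0.08 Hz
    n_kept <- sum({k <- 0:113; f <- pmin(k, 114 - k) / 342; f >= 0.01 & f <= 0.08})
    big <- matrix(rnorm(114 * 400), 114, 400)
    ratio <- mean(apply(bandpass(big, 3), 2, var)) / mean(apply(big, 2, var))
    expect_equal(ratio, n_kept / 114, tolerance = 0.03)
  })
  expect_error(bandpass(matrix(rnorm(40), 20, 2), 3, high_hz = 0.2), "Nyquist")
  expect_error(bandpass(matrix(rnorm(40), 20, 2), 3, 0.08, 0.01), "below")
})

test_that("pairwise connectivity matches the product-moment formula", {
  map2 <- tibble::tibble(node_id = 0:1, abbreviation = c("A", "B"),
                         name = c("A", "B"), subsystem = c("s1", "s2"))
  tc <- cbind(A = c(1, 2, 3, 4), B = c(1, 3, 2, 4))
  expect_equal(unname(pairwise_connectivity(tc, map2)), 0.8)
  tc2 <- cbind(A = c(1, 2, 3, 4), B = -c(1, 2, 3, 4))
  expect_equal(unname(pairwise_connectivity(tc2, map2)), -1.0)
  tc3 <- cbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4))
  expect_equal(unname(pairwise_connectivity(tc3, map2)), 1.0)
})

test_that("pairwise connectivity is invariant to positive affine rescaling", {
  withr::with_seed(33, {
    tc <- matrix(rnorm(50 * 11), 50, 11)
    r1 <- pairwise_connectivity(tc)
    tc2 <- tc
    tc2[, 3] <- 2.5 * tc2[, 3] + 7
    expect_equal(pairwise_connectivity(tc2), r1, tolerance = 1e-12)
  })
  bad <- matrix(rnorm(40), 20, 2)
  bad <- cbind(bad, matrix(1, 20, 9))
  colnames(bad) <- dmn_nodes()$abbreviation[order(dmn_nodes()$node_id)]
  expect_error(pairwise_connectivity(bad), "zero-variance")
})

test_that("framewise displacement follows the summed-absolute-differences rule", {
  flat <- matrix(1.3, 10, 6)
  expect_identical(mean_framewise_displacement(flat), 0)
  # single 1 mm x-translation step between volumes 1 and 2 of 3
  m <- matrix(0, 3, 6); m[2:3, 1] <- 1
  expect_equal(mean_framewise_displacement(m), 0.5)
  # single 0.01 rad rotation step across 2 volumes: 50 mm * 0.01
  m2 <- matrix(0, 2, 6); m2[2, 4] <- 0.01
  expect_equal(mean_framewise_displacement(m2), 0.5)
  # invariant to a constant offset of the whole trace
  withr::with_seed(34, {
    tr <- generate_motion_trace(1.2, 40)
    expect_equal(mean_framewise_displacement(tr + 3),
                 mean_framewise_displacement(tr), tolerance = 1e-12)
  })
  expect_error(mean_framewise_displacement(matrix(0, 1, 6)), "at least 2")
})

test_that("QC threshold is inclusive at 3.0 mm", {
  subj <- tibble::tibble(subject_id = sprintf("S%02d", 1:4),
                         mfwd = c(1.0, 2.99, 3.0, 4.0))
  qc <- qc_filter(subj)
  expect_identical(qc$retained$subject_id, c("S01", "S02"))
  expect_identical(qc$excluded$subject_id, c("S03", "S04"))
  expect_match(qc$excluded$qc_reason[1], ">= 3.00 mm")
})

test_that("mean subsystem connectivity averages exactly the block entries", {
  keys <- inter_block_pairs("midline_core", "dorsomedial")$pair
  conn <- tibble::as_tibble(setNames(as.list(rep(0.25, 55)),
                                     dmn_node_pairs()$pair))
  expect_equal(mean_subsystem_connectivity(conn, "midline_core", "dorsomedial"),
               0.25)
  conn2 <- conn
  conn2[keys] <- as.list(1:15)
  expect_equal(mean_subsystem_connectivity(conn2, "midline_core", "dorsomedial"),
               8.0)
  expect_identical(length(keys), 15L)
  expect_identical(nrow(inter_block_pairs("midline_core", "medial_temporal")), 9L)
  dropped <- conn[, setdiff(names(conn), "dlTC-PCC")]
  expect_error(mean_subsystem_connectivity(dropped, "midline_core",
                                           "dorsomedial"), "missing pair")
})
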