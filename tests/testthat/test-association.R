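test_that("noiseless outcomes are recovered exactly by the pair model", {
  withr::with_seed(41, {
    n <- 60L
    data <- tibble::tibble(
      subject_id = sprintf("S%03d", 1:n),
      race = factor(rep(race_levels <- c("caucasian", "african_american"),
                        length.out = n), levels = race_levels),
      diagnosis = factor("NC", levels = c("NC", "MCI", "AD")),
      sex = factor(sample(rep(c("female", "male"), length.out = n))),
      age = runif(n, 60, 85),
      mfwd = runif(n, 0.1, 0.6),
      apoe_e4 = rbinom(n, 1, 0.4),
      cognitive_z = rnorm(n),
      abeta42 = runif(n, 60, 300)
    )
    aa <- as.integer(data$race == "african_american")
    fem <- as.integer(data$sex == "female")
    data[["PCU-vlTC"]] <- 0.05 + 0.3 * data$cognitive_z - 0.2 * aa +
      0.18 * aa * data$cognitive_z + 0.001 * data$age + 0.02 * fem +
      0.01 * data$apoe_e4 - 0.05 * data$mfwd
    fit <- fit_pair_model(data, "PCU-vlTC", "cognition", interaction = TRUE)
    est <- setNames(fit$terms$estimate, fit$terms$term)
    expect_equal(est[["race:cognitive_z"]], 0.18, tolerance = 1e-8)
    expect_equal(est[["cognitive_z"]], 0.3, tolerance = 1e-8)
    expect_equal(est[["race"]], -0.2, tolerance = 1e-8)
    expect_equal(est[["age"]], 0.001, tolerance = 1e-8)
    expect_identical(fit$n_used, n)
  })
})

test_that("scan engine reproduces per-pair lm fits exactly", {
  data <- simulated_data(small_config(), seed = 6)
  scan <- interaction_scan(data, "ttau", subset = "amyloid_positive")
  gated <- abeta_gate(data)
  for (key in c("PCU-vlTC", "dlTC-dmPFC", "HIP-PCC")) {
    row <- scan$results[scan$results$pair == key, ]
    # independent route: stats::lm with the same design
    d <- dplyr::mutate(gated,
                       race_aa = as.integer(race == "african_american"),
                       sex_female = as.integer(sex == "female"))
    d$y <- d[[key]]
    ref <- lm(y ~ age + sex_female + mfwd + apoe_e4 + ttau + race_aa +
                race_aa:ttau, data = d)
    co <- summary(ref)$coefficients["ttau:race_aa", ]
    expect_equal(row$estimate, unname(co["Estimate"]), tolerance = 1e-10)
    expect_equal(row$p.value, unname(co["Pr(>|t|)"]), tolerance = 1e-10)
    ci <- confint(ref)["ttau:race_aa", ]
    expect_equal(c(row$conf.low, row$conf.high), unname(ci), tolerance = 1e-10)
    # and the single-pair public route agrees as well
    fit <- fit_pair_model(data, key, "ttau", interaction = TRUE,
                          subset = "amyloid_positive")
    focal <- fit$terms[fit$terms$term == "race:ttau", ]
    expect_equal(focal$estimate, row$estimate, tolerance = 1e-12)
    expect_equal(focal$p.value, row$p.value, tolerance = 1e-12)
  }
})

test_that("baseline contrast uses controls only and reports all pairs by p", {
  data <- simulated_data(small_config(), seed = 7)
  base <- baseline_contrast(data)
  expect_s3_class(base, "dmn_scan")
  expect_identical(nrow(base$results), 55L)
  expect_identical(base$n_used, sum(data$diagnosis == "NC"))
  expect_false(is.unsorted(base$results$p.value, na.rm = TRUE))
  single_race <- dplyr::filter(data, race == "caucasian")
  expect_error(baseline_contrast(single_race), "both races")
})

test_that("interaction scans cover all pairs and expose correction columns", {
  data <- simulated_data(small_config(), seed = 8)
  scans <- scan_all_biomarkers(data)
  expect_named(scans, c("cognition", "abeta42", "ttau"))
  for (s in scans) {
    expect_identical(nrow(s$results), 55L)
    expect_true(all(c("bh_adjusted", "bh_rejected", "storey_q")
                    %in% names(s$results)))
  }
  expect_identical(scans$ttau$n_used, nrow(abeta_gate(data)))
  pool <- pool_pvalues(scans)
  expect_identical(nrow(pool), 165L)
  # degenerate outcome: marked failed, not fatal
  broken <- data
  broken[["PCU-vlTC"]] <- 0.4
  scan <- interaction_scan(broken, "cognition")
  expect_identical(scan$failed, "PCU-vlTC")
  expect_true(is.na(scan$results$p.value[scan$results$pair == "PCU-vlTC"]))
  # but fatal for the single-pair fit, naming the pair
  expect_error(fit_pair_model(broken, "PCU-vlTC", "cognition",
                              interaction = TRUE), "zero outcome variance")
})

test_that("the amyloid gate is strict at the cutoff", {
  subj <- tibble::tibble(abeta42 = c(150, 192, 200, 77.65))
  expect_identical(nrow(abeta_gate(subj)), 2L)
  expect_identical(abeta_gate(subj)$abeta42, c(150, 77.65))
  expect_identical(nrow(abeta_gate(tibble::tibble(abeta42 = 191.9))), 1L)
  expect_identical(nrow(abeta_gate(tibble::tibble(abeta42 = 192.0))), 0L)
})

test_that("BH step-up matches the hand-worked example and boundary cases", {
  got <- bh_stepup(c(0.01, 0.02, 0.50), q = 0.10)
  expect_identical(got$bh_rejected, c(TRUE, TRUE, FALSE))
  expect_equal(got$bh_adjusted, c(0.03, 0.03, 0.50))
  all_one <- bh_stepup(rep(1, 5))
  expect_true(all(!all_one$bh_rejected))
  expect_true(all(all_one$bh_adjusted == 1))
  single <- bh_stepup(0.09, q = 0.10)
  expect_true(single$bh_rejected)
  expect_error(bh_stepup(c(0.1, 0)), "\\(0, 1\\]")
})

test_that("BH rejections are monotone in the FDR level", {
  withr::with_seed(42, {
    for (i in 1:50) {
      p <- runif(55)^rexp(1, 0.5)
      r05 <- bh_stepup(p, 0.05)$bh_rejected
      r10 <- bh_stepup(p, 0.10)$bh_rejected
      expect_true(all(r10[r05]))
    }
  })
})

test_that("Storey q-values match the hand-worked formulas", {
  got <- storey_q(c(0.01, 0.02, 0.5, 0.9), lambda = 0.5)
  expect_equal(attr(got, "pi0"), 0.5)
  expect_equal(got$storey_q, c(0.02, 0.02, 1 / 3, 0.45))
  # pi0 capped at 1: q-values collapse onto BH adjusted p
  p_high <- c(0.6, 0.7, 0.8, 0.95)
  capped <- storey_q(p_high)
  expect_equal(attr(capped, "pi0"), 1)
  expect_equal(capped$storey_q, p.adjust(p_high, "BH"))
  # pi0 is consistent for uniform p at large m
  withr::with_seed(43, {
    expect_lt(abs(attr(storey_q(runif(10000)), "pi0") - 1), 0.05)
  })
  expect_error(storey_q(c(0.2, 0.3), lambda = 1.2), "lambda")
})

test_that("subsystem ANCOVA detects a planted uniform race offset", {
  eff <- purrr::map_dfr(inter_block_pairs("midline_core", "dorsomedial")$pair,
                        effect_spec, beta_race = 0.15)
  hits <- 0L
  for (r in 1:40) {
    data <- simulated_data(cohort_config(), effects = eff, seed = 100 + r)
    res <- subsystem_ancova(data, "dm_midline")
    hits <- hits + (res$p.value < 0.05)
  }
  expect_gte(hits / 40, 0.8)
})

test_that("subsystem ANCOVA matches a base-R model-comparison F test", {
  data <- simulated_data(small_config(), seed = 9)
  got <- subsystem_ancova(data, "mtl_midline")
  d <- dplyr::mutate(data,
                     race_aa = as.integer(race == "african_american"),
                     sex_female = as.integer(sex == "female"),
                     y = mean_subsystem_connectivity(data, "midline_core",
                                                     "medial_temporal"))
  full <- lm(y ~ race_aa + diagnosis + age + sex_female, data = d)
  red <- lm(y ~ diagnosis + age + sex_female, data = d)
  ref <- anova(red, full)
  expect_equal(got$statistic, ref$F[2], tolerance = 1e-10)
  expect_equal(got$p.value, ref$`Pr(>F)`[2], tolerance = 1e-10)
  # degenerate design: a race stratum with a single diagnosis
  degen <- dplyr::filter(data, !(race == "african_american" & diagnosis != "NC"))
  expect_error(subsystem_ancova(degen, "dm_midline"), "degenerate")
})

test_that("fitted values are invariant to centering covariates", {
  data <- simulated_data(small_config(), seed = 10)
  f1 <- fit_pair_model(data, "PCU-vlTC", "cognition", interaction = TRUE)
  centered <- dplyr::mutate(data, age = age - mean(age), mfwd = mfwd - mean(mfwd))
  f2 <- fit_pair_model(centered, "PCU-vlTC", "cognition", interaction = TRUE)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-10)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  int1 <- f1$terms[f1$terms$term == "race:cognitive_z", ]
  int2 <- f2$terms[f2$terms$term == "race:cognitive_z", ]
  expect_equal(int1$estimate, int2$estimate, tolerance = 1e-10)
})

test_that("collinear designs raise an informative error", {
  data <- simulated_data(small_config(), seed = 12)
  data$dup <- data$age
  expect_error(
    fit_pair_model(data, "PCU-vlTC", "cognition", interaction = TRUE,
                   extra_covariates = c("age", "dup")),
    "collinear"
  )
})
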