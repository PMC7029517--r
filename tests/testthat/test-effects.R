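cohort1 <- generate_cohort(seed = 2)[1, ]
cohort_aa <- dplyr::filter(generate_cohort(seed = 2), race == "african_american")[1, ]

test_that("all-zero betas leave the base matrix exactly untouched", {
  eff <- dplyr::bind_rows(
    effect_spec("PCU-vlTC", "cognition"),
    effect_spec("TP-HIP")
  )
  base <- default_base_correlation()
  expect_identical(target_correlation_matrix(cohort1, eff, base), base)
  expect_identical(target_correlation_matrix(cohort1, NULL, base), base)
})

test_that("a pure race offset reduces to tanh(atanh(r0) + beta_race)", {
  eff <- effect_spec("PCU-vlTC", beta_race = -0.31, baseline_r = 0.2)
  base <- default_base_correlation()
  got_aa <- target_correlation_matrix(cohort_aa, eff, base)
  expect_equal(got_aa["PCU", "vlTC"], tanh(atanh(0.2) - 0.31), tolerance = 1e-12)
  # reference race keeps the baseline
  cau <- dplyr::mutate(cohort1, race = factor("caucasian", levels = levels(race)))
  got_c <- target_correlation_matrix(cau, eff, base)
  expect_equal(got_c["PCU", "vlTC"], 0.2, tolerance = 1e-12)
})

test_that("interaction planting is linear in the biomarker on the atanh scale", {
  subj <- dplyr::mutate(cohort_aa, cognitive_z = -1.5)
  eff <- effect_spec("PCU-vlTC", "cognition", beta_interaction = 0.18,
                     baseline_r = 0.1)
  got <- target_correlation_matrix(subj, eff, default_base_correlation())
  expect_equal(got["vlTC", "PCU"], tanh(atanh(0.1) + 0.18 * -1.5),
               tolerance = 1e-12)
})

test_that("positive-definiteness repair is deterministic and well-formed", {
  m <- default_base_correlation()
  m["PCU", "PCC"] <- m["PCC", "PCU"] <- 0.999
  m["PCU", "vmPFC"] <- m["vmPFC", "PCU"] <- -0.999
  m["PCC", "vmPFC"] <- m["vmPFC", "PCC"] <- 0.999
  expect_true(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < 0)
  r1 <- repair_correlation(m)
  r2 <- repair_correlation(m)
  expect_identical(r1, r2)
  expect_equal(diag(r1), setNames(rep(1, 11), colnames(m)))
  expect_true(min(eigen(r1, symmetric = TRUE, only.values = TRUE)$values) > 0)
  # already-PD input passes through untouched
  expect_identical(repair_correlation(default_base_correlation()),
                   default_base_correlation())
})

test_that("effect rows on the same pair combine additively on the atanh scale", {
  subj <- dplyr::mutate(cohort_aa, cognitive_z = -1, ttau = 100)
  eff <- dplyr::bind_rows(
    effect_spec("PCU-vlTC", "cognition", beta_interaction = 0.18, baseline_r = 0.1),
    effect_spec("PCU-vlTC", "ttau", beta_interaction = 0.003)
  )
  got <- target_correlation_matrix(subj, eff, default_base_correlation())
  expect_equal(got["PCU", "vlTC"],
               tanh(atanh(0.1) + 0.18 * -1 + 0.003 * 100), tolerance = 1e-12)
})

test_that("vectorized per-subject targets agree with the single-subject path", {
  cohort <- generate_cohort(seed = 4)[1:10, ]
  eff <- default_effects()
  base <- default_base_correlation()
  fast <- dmnmod:::planted_targets(cohort, eff, base, dmn_nodes())
  for (i in seq_len(nrow(cohort))) {
    expect_equal(fast[[i]],
                 target_correlation_matrix(cohort[i, ], eff, base),
                 tolerance = 1e-12)
  }
})

test_that("malformed effect specifications are rejected", {
  expect_error(effect_spec("PCU-vlTC", baseline_r = 1), "inside")
  expect_error(effect_spec("PCU-vlTC", beta_interaction = 0.1), "biomarker")
  expect_error(effect_spec("PCU-XX", "cognition"), "unknown node")
})
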