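test_that("degenerate spec with all variances zero yields the grand mean", {
  spec <- simulation_spec(n_genotypes = 4, n_harvests = 3, n_replicates = 2,
                          sigma2_g = 0, sigma2_e = 0, env_effect_sd = 0,
                          interaction_rank = 0, interaction_sd = 0,
                          grand_mean = 5, seed = 1)
  sim <- generate_met(spec)
  expect_true(all(sim$records$value == 5))
})

test_that("the same spec and seed reproduce the trial exactly", {
  spec <- simulation_spec(n_genotypes = 10, seed = 42)
  a <- generate_met(spec)
  b <- generate_met(spec)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- generate_met(simulation_spec(n_genotypes = 10, seed = 43))
  expect_false(identical(a$records$value, c$records$value))
})

test_that("planted effects sum to zero exactly and have the stated rank", {
  spec <- simulation_spec(n_genotypes = 15, n_harvests = 6,
                          interaction_rank = 3, seed = 7)
  truth <- generate_met(spec)$truth
  expect_equal(sum(truth$genotype_effects), 0)
  expect_equal(sum(truth$harvest_effects), 0)
  sv <- svd(truth$interaction)$d
  expect_equal(sum(sv > 1e-10), 3)
  expect_equal(sort(sv[1:3], decreasing = TRUE), sort(truth$lambdas, decreasing = TRUE),
               tolerance = 1e-10)
  # planted score vectors are orthonormal
  expect_equal(crossprod(truth$genotype_scores), diag(3), ignore_attr = TRUE)
  expect_equal(crossprod(truth$env_scores), diag(3), ignore_attr = TRUE)
})

test_that("spec invariants are enforced", {
  expect_error(simulation_spec(n_genotypes = 5, n_harvests = 4,
                               interaction_rank = 4), "interaction_rank")
  expect_error(simulation_spec(sigma2_g = -1), "non-negative")
  expect_error(simulation_spec(regimes = "arid"), "regimes")
})

test_that("empirical grand mean converges to the specified one", {
  spec <- simulation_spec(n_genotypes = 40, n_harvests = 6, n_replicates = 8,
                          sigma2_g = 2, sigma2_e = 1, seed = 3)
  sim <- generate_met(spec)
  # effects are centered exactly, so the deviation is pure residual noise
  se <- sqrt(spec$sigma2_e / nrow(sim$records))
  expect_lt(abs(mean(sim$records$value) - spec$grand_mean), 3 * se)
})

test_that("stress multipliers act on the wet expectation as specified", {
  spec <- simulation_spec(n_genotypes = 12, sigma2_g = 1, sigma2_e = 0,
                          env_effect_sd = 0, interaction_sd = 0,
                          interaction_rank = 0, seed = 5)
  ps <- generate_paired_stress_trial(spec,
                                     stress_yield_multiplier = c(MWS = 1.0),
                                     tolerance_fraction = 0)
  means <- tapply(ps$records$value, list(ps$records$genotype, ps$records$regime), mean)
  expect_equal(means[, "MWS"], means[, "wet"], tolerance = 1e-12)
  expect_length(ps$tolerant, 0)

  ps2 <- generate_paired_stress_trial(spec,
                                      stress_yield_multiplier = c(MWS = 0.5),
                                      tolerance_fraction = 0)
  m2 <- tapply(ps2$records$value, list(ps2$records$genotype, ps2$records$regime), mean)
  expect_equal(m2[, "MWS"], 0.5 * m2[, "wet"], tolerance = 1e-12)

  expect_error(generate_paired_stress_trial(
    spec, stress_yield_multiplier = c(MWS = 0)), "\\(0, 1\\]")
  expect_error(generate_paired_stress_trial(spec, tolerance_fraction = 1.2),
               "tolerance_fraction")
})

test_that("tolerant genotypes escape most of the stress penalty", {
  spec <- simulation_spec(n_genotypes = 30, sigma2_g = 1, sigma2_e = 0,
                          env_effect_sd = 0, interaction_sd = 0,
                          interaction_rank = 0, seed = 11)
  ps <- generate_paired_stress_trial(spec, tolerance_fraction = 0.2,
                                     tolerance_attenuation = 1)
  means <- tapply(ps$records$value, list(ps$records$genotype, ps$records$regime), mean)
  tol <- rownames(means) %in% ps$tolerant
  expect_equal(means[tol, "MWS"], means[tol, "wet"], tolerance = 1e-12)
  expect_true(all(means[!tol, "MWS"] < means[!tol, "wet"]))
  expect_length(ps$tolerant, ceiling(0.2 * 30))
})

test_that("feed-quality draws honour the requested correlation structure", {
  fq0 <- feed_quality_spec(cp_fiber_cor = c(NDF = 0, ADF = 0, ADL = 0))
  rec <- generate_feed_quality(fq0, n_genotypes = 200, seed = 1)
  wide <- tidyr::pivot_wider(rec, names_from = "trait", values_from = "value")
  expect_lt(abs(cor(wide$CP, wide$NDF)), 0.2)

  fq <- feed_quality_spec(cp_fiber_cor = c(NDF = -0.6, ADF = -0.55, ADL = -0.4))
  rec2 <- generate_feed_quality(fq, n_genotypes = 500, seed = 2)
  wide2 <- tidyr::pivot_wider(rec2, names_from = "trait", values_from = "value")
  # Fisher-z sampling band around the -0.6 target at n = 500
  expect_gt(cor(wide2$CP, wide2$NDF), -0.75)
  expect_lt(cor(wide2$CP, wide2$NDF), -0.45)
  expect_lt(cor(wide2$CP, wide2$ADF), 0)

  expect_error(feed_quality_spec(cp_fiber_cor = c(NDF = -1.5, ADF = 0, ADL = 0)),
               "\\[-1, 1\\]")
  expect_error(feed_quality_spec(cp_fiber_cor = c(NDF = -0.9, ADF = -0.9,
                                                  ADL = 0.9)),
               "positive semi-definite")
})
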