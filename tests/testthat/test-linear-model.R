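test_that("factorial sums of squares match the direct-summation oracle", {
  set.seed(20)
  for (rep in 1:3) {
    grid <- expand.grid(genotype = paste0("g", 1:3),
                        regime = c("MWS", "SWS"),
                        harvest = 1:2, replicate = 1:2,
                        stringsAsFactors = FALSE)
    df <- make_records(grid$genotype, grid$regime, grid$harvest,
                       grid$replicate, "TDW", rnorm(nrow(grid), 10, 3))
    got <- fit_factorial_anova(df, "TDW")
    ora <- oracle_factorial_ss(df)
    for (term in c("G", "T", "H", "G:T", "G:H", "T:H", "G:T:H", "Residuals")) {
      expect_equal(got$sumsq[got$term == term], ora[[term]],
                   tolerance = 1e-10, label = term)
    }
    # SS additivity on balanced data
    expect_equal(sum(got$sumsq), ora$total, tolerance = 1e-8)
  }
})

test_that("pure single-factor signal loads all structural SS on that factor", {
  spec <- simulation_spec(n_genotypes = 6, n_harvests = 4, n_replicates = 2,
                          regimes = c("MWS", "SWS"), sigma2_g = 9,
                          sigma2_e = 0, env_effect_sd = 0,
                          interaction_rank = 0, interaction_sd = 0, seed = 2)
  tab <- fit_factorial_anova(generate_met(spec)$records, "TDW")
  non_g <- sum(tab$sumsq[!tab$term %in% c("G", "Residuals")])
  expect_lt(non_g, 1e-8 * tab$sumsq[tab$term == "G"])
  expect_lt(tab$p.value[tab$term == "G"], 1e-10)
})

test_that("constant data gives zero SS and undefined F", {
  df <- make_records(rep(c("g1", "g2"), each = 4), "MWS",
                     rep(rep(1:2, each = 2), 2), rep(1:2, 4), "TDW", 7)
  tab <- fit_factorial_anova(df, "TDW")
  expect_equal(tab$sumsq, rep(0, nrow(tab)))
  expect_true(all(is.na(tab$statistic)))
})

test_that("unbalanced or degenerate designs are refused", {
  df <- make_records(c("g1", "g1", "g2"), "MWS", c(1, 2, 1), 1, "TDW", 1:3)
  expect_error(fit_factorial_anova(df, "TDW"), "unbalanced")
  one_level <- make_records("g1", "MWS", 1:4, 1, "TDW", 1:4)
  expect_error(fit_factorial_anova(one_level, "TDW"), "2 levels")
  expect_error(fit_factorial_anova(df, "PH"), "no observations")
})

test_that("wet-season data drop the treatment term", {
  sim <- generate_met(simulation_spec(n_genotypes = 4, regimes = "wet", seed = 4))
  tab <- fit_factorial_anova(sim$records, "TDW")
  expect_setequal(tab$term, c("G", "H", "G:H", "Residuals"))
})

test_that("LSD has the closed form and the expected monotonicities", {
  # t(0.975, 10) = 2.228139 from published t tables; sqrt(2*2/4) = 1
  expect_equal(lsd_value(2, 10, 4, 0.05), 2.228139, tolerance = 1e-6)
  expect_equal(lsd_value(0, 10, 4), 0)
  expect_gt(lsd_value(3, 10, 4), lsd_value(2, 10, 4))
  expect_lt(lsd_value(2, 10, 8), lsd_value(2, 10, 4))
  # as alpha -> 1 the quantile collapses and LSD -> 0 monotonically
  alphas <- c(0.05, 0.2, 0.5, 0.8, 0.99)
  lsds <- vapply(alphas, function(a) lsd_value(2, 10, 4, a), numeric(1))
  expect_true(all(diff(lsds) < 0))
  expect_lt(lsds[length(lsds)], 0.05)
  expect_error(lsd_value(2, 10, 4, alpha = 1.2), "alpha")
  expect_error(lsd_value(2, 0, 4), "df_error")
})

test_that("letter display agrees with exhaustive pairwise LSD checks", {
  expect_equal(letter_display(c(a = 10, b = 5), lsd = 2)$letters, c("a", "b"))
  expect_equal(letter_display(c(a = 10, b = 10), lsd = 2)$letters, c("a", "a"))
  set.seed(30)
  for (i in 1:20) {
    means <- setNames(runif(10, 0, 10), paste0("m", 1:10))
    lsd <- runif(1, 0.5, 4)
    disp <- letter_display(means, lsd)
    m <- setNames(disp$mean, disp$group)
    for (p in seq_len(9)) for (q in (p + 1):10) {
      share <- any(strsplit(disp$letters[p], "")[[1]] %in%
                     strsplit(disp$letters[q], "")[[1]])
      expect_identical(share, abs(m[[p]] - m[[q]]) <= lsd,
                       label = sprintf("pair %d-%d (lsd %.3f)", p, q, lsd))
    }
  }
})

test_that("CV percent follows its definition", {
  expect_equal(cv_percent(0, 5), 0)
  expect_equal(cv_percent(4, 20), 10)
  expect_error(cv_percent(4, 0), "zero")
  # simulation: residual sd at 15% of the mean gives CV near 15
  spec <- simulation_spec(n_genotypes = 50, n_harvests = 4, n_replicates = 4,
                          sigma2_g = 1, sigma2_e = 2.25, grand_mean = 10,
                          seed = 6)
  sim <- generate_met(spec)
  tab <- fit_factorial_anova(sim$records, "TDW")
  ms_e <- tab$meansq[tab$term == "Residuals"]
  expect_equal(cv_percent(ms_e, mean(sim$records$value)), 15, tolerance = 0.08)
})

test_that("Bartlett check flags heterogeneity and rejects degenerate groups", {
  same <- list(c(1, 2, 3, 4), c(11, 12, 13, 14))  # identical spread pattern
  expect_equal(bartlett_check(same)$statistic, 0, tolerance = 1e-12)
  set.seed(8)
  het <- list(rnorm(50, sd = 1), rnorm(50, sd = 10))
  expect_lt(bartlett_check(het)$p.value, 1e-3)
  expect_error(bartlett_check(list(c(1, 2))), "2 groups")
  expect_error(bartlett_check(list(c(1, 1, 1), c(1, 2, 3))), "zero variance")
})
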