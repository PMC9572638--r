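random_cells <- function(n, m, r = 2) {
  as_cell_means(matrix(rnorm(n * m, 10, 2), n, m), replication = r)
}

test_that("a purely additive table has no multiplicative structure", {
  g <- c(-2, 0, 1, 1); e <- c(-1, 0.5, 0.5, 0, 0)
  y <- 10 + outer(g, rep(1, 5)) + outer(rep(1, 4), e)
  fit <- fit_ammi(as_cell_means(y), n_axes = 2)
  expect_equal(fit$mu, 10)
  expect_equal(unname(fit$g), g)
  expect_equal(unname(fit$e), e)
  expect_lt(max(fit$lambdas), 1e-10)
  expect_equal(ammi_anova(fit)$sumsq[3], 0, tolerance = 1e-20)
})

test_that("full-rank reconstruction reproduces the cells exactly", {
  set.seed(23)
  cells <- random_cells(7, 5)
  fit <- fit_ammi(cells, n_axes = 4)
  recon <- fit$mu + outer(fit$g, rep(1, 5)) + outer(rep(1, 7), fit$e) +
    fit$gscores %*% diag(fit$lambdas) %*% t(fit$escores)
  expect_equal(unname(recon), unname(cells$means), tolerance = 1e-8)
  expect_lt(max(abs(fit$residual)), 1e-8)
})

test_that("a planted rank-1 interaction is recovered up to sign", {
  set.seed(24)
  n <- 10; m <- 6
  a <- rnorm(n); a <- a - mean(a); a <- a / sqrt(sum(a^2))
  b <- rnorm(m); b <- b - mean(b); b <- b / sqrt(sum(b^2))
  lambda <- 7.3
  y <- 10 + lambda * outer(a, b)
  fit <- fit_ammi(as_cell_means(y), n_axes = 2)
  expect_equal(fit$lambdas[1], lambda, tolerance = 1e-8)
  expect_lt(fit$lambdas[2], 1e-8)
  sgn <- sign(sum(fit$gscores[, 1] * a))
  expect_equal(sgn * unname(fit$gscores[, 1]), a, tolerance = 1e-8)
  expect_equal(sgn * unname(fit$escores[, 1]), b, tolerance = 1e-8)
})

test_that("main effects sum to zero and scores stay orthonormal", {
  set.seed(25)
  fit <- fit_ammi(random_cells(9, 6), n_axes = 3)
  expect_lt(abs(sum(fit$g)), 1e-10)
  expect_lt(abs(sum(fit$e)), 1e-10)
  k <- length(fit$lambdas)
  expect_equal(crossprod(fit$gscores), diag(k), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(crossprod(fit$escores), diag(k), ignore_attr = TRUE,
               tolerance = 1e-10)
  # singular values exhaust the interaction sum of squares
  expect_equal(sum(fit$lambdas^2), sum(fit$interaction^2), tolerance = 1e-8)
})

test_that("the SS partition matches brute-force double summation", {
  set.seed(26)
  cells <- random_cells(6, 5, r = 3)
  y <- cells$means; n <- 6; m <- 5; r <- 3
  fit <- fit_ammi(cells, n_axes = 2)
  tab <- ammi_anova(fit)
  gm <- mean(y)
  ss_g <- 0; ss_e <- 0; ss_gei <- 0
  for (i in 1:n) ss_g <- ss_g + m * r * (mean(y[i, ]) - gm)^2
  for (j in 1:m) ss_e <- ss_e + n * r * (mean(y[, j]) - gm)^2
  for (i in 1:n) for (j in 1:m) {
    ss_gei <- ss_gei + r * (y[i, j] - mean(y[i, ]) - mean(y[, j]) + gm)^2
  }
  expect_equal(tab$sumsq[tab$term == "G"], ss_g, tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "E"], ss_e, tolerance = 1e-10)
  expect_equal(tab$sumsq[tab$term == "GEI"], ss_gei, tolerance = 1e-10)
  # Frobenius identity: GEI = sum over all IPC axes
  expect_equal(sum(fit$ss$IPC), fit$ss$GEI, tolerance = 1e-8)
  # Gollob df
  expect_equal(tab$df[tab$term == "IPC1"], n + m - 1 - 2)
  expect_equal(tab$df[tab$term == "IPC2"], n + m - 1 - 4)
})

test_that("ASV follows the weighted-distance formula", {
  expect_equal(asv(0, 0, 2, 1), 0)
  expect_equal(asv(3, 4, 5, 5), 5)  # equal SS: a 3-4-5 triangle
  expect_error(asv(1, 1, 2, 0), "degenerate")
  expect_equal(asv(2, 1, 6, 2, weight = "ms", df_ipc1 = 3, df_ipc2 = 1),
               sqrt(4 + 1))
  # monotone in both coordinates
  expect_gt(asv(2, 1, 3, 1), asv(1, 1, 3, 1))
  expect_gt(asv(1, 2, 3, 1), asv(1, 1, 3, 1))
})

test_that("pipeline ASV equals the formula oracle on fitted scores", {
  set.seed(27)
  fit <- fit_ammi(random_cells(20, 6))
  st <- stability_ranking(fit)
  ora <- oracle_asv(st$IPC1, st$IPC2, fit$ss$IPC[1], fit$ss$IPC[2])
  expect_equal(st$ASV, ora, tolerance = 1e-12)
})

test_that("YSI ordering equals a brute-force rank-and-sum oracle", {
  set.seed(28)
  fit <- fit_ammi(random_cells(20, 6))
  st <- stability_ranking(fit)
  ora <- oracle_ysi(st$mean_yield, st$ASV)
  expect_equal(st$YSI, ora)
  expect_true(all(st$YSI >= 2))
  expect_equal(sort(st$RY), sort(rank(seq_len(20))))
  # a genotype that is top yielder and most stable attains the minimum
  y <- matrix(10, 4, 4) + outer(c(3, 0, -1, -2), rep(1, 4)) +
    rbind(c(0, 0, 0, 0), c(1, -1, 0, 0), c(-1, 0, 1, 0), c(0, 1, -1, 0))
  st2 <- stability_ranking(fit_ammi(as_cell_means(y)))
  expect_equal(st2$YSI[st2$genotype == "g1"], 2)
})

test_that("flipping an SVD axis leaves ASV, SS and reconstruction unchanged", {
  set.seed(29)
  cells <- random_cells(8, 5)
  fit <- fit_ammi(cells)
  flipped <- fit
  flipped$gscores[, 1] <- -flipped$gscores[, 1]
  flipped$escores[, 1] <- -flipped$escores[, 1]
  expect_equal(stability_ranking(flipped)$ASV, stability_ranking(fit)$ASV)
  recon <- function(f) f$gscores %*% diag(f$lambdas) %*% t(f$escores)
  expect_equal(recon(flipped), recon(fit))
})

test_that("rescaling all cells scales lambdas and preserves the ranking", {
  set.seed(31)
  cells <- random_cells(10, 6)
  fit1 <- fit_ammi(cells)
  fit2 <- fit_ammi(as_cell_means(cells$means * 4, replication = cells$replication))
  expect_equal(fit2$lambdas, 4 * fit1$lambdas, tolerance = 1e-10)
  s1 <- stability_ranking(fit1); s2 <- stability_ranking(fit2)
  expect_equal(s2$RY, s1$RY)
  expect_equal(s2$RASV, s1$RASV)
  expect_equal(s2$YSI, s1$YSI)
})

test_that("cell matrices reject missing cells and tiny designs", {
  m <- matrix(1, 3, 3); m[2, 2] <- NA
  expect_error(as_cell_means(m), "missing")
  expect_error(as_cell_means(matrix(1, 2, 5)), "at least 3")
  expect_error(fit_ammi(as_cell_means(matrix(rnorm(9), 3, 3)), n_axes = 5),
               "n_axes")
  rec <- make_records(rep(c("g1", "g2", "g3"), each = 3), "MWS",
                      rep(1:3, 3), 1, "TDW", rnorm(9))
  cm <- cell_means(rec, regime = "MWS")
  expect_equal(dim(cm$means), c(3, 3))
  expect_equal(cm$replication, 1)
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(32)
  fit <- fit_ammi(random_cells(6, 5))
  td <- tidy(fit, ms_error = 1, df_error = 40)
  expect_true(all(c("term", "df", "sumsq", "statistic", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$prop_ss_G + gl$prop_ss_E + gl$prop_ss_GEI, 1, tolerance = 1e-12)
})
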