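# Seeded RNG scope: every generator draws from its own stream and restores
# the caller's RNG state, so simulation calls never leak global state.
with_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define a multi-environment trial simulation
#'
#' Describes a balanced staged-harvest trial with additive genotype and
#' harvest (environment) effects, a low-rank genotype-by-environment
#' interaction and Gaussian residual error. The same spec and seed always
#' produce the same trial, and all drawn effects are returned as ground
#' truth so downstream estimators can be checked for parameter recovery.
#'
#' @param n_genotypes,n_harvests,n_replicates Design size. Harvest rounds
#'   play the role of environments for stability analysis.
#' @param regimes Water regimes to simulate, a subset of
#'   `c("wet", "MWS", "SWS")`.
#' @param sigma2_g Genotypic variance (trait units squared).
#' @param sigma2_e Residual (plot error) variance.
#' @param env_effect_sd Spread of harvest effects (and of regime effects when
#'   more than one regime is simulated).
#' @param interaction_rank Number of nonzero singular values of the planted
#'   genotype-by-harvest interaction; must be at most
#'   `min(n_genotypes, n_harvests) - 1`.
#' @param interaction_sd Root-mean-square size of the interaction term.
#' @param grand_mean Overall trait mean, in trait units.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A `simulation_spec` object (a validated list).
#' @export
simulation_spec <- function(n_genotypes = 84, n_harvests = 6, n_replicates = 2,
                            regimes = "MWS",
                            sigma2_g = 4, sigma2_e = 1, env_effect_sd = 2,
                            interaction_rank = 2, interaction_sd = 1,
                            grand_mean = 10, seed = 1L) {
  if (n_genotypes < 2 || n_harvests < 1 || n_replicates < 1) {
    abort("design must have >= 2 genotypes and >= 1 harvest and replicate")
  }
  bad <- setdiff(regimes, regime_levels)
  if (length(regimes) == 0 || length(bad) > 0) {
    abort("regimes must be a non-empty subset of wet, MWS, SWS")
  }
  if (sigma2_g < 0 || sigma2_e < 0 || env_effect_sd < 0 || interaction_sd < 0) {
    abort("variances and effect spreads must be non-negative")
  }
  if (interaction_rank < 0 ||
      interaction_rank > min(n_genotypes, n_harvests) - 1) {
    abort(paste0("interaction_rank must be between 0 and ",
                 "min(n_genotypes, n_harvests) - 1"))
  }
  structure(
    list(n_genotypes = as.integer(n_genotypes),
         n_harvests = as.integer(n_harvests),
         n_replicates = as.integer(n_replicates),
         regimes = regimes,
         sigma2_g = sigma2_g, sigma2_e = sigma2_e,
         env_effect_sd = env_effect_sd,
         interaction_rank = as.integer(interaction_rank),
         interaction_sd = interaction_sd,
         grand_mean = grand_mean, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

# Centered draws: models downstream assume effects sum to zero, which
# sampling gives only in expectation, so it is enforced exactly.
draw_centered <- function(n, sd) {
  if (sd == 0 || n == 1) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  x - mean(x)
}

# Low-rank interaction with exactly `rank` nonzero singular values, built
# from orthonormalized Gaussian score vectors that are also orthogonal to
# the constant vector (so the planted matrix is doubly centered).
draw_interaction <- function(n, m, rank, sd) {
  if (rank == 0 || sd == 0) {
    return(list(matrix = matrix(0, n, m), lambdas = numeric(0),
                gscores = matrix(0, n, 0), escores = matrix(0, m, 0)))
  }
  orth <- function(k, r) {
    z <- matrix(stats::rnorm(k * r), k, r)
    z <- sweep(z, 2, colMeans(z))      # row/column sums of the product are 0
    qr.Q(qr(z))
  }
  a <- orth(n, rank)
  g <- orth(m, rank)
  w <- 2^(-(seq_len(rank) - 1))
  w <- w / sqrt(sum(w^2))
  lambdas <- sd * sqrt(n * m) * w      # RMS cell size of the interaction = sd
  list(matrix = a %*% diag(lambdas, rank) %*% t(g),
       lambdas = lambdas, gscores = a, escores = g)
}

#' Generate a balanced multi-environment trial with known ground truth
#'
#' Draws one observation per genotype x regime x harvest x replicate as
#' `grand_mean + genotype effect + regime effect + harvest effect +
#' low-rank interaction + Gaussian error`. Genotype, regime and harvest
#' effects are centered to sum to zero exactly; the genotype-by-harvest
#' interaction is built from orthonormal score vectors and shared across
#' regimes.
#'
#' @param spec A [simulation_spec()].
#' @param trait Trait label recorded on every observation.
#' @return A list with `records` (a long-format tibble of trial records)
#'   and `truth` (all drawn effects: `genotype_effects`, `harvest_effects`,
#'   `regime_effects`, `lambdas`, `genotype_scores`, `env_scores`).
#' @export
#' @examples
#' sim <- generate_met(simulation_spec(n_genotypes = 6, seed = 42))
#' head(sim$records)
generate_met <- function(spec, trait = "TDW") {
  stopifnot(inherits(spec, "simulation_spec"))
  with_rng(spec$seed, {
    n <- spec$n_genotypes; m <- spec$n_harvests; r <- spec$n_replicates
    genotypes <- sprintf("g%03d", seq_len(n))
    g <- draw_centered(n, sqrt(spec$sigma2_g))
    h <- draw_centered(m, spec$env_effect_sd)
    t_eff <- if (length(spec$regimes) > 1) {
      draw_centered(length(spec$regimes), spec$env_effect_sd)
    } else rep(0, length(spec$regimes))
    names(t_eff) <- spec$regimes
    inter <- draw_interaction(n, m, spec$interaction_rank, spec$interaction_sd)

    grid <- tidyr::expand_grid(
      genotype = genotypes,
      regime = spec$regimes,
      harvest = seq_len(m),
      replicate = seq_len(r)
    )
    gi <- match(grid$genotype, genotypes)
    hk <- grid$harvest
    mu <- spec$grand_mean + g[gi] + t_eff[grid$regime] + h[hk] +
      inter$matrix[cbind(gi, hk)]
    eps <- if (spec$sigma2_e > 0) stats::rnorm(nrow(grid), 0, sqrt(spec$sigma2_e)) else 0
    records <- tibble::tibble(
      genotype = grid$genotype, regime = grid$regime,
      harvest = as.integer(grid$harvest), replicate = as.integer(grid$replicate),
      trait = trait, value = mu + eps
    )
    list(
      records = records,
      truth = list(
        genotypes = genotypes,
        genotype_effects = stats::setNames(g, genotypes),
        harvest_effects = h,
        regime_effects = t_eff,
        lambdas = inter$lambdas,
        genotype_scores = inter$gscores,
        env_scores = inter$escores,
        interaction = inter$matrix,
        grand_mean = spec$grand_mean
      )
    )
  })
}

#' Generate a paired wet/stress trial with planted tolerant genotypes
#'
#' Emulates a drought-screening trial: wet-season yields are drawn as in
#' [generate_met()], and each stress regime's expected yield is the wet
#' expectation scaled by a regime multiplier. A seeded random fraction of
#' genotypes is "tolerant" and receives an attenuated penalty (their
#' multiplier is pulled toward 1), so index-based screening can be checked
#' against the planted truth.
#'
#' @param spec A [simulation_spec()]; its `regimes` field is ignored, the
#'   regimes simulated are `wet` plus the names of
#'   `stress_yield_multiplier`. The default uses a unit genotypic variance
#'   so that tolerance, not constitutive yield potential, is the dominant
#'   signal the screening indices must recover.
#' @param stress_yield_multiplier Named fractions in (0, 1]: expected stress
#'   yield as a share of the wet expectation, per stress regime.
#' @param tolerance_fraction Fraction of genotypes planted as tolerant.
#' @param tolerance_attenuation How much of the stress penalty tolerant
#'   genotypes escape, in \[0, 1\]: their multiplier becomes
#'   `m + (1 - m) * tolerance_attenuation`.
#' @return A list with `records` (wet + stress regimes, trait TDW),
#'   `tolerant` (character vector of planted tolerant genotype ids) and
#'   `truth` from the wet draw.
#' @export
generate_paired_stress_trial <- function(spec = simulation_spec(sigma2_g = 1),
                                         stress_yield_multiplier = c(MWS = 0.45, SWS = 0.30),
                                         tolerance_fraction = 0.2,
                                         tolerance_attenuation = 0.9) {
  stopifnot(inherits(spec, "simulation_spec"))
  mult <- stress_yield_multiplier
  if (is.null(names(mult)) || !all(names(mult) %in% c("MWS", "SWS"))) {
    abort("stress_yield_multiplier must be named with stress regimes MWS/SWS")
  }
  if (any(mult <= 0) || any(mult > 1)) {
    abort("stress yield multipliers must lie in (0, 1]")
  }
  if (tolerance_fraction < 0 || tolerance_fraction > 1) {
    abort("tolerance_fraction must lie in [0, 1]")
  }
  if (tolerance_attenuation < 0 || tolerance_attenuation > 1) {
    abort("tolerance_attenuation must lie in [0, 1]")
  }
  wet_spec <- spec
  wet_spec$regimes <- "wet"
  sim <- generate_met(wet_spec)
  truth <- sim$truth
  n <- spec$n_genotypes

  with_rng(spec$seed + 1L, {
    n_tol <- ceiling(tolerance_fraction * n)
    tolerant <- truth$genotypes[sample.int(n)][seq_len(n_tol)]
    if (n_tol == 0) tolerant <- character(0)

    expect_wet <- spec$grand_mean + truth$genotype_effects  # per-genotype wet expectation
    stress <- purrr::map(names(mult), function(regime) {
      m_base <- rep(mult[[regime]], n)
      m_base[truth$genotypes %in% tolerant] <-
        mult[[regime]] + (1 - mult[[regime]]) * tolerance_attenuation
      grid <- tidyr::expand_grid(genotype = truth$genotypes,
                                 harvest = seq_len(spec$n_harvests),
                                 replicate = seq_len(spec$n_replicates))
      gi <- match(grid$genotype, truth$genotypes)
      mu <- expect_wet[gi] * m_base[gi] +
        truth$harvest_effects[grid$harvest] * mult[[regime]]
      eps <- if (spec$sigma2_e > 0) stats::rnorm(nrow(grid), 0, sqrt(spec$sigma2_e)) else 0
      tibble::tibble(genotype = grid$genotype, regime = regime,
                     harvest = as.integer(grid$harvest),
                     replicate = as.integer(grid$replicate),
                     trait = "TDW", value = mu + eps)
    })
    list(
      records = dplyr::bind_rows(sim$records, stress),
      tolerant = sort(tolerant),
      truth = truth
    )
  })
}

#' Define feed-quality trait distributions
#'
#' Trait means and standard deviations for the seven forage feed-quality
#' traits, and the target correlation between crude protein (CP) and each
#' fiber fraction (NDF, ADF, ADL) — negative by default, since fiber and
#' protein content move in opposite directions in forage grasses. Defaults
#' follow typical wet-season Napier grass values (fiber and organic matter
#' in % DM, CP and IVOMD in % DM, Me in MJ/kg DM).
#'
#' @param means,sds Named numeric vectors over
#'   `NDF, ADF, ADL, OM, CP, IVOMD, Me`.
#' @param cp_fiber_cor Named target correlations of CP with `NDF`, `ADF`,
#'   `ADL`; each must lie in \[-1, 1\] and the implied 7x7 correlation
#'   matrix must be positive semi-definite.
#' @return A `feed_quality_spec` object.
#' @export
feed_quality_spec <- function(means = c(NDF = 67.6, ADF = 41.2, ADL = 3.9,
                                        OM = 82.7, CP = 12.1, IVOMD = 55.2,
                                        Me = 7.65),
                              sds = c(NDF = 3.3, ADF = 3.0, ADL = 1.1,
                                      OM = 1.3, CP = 2.4, IVOMD = 2.5,
                                      Me = 0.33),
                              cp_fiber_cor = c(NDF = -0.6, ADF = -0.55,
                                               ADL = -0.4)) {
  traits <- c("NDF", "ADF", "ADL", "OM", "CP", "IVOMD", "Me")
  if (!all(traits %in% names(means)) || !all(traits %in% names(sds))) {
    abort("means and sds must name all seven feed-quality traits")
  }
  if (any(sds < 0)) abort("trait standard deviations must be non-negative")
  fibers <- c("NDF", "ADF", "ADL")
  if (!all(fibers %in% names(cp_fiber_cor))) {
    abort("cp_fiber_cor must name NDF, ADF and ADL")
  }
  if (any(abs(cp_fiber_cor) > 1)) {
    abort("correlation targets must lie in [-1, 1]")
  }
  R <- diag(7)
  dimnames(R) <- list(traits, traits)
  for (f in fibers) {
    R["CP", f] <- R[f, "CP"] <- cp_fiber_cor[[f]]
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("implied trait correlation matrix is not positive semi-definite")
  }
  structure(list(means = means[traits], sds = sds[traits], correlation = R),
            class = "feed_quality_spec")
}

#' Generate correlated per-genotype feed-quality traits
#'
#' Draws one trait vector per genotype from the multivariate normal implied
#' by a [feed_quality_spec()], reproducing the negative fiber-protein
#' association of real forage data.
#'
#' @param fq A [feed_quality_spec()].
#' @param n_genotypes Number of genotypes.
#' @param seed Integer seed.
#' @param regime Regime label stamped on the records.
#' @return A long-format tibble of trial records (harvest 1, replicate 1).
#' @export
generate_feed_quality <- function(fq, n_genotypes, seed = 1L, regime = "wet") {
  stopifnot(inherits(fq, "feed_quality_spec"))
  if (n_genotypes < 1) abort("n_genotypes must be positive")
  with_rng(seed, {
    traits <- names(fq$means)
    ed <- eigen(fq$correlation, symmetric = TRUE)
    root <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0))) %*% t(ed$vectors)
    z <- matrix(stats::rnorm(n_genotypes * length(traits)), n_genotypes)
    x <- sweep(z %*% root, 2, fq$sds, `*`)
    x <- sweep(x, 2, fq$means, `+`)
    colnames(x) <- traits
    tibble::as_tibble(x) %>%
      dplyr::mutate(genotype = sprintf("g%03d", seq_len(n_genotypes))) %>%
      tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                          values_to = "value") %>%
      dplyr::mutate(regime = regime, harvest = 1L, replicate = 1L) %>%
      dplyr::select(dplyr::all_of(c(trial_key_cols, "value")))
  })
}
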