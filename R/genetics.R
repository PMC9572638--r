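#' Variance components from a genotype ANOVA
#'
#' Expected-mean-squares (method-of-moments) estimates: the residual mean
#' square estimates the error variance, and
#' `sigma2_g = (MS_genotype - MS_residual) / r` where `r` is the number of
#' observations behind each genotype mean. A negative genotype estimate is
#' truncated to zero and flagged. Phenotypic variance is the plot-basis sum
#' `sigma2_g + sigma2_e`.
#'
#' @param anova An ANOVA tibble containing a `G` and a `Residuals` term
#'   (e.g. from [fit_factorial_anova()]).
#' @param r Effective replication: observations per genotype.
#' @param grand_mean Trial grand mean for the trait, used by the
#'   coefficient-of-variation formulas.
#' @return A one-row tibble: `sigma2_g`, `sigma2_e`, `sigma2_p`,
#'   `grand_mean`, `r`, `truncated`.
#' @export
estimate_components <- function(anova, r, grand_mean = NA_real_) {
  if (r < 1) abort("replication count r must be >= 1")
  need <- c("G", "Residuals")
  if (!all(need %in% anova$term)) {
    abort("anova table must contain 'G' and 'Residuals' terms")
  }
  ms_g <- anova$meansq[anova$term == "G"]
  ms_e <- anova$meansq[anova$term == "Residuals"]
  raw <- (ms_g - ms_e) / r
  tibble::tibble(
    sigma2_g = max(0, raw),
    sigma2_e = ms_e,
    sigma2_p = max(0, raw) + ms_e,
    grand_mean = grand_mean,
    r = r,
    truncated = raw < 0
  )
}

#' Genotypic coefficient of variation, percent
#'
#' `100 * sqrt(sigma2_g) / grand_mean`.
#'
#' @param vc A variance-component row from [estimate_components()].
#' @return GCV in percent.
#' @export
gcv <- function(vc) {
  if (is.na(vc$grand_mean) || vc$grand_mean <= 0) {
    abort("GCV needs a positive grand mean")
  }
  100 * sqrt(vc$sigma2_g) / vc$grand_mean
}

#' Phenotypic coefficient of variation, percent
#'
#' `100 * sqrt(sigma2_p) / grand_mean`, with
#' `sigma2_p = sigma2_g + sigma2_e`. Always at least the GCV.
#'
#' @inheritParams gcv
#' @return PCV in percent.
#' @export
pcv <- function(vc) {
  if (is.na(vc$grand_mean) || vc$grand_mean <= 0) {
    abort("PCV needs a positive grand mean")
  }
  100 * sqrt(vc$sigma2_p) / vc$grand_mean
}

#' Broad-sense heritability, percent
#'
#' The genotypic share of plot-basis phenotypic variance,
#' `100 * sigma2_g / (sigma2_g + sigma2_e)`. Undefined (returned as `NA`)
#' when both components are zero.
#'
#' @inheritParams gcv
#' @return Heritability in percent, in \[0, 100\].
#' @export
heritability <- function(vc) {
  # guard against pure floating-point residue from degenerate (constant) data
  floor_p <- 1e-14 * max(1, vc$grand_mean^2, na.rm = TRUE)
  if (vc$sigma2_p <= floor_p) return(NA_real_)
  100 * vc$sigma2_g / (vc$sigma2_g + vc$sigma2_e)
}

#' Per-trait genetic variation summary for one regime
#'
#' Subsets one water regime, fits an additive genotype + harvest ANOVA
#' (one-way in genotype when only a single harvest is present), and reports
#' the observed mean and range together with PCV, GCV and broad-sense
#' heritability. Harvest-to-harvest shifts are removed by the additive
#' harvest term; genotype-by-harvest interaction is pooled into the
#' residual, matching the plot-basis definition of the coefficients.
#'
#' @param records Long-format trial records.
#' @param trait Trait to summarize.
#' @param regime Regime to subset (`wet`, `MWS` or `SWS`).
#' @return A one-row tibble: `trait`, `regime`, `mean`, `min`, `max`,
#'   `pcv`, `gcv`, `h2`, `sigma2_g`, `sigma2_e`, `truncated`.
#' @export
#' @examples
#' sim <- generate_met(simulation_spec(n_genotypes = 20, seed = 3))
#' genetic_summary(sim$records, "TDW", "MWS")
genetic_summary <- function(records, trait, regime) {
  records <- validate_trial_records(records)
  dat <- dplyr::filter(records, .data$trait == .env$trait,
                       .data$regime == .env$regime)
  if (nrow(dat) == 0) {
    abort(paste0("no observations for trait ", trait, " in regime ", regime))
  }
  counts <- dplyr::count(dat, .data$genotype)
  if (dplyr::n_distinct(counts$n) != 1) {
    abort("genotypes are unequally replicated in this regime")
  }
  r <- counts$n[1]
  n_harvest <- dplyr::n_distinct(dat$harvest)
  dat <- dplyr::mutate(dat, genotype = factor(.data$genotype),
                       harvest = factor(.data$harvest))
  form <- if (n_harvest > 1) value ~ genotype + harvest else value ~ genotype
  tab <- summary(stats::aov(form, data = dat))[[1]]
  anova <- tibble::tibble(
    term = dplyr::recode(trimws(rownames(tab)), genotype = "G", harvest = "H"),
    df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`
  )
  vc <- estimate_components(anova, r = r, grand_mean = mean(dat$value))
  tibble::tibble(
    trait = trait, regime = regime,
    mean = mean(dat$value), min = min(dat$value), max = max(dat$value),
    pcv = pcv(vc), gcv = gcv(vc), h2 = heritability(vc),
    sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e, truncated = vc$truncated
  )
}
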