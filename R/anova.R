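#' Fit the balanced factorial trial ANOVA
#'
#' Fits the trial model `value = mu + G + T + H + G:T + G:H + T:H + G:T:H +
#' error` for one trait, where G is genotype, T the water-stress treatment
#' and H the harvest round. When the data contain a single regime (e.g. a
#' wet-season run) the treatment term and its interactions are dropped.
#' Only balanced designs are accepted: every factor-level combination must
#' carry the same number of observations, so the sums of squares are the
#' unique balanced-design decomposition and each term is tested against the
#' residual mean square.
#'
#' @param records Long-format trial records.
#' @param trait Trait to analyse.
#' @return A tibble with columns `term` (`G`, `T`, `H`, their interactions,
#'   `Residuals`), `df`, `sumsq`, `meansq`, `statistic`, `p.value`.
#'   `statistic`/`p.value` are `NA` where the F-test is undefined (zero
#'   residual variance or zero residual df).
#' @export
#' @examples
#' sim <- generate_met(simulation_spec(n_genotypes = 5, regimes = c("MWS", "SWS"),
#'                                     seed = 7))
#' fit_factorial_anova(sim$records, "TDW")
fit_factorial_anova <- function(records, trait) {
  records <- validate_trial_records(records)
  dat <- dplyr::filter(records, .data$trait == .env$trait)
  if (nrow(dat) == 0) abort(paste0("no observations for trait ", trait))

  n_regimes <- dplyr::n_distinct(dat$regime)
  factors <- if (n_regimes > 1) c("genotype", "regime", "harvest") else c("genotype", "harvest")
  for (f in factors) {
    if (dplyr::n_distinct(dat[[f]]) < 2) {
      abort(paste0("factor '", f, "' needs at least 2 levels"))
    }
  }
  counts <- dplyr::count(dat, dplyr::across(dplyr::all_of(factors)))
  full <- prod(vapply(factors, function(f) dplyr::n_distinct(dat[[f]]), 1L))
  if (nrow(counts) != full || dplyr::n_distinct(counts$n) != 1) {
    off <- counts[counts$n != max(counts$n), factors, drop = FALSE]
    cells <- utils::head(apply(off, 1, paste, collapse = "/"), 3)
    abort(paste0("unbalanced design: cell counts differ (e.g. ",
                 paste(cells, collapse = ", "),
                 "); this model requires equal replication in every cell"))
  }

  dat <- dplyr::mutate(dat,
                       dplyr::across(dplyr::all_of(factors), factor))
  form <- if (n_regimes > 1) value ~ genotype * regime * harvest else value ~ genotype * harvest
  fit <- stats::aov(form, data = dat)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  relabel <- c(genotype = "G", regime = "T", harvest = "H")
  pretty <- vapply(strsplit(term, ":"), function(p) {
    paste(ifelse(p %in% names(relabel), relabel[p], p), collapse = ":")
  }, character(1))
  out <- tibble::tibble(
    term = pretty,
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
    p.value = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_
  )
  # constant data: aov leaves only floating-point residue; report the
  # decomposition as exactly zero with undefined F-tests
  tss <- sum((dat$value - mean(dat$value))^2)
  if (tss <= 1e-20 * max(1, mean(dat$value)^2) * nrow(dat)) {
    out$sumsq <- 0
    out$meansq <- 0
    out$statistic <- NA_real_
    out$p.value <- NA_real_
  }
  out$statistic[!is.finite(out$statistic)] <- NA_real_
  out$p.value[!is.finite(out$p.value)] <- NA_real_
  out
}

#' Least significant difference
#'
#' The minimum difference between two group means declared significant at
#' level `alpha` under a common error variance:
#' `t(1 - alpha/2, df_error) * sqrt(2 * ms_error / n_per_mean)`.
#'
#' @param ms_error Residual mean square.
#' @param df_error Residual degrees of freedom.
#' @param n_per_mean Observations per group mean.
#' @param alpha Significance level (default 0.05).
#' @return The LSD, in trait units.
#' @export
lsd_value <- function(ms_error, df_error, n_per_mean, alpha = 0.05) {
  if (ms_error < 0) abort("ms_error must be non-negative")
  if (df_error < 1 || n_per_mean < 1) abort("df_error and n_per_mean must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie strictly in (0, 1)")
  stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n_per_mean)
}

# letters after "z" continue "aa", "ab", ... (rarely needed in practice)
letter_symbols <- function(k) {
  if (k <= 26) return(letters[seq_len(k)])
  c(letters, c(t(outer(letters, letters, paste0))))[seq_len(k)]
}

#' LSD letter display for group means
#'
#' Assigns significance-group letters by the insert-and-absorb rule on
#' means sorted descending: two groups share a letter exactly when their
#' means differ by at most the LSD.
#'
#' @param means Named numeric vector of group means.
#' @param lsd The least significant difference, from [lsd_value()].
#' @return A tibble with `group`, `mean`, `letters`, sorted by descending
#'   mean.
#' @export
#' @examples
#' letter_display(c(a1 = 10, a2 = 9.8, a3 = 5), lsd = 0.5)
letter_display <- function(means, lsd) {
  if (length(means) == 0) abort("at least one group mean is required")
  if (lsd < 0) abort("lsd must be non-negative")
  if (is.null(names(means))) names(means) <- paste0("group", seq_along(means))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  n <- length(m)
  # maximal runs of sorted means whose range is <= LSD; each run is one letter
  ends <- vapply(seq_len(n), function(i) {
    max(which(m[i] - m <= lsd + 1e-12))
  }, integer(1))
  keep <- which(ends > dplyr::lag(ends, default = 0L))
  runs <- lapply(keep, function(i) seq(i, ends[i]))
  sym <- letter_symbols(length(runs))
  lab <- vapply(seq_len(n), function(i) {
    paste(sym[vapply(runs, function(r) i %in% r, logical(1))], collapse = "")
  }, character(1))
  tibble::tibble(group = names(m), mean = unname(m), letters = lab)
}

#' Coefficient of variation, percent
#'
#' `100 * sqrt(ms_error) / grand_mean`, the residual coefficient of
#' variation reported alongside trial ANOVA tables.
#'
#' @param ms_error Residual mean square.
#' @param grand_mean Trial grand mean (must be nonzero).
#' @return CV in percent.
#' @export
cv_percent <- function(ms_error, grand_mean) {
  if (ms_error < 0) abort("ms_error must be non-negative")
  if (grand_mean == 0) abort("grand mean of zero: CV undefined")
  100 * sqrt(ms_error) / abs(grand_mean)
}

#' Bartlett homogeneity-of-variance check
#'
#' Bartlett's chi-squared test that the groups share a common variance,
#' used as the pre-analysis homogeneity screen on trial data.
#'
#' @param groups A list of numeric vectors, one per group.
#' @return A tibble with `statistic`, `df`, `p.value`.
#' @export
bartlett_check <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("at least 2 groups are required")
  }
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2)) abort("every group needs at least 2 values")
  vars <- vapply(groups, stats::var, numeric(1))
  if (any(vars == 0)) {
    abort("a group has zero variance; Bartlett's statistic is undefined (log of zero variance)")
  }
  bt <- stats::bartlett.test(groups)
  tibble::tibble(statistic = unname(bt$statistic),
                 df = unname(bt$parameter),
                 p.value = bt$p.value)
}
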