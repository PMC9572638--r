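#' Genotype-by-environment cell mean matrix
#'
#' Averages a long-format trial down to one mean per genotype and harvest
#' round (the environments of the stability analysis) for a single trait
#' and regime. All cells must be filled.
#'
#' @param records Long-format trial records.
#' @param trait Yield trait, default `TDW`.
#' @param regime Regime to subset; `NULL` uses all records as given.
#' @return A `cell_means` object: the mean matrix plus the per-cell
#'   replication count.
#' @export
cell_means <- function(records, trait = "TDW", regime = NULL) {
  records <- validate_trial_records(records)
  dat <- dplyr::filter(records, .data$trait == .env$trait)
  if (!is.null(regime)) dat <- dplyr::filter(dat, .data$regime == .env$regime)
  if (nrow(dat) == 0) abort("no observations selected")
  counts <- dplyr::count(dat, .data$genotype, .data$harvest)
  if (dplyr::n_distinct(counts$n) != 1) {
    abort("unequal replication across genotype-by-harvest cells")
  }
  wide <- dat %>%
    dplyr::summarise(value = mean(.data$value),
                     .by = c("genotype", "harvest")) %>%
    tidyr::pivot_wider(names_from = "harvest", values_from = "value")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$genotype
  as_cell_means(mat, replication = counts$n[1])
}

#' Construct a cell mean matrix directly
#'
#' @param means Numeric genotype x environment matrix with no missing
#'   cells; at least 3 rows and 3 columns (two interaction axes need
#'   `min(n, m) - 1 >= 2`).
#' @param replication Observations behind each cell mean.
#' @return A `cell_means` object.
#' @export
as_cell_means <- function(means, replication = 1) {
  means <- as.matrix(means)
  if (any(!is.finite(means))) {
    abort("cell mean matrix has missing cells; the analysis requires a complete table")
  }
  if (nrow(means) < 3 || ncol(means) < 3) {
    abort("need at least 3 genotypes and 3 environments")
  }
  if (replication < 1) abort("replication must be >= 1")
  if (is.null(rownames(means))) rownames(means) <- paste0("g", seq_len(nrow(means)))
  if (is.null(colnames(means))) colnames(means) <- paste0("e", seq_len(ncol(means)))
  structure(list(means = means, replication = replication), class = "cell_means")
}

#' Fit the AMMI model
#'
#' Additive main effects and multiplicative interaction: the cell mean
#' table is decomposed as `Y_ij = mu + g_i + e_j + sum_k lambda_k *
#' alpha_ik * gamma_jk + resid_ij`, where `mu` is the grand mean, `g` and
#' `e` are the row and column deviations (each summing to zero), and the
#' multiplicative terms come from the singular value decomposition of the
#' doubly-centered interaction residual. `lambda_k` is the k-th singular
#' value and `alpha`/`gamma` are the orthonormal genotype and environment
#' scores of interaction principal component (IPC) axis k.
#'
#' @param cells A [cell_means()] object.
#' @param n_axes Number of IPC axes to retain (default 2); at most
#'   `min(n, m) - 1`.
#' @return An `ammi_fit` object with elements `mu`, `g`, `e`, `lambdas`
#'   (all axes, descending), `gscores`, `escores` (orthonormal, all axes),
#'   `interaction` (the doubly-centered matrix), `residual` (after the
#'   retained axes), `n_axes`, `replication` and `ss` (sum-of-squares
#'   partition on the plot basis).
#' @export
#' @examples
#' sim <- generate_met(simulation_spec(n_genotypes = 8, seed = 11))
#' fit <- fit_ammi(cell_means(sim$records, regime = "MWS"))
#' glance(fit)
fit_ammi <- function(cells, n_axes = 2) {
  stopifnot(inherits(cells, "cell_means"))
  y <- cells$means
  n <- nrow(y); m <- ncol(y)
  kmax <- min(n, m) - 1
  if (n_axes < 1 || n_axes > kmax) {
    abort(paste0("n_axes must be between 1 and min(n, m) - 1 = ", kmax))
  }
  mu <- mean(y)
  g <- rowMeans(y) - mu
  e <- colMeans(y) - mu
  z <- y - mu - outer(g, rep(1, m)) - outer(rep(1, n), e)
  sv <- svd(z)
  # the doubly-centered matrix has rank at most min(n, m) - 1
  lambdas <- sv$d[seq_len(kmax)]
  gsc <- sv$u[, seq_len(kmax), drop = FALSE]
  esc <- sv$v[, seq_len(kmax), drop = FALSE]
  rownames(gsc) <- rownames(y); rownames(esc) <- colnames(y)
  recon <- gsc[, seq_len(n_axes), drop = FALSE] %*%
    diag(lambdas[seq_len(n_axes)], n_axes) %*%
    t(esc[, seq_len(n_axes), drop = FALSE])
  r <- cells$replication
  ss <- list(
    G = m * r * sum(g^2),
    E = n * r * sum(e^2),
    GEI = r * sum(z^2),
    IPC = r * lambdas^2,
    residual = r * sum((z - recon)^2)
  )
  structure(
    list(mu = mu, g = g, e = e, lambdas = lambdas,
         gscores = gsc, escores = esc,
         interaction = z, residual = z - recon,
         n_axes = n_axes, replication = r, ss = ss,
         genotypes = rownames(y), environments = colnames(y)),
    class = "ammi_fit"
  )
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("AMMI fit:", length(x$g), "genotypes x", length(x$e), "environments,",
      x$n_axes, "IPC axes retained\n")
  share <- 100 * cumsum(x$lambdas^2) / sum(x$lambdas^2)
  cat("GEI explained by first", x$n_axes, "axes:",
      sprintf("%.1f%%", share[x$n_axes]), "\n")
  invisible(x)
}

#' AMMI analysis-of-variance partition
#'
#' Partitions the total sum of squares into genotype (G), environment (E)
#' and interaction (GEI), then splits GEI over the IPC axes, with Gollob
#' degrees of freedom `n + m - 1 - 2k` per axis. Sums of squares are on
#' the plot basis (cell means times replication). F-tests against a
#' plot-level error mean square are reported when one is supplied.
#'
#' @param fit An [fit_ammi()] object.
#' @param ms_error Optional plot-level residual mean square.
#' @param df_error Residual degrees of freedom for `ms_error`.
#' @return A tibble with `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value`.
#' @export
ammi_anova <- function(fit, ms_error = NULL, df_error = NULL) {
  stopifnot(inherits(fit, "ammi_fit"))
  n <- length(fit$g); m <- length(fit$e)
  k <- seq_along(fit$lambdas)
  ipc_keep <- seq_len(fit$n_axes)
  df_ipc <- n + m - 1 - 2 * ipc_keep
  df_gei <- (n - 1) * (m - 1)
  terms <- tibble::tibble(
    term = c("G", "E", "GEI", paste0("IPC", ipc_keep), "GEI residual"),
    df = c(n - 1, m - 1, df_gei, df_ipc, df_gei - sum(df_ipc)),
    sumsq = c(fit$ss$G, fit$ss$E, fit$ss$GEI, fit$ss$IPC[ipc_keep],
              fit$ss$GEI - sum(fit$ss$IPC[ipc_keep]))
  )
  terms$meansq <- ifelse(terms$df > 0, terms$sumsq / terms$df, NA_real_)
  if (!is.null(ms_error)) {
    if (is.null(df_error)) abort("df_error must accompany ms_error")
    terms$statistic <- terms$meansq / ms_error
    terms$p.value <- stats::pf(terms$statistic, terms$df, df_error,
                               lower.tail = FALSE)
  } else {
    terms$statistic <- NA_real_
    terms$p.value <- NA_real_
  }
  terms
}

#' AMMI stability value
#'
#' Distance of a genotype from the origin of the weighted IPC1-IPC2 score
#' plane: `ASV = sqrt(((ss_ipc1 / ss_ipc2) * ipc1)^2 + ipc2^2)`. The first
#' axis is weighted up by the ratio of interaction sums of squares it
#' explains. Smaller ASV means a more stable genotype.
#'
#' @param ipc1,ipc2 Genotype scores on the first two IPC axes (symmetric
#'   `alpha * sqrt(lambda)` scaling); vectorized.
#' @param ss_ipc1,ss_ipc2 Interaction sums of squares of the two axes
#'   (`ss_ipc2` must be positive).
#' @param weight Use the sum-of-squares ratio (`"ss"`, the published
#'   convention, equal to the mean-square ratio times the df ratio) or the
#'   mean-square ratio (`"ms"`) with the supplied degrees of freedom.
#' @param df_ipc1,df_ipc2 Axis degrees of freedom, only used for
#'   `weight = "ms"`.
#' @return ASV values.
#' @export
asv <- function(ipc1, ipc2, ss_ipc1, ss_ipc2, weight = c("ss", "ms"),
                df_ipc1 = NULL, df_ipc2 = NULL) {
  weight <- match.arg(weight)
  if (ss_ipc2 <= 0) abort("second IPC axis is degenerate (zero sum of squares)")
  ratio <- if (weight == "ss") ss_ipc1 / ss_ipc2 else {
    if (is.null(df_ipc1) || is.null(df_ipc2)) {
      abort("mean-square weighting needs df_ipc1 and df_ipc2")
    }
    (ss_ipc1 / df_ipc1) / (ss_ipc2 / df_ipc2)
  }
  sqrt((ratio * ipc1)^2 + ipc2^2)
}

#' Yield and stability ranking of genotypes
#'
#' Ranks genotypes on mean yield across environments (`RY`, rank 1 = top
#' yielder) and on ASV (`RASV`, rank 1 = most stable), and combines them as
#' the yield stability index `YSI = RASV + RY`. Low YSI marks genotypes
#' that are both high-yielding and stable. Ties receive average ranks.
#'
#' @param fit An [fit_ammi()] object with at least 2 retained axes.
#' @return A `stability_table` tibble: `genotype`, `mean_yield`, `RY`,
#'   `IPC1`, `IPC2`, `ASV`, `RASV`, `YSI`, sorted by YSI.
#' @export
stability_ranking <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (fit$n_axes < 2 || length(fit$lambdas) < 2) {
    abort("stability ranking needs two IPC axes")
  }
  s1 <- unname(fit$gscores[, 1]) * sqrt(fit$lambdas[1])
  s2 <- unname(fit$gscores[, 2]) * sqrt(fit$lambdas[2])
  mean_yield <- unname(fit$mu + fit$g)
  out <- tibble::tibble(
    genotype = fit$genotypes,
    mean_yield = unname(mean_yield),
    RY = rank(-mean_yield, ties.method = "average"),
    IPC1 = unname(s1),
    IPC2 = unname(s2),
    ASV = asv(s1, s2, fit$ss$IPC[1], fit$ss$IPC[2])
  )
  out$RASV <- rank(out$ASV, ties.method = "average")
  out$YSI <- out$RASV + out$RY
  out <- dplyr::arrange(out, .data$YSI)
  class(out) <- c("stability_table", class(out))
  out
}

#' Biplot coordinates for an AMMI fit
#'
#' Symmetric-scaled (`score * sqrt(lambda)`) genotype and environment
#' coordinates on the first two IPC axes.
#'
#' @param fit An [fit_ammi()] object.
#' @return A tibble with `label`, `type` (genotype/environment), `IPC1`,
#'   `IPC2`.
#' @export
ammi_biplot_scores <- function(fit) {
  stopifnot(inherits(fit, "ammi_fit"))
  if (length(fit$lambdas) < 2) abort("biplot needs two IPC axes")
  sqrt_l <- sqrt(fit$lambdas[1:2])
  dplyr::bind_rows(
    tibble::tibble(label = fit$genotypes, type = "genotype",
                   IPC1 = fit$gscores[, 1] * sqrt_l[1],
                   IPC2 = fit$gscores[, 2] * sqrt_l[2]),
    tibble::tibble(label = fit$environments, type = "environment",
                   IPC1 = fit$escores[, 1] * sqrt_l[1],
                   IPC2 = fit$escores[, 2] * sqrt_l[2])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the AMMI sum-of-squares partition
#'
#' @param x An `ammi_fit`.
#' @param ... Passed to [ammi_anova()] (`ms_error`, `df_error`).
#' @return The [ammi_anova()] tibble.
#' @export
tidy.ammi_fit <- function(x, ...) ammi_anova(x, ...)

#' One-row summary of an AMMI fit
#'
#' @param x An `ammi_fit`.
#' @param ... Unused.
#' @return A tibble with the grand mean, design size, and the shares of
#'   total SS taken by G, E and GEI plus the GEI share of the retained
#'   axes.
#' @export
glance.ammi_fit <- function(x, ...) {
  total <- x$ss$G + x$ss$E + x$ss$GEI
  gei_share <- if (x$ss$GEI > 0) {
    sum(x$ss$IPC[seq_len(x$n_axes)]) / x$ss$GEI
  } else NA_real_
  tibble::tibble(
    grand_mean = x$mu,
    n_genotypes = length(x$g),
    n_environments = length(x$e),
    n_axes = x$n_axes,
    prop_ss_G = x$ss$G / total,
    prop_ss_E = x$ss$E / total,
    prop_ss_GEI = x$ss$GEI / total,
    prop_gei_retained = gei_share
  )
}
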