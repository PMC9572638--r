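#' Annual total dry weight per genotype
#'
#' Accumulates each genotype's annual yield by summing its per-harvest mean
#' TDW over the wet-season harvests and over the harvests of the named dry
#' regime, then applying a unit scale factor (e.g. a per-plant to
#' per-hectare conversion from planting density).
#'
#' @param records Long-format trial records with wet and dry TDW.
#' @param dry_regime The dry-season regime to accumulate (`MWS` or `SWS`).
#' @param scale Multiplicative unit conversion, default 1.
#' @param trait Yield trait, default `TDW`.
#' @return A tibble: `genotype`, `annual_tdw`.
#' @export
annual_tdw <- function(records, dry_regime, scale = 1, trait = "TDW") {
  records <- validate_trial_records(records)
  dat <- dplyr::filter(records, .data$trait == .env$trait,
                       .data$regime %in% c("wet", .env$dry_regime))
  if (nrow(dat) == 0 || !all(c("wet", dry_regime) %in% dat$regime)) {
    abort(paste0("need ", trait, " records in both wet and ", dry_regime))
  }
  dat %>%
    dplyr::summarise(value = mean(.data$value),
                     .by = c("genotype", "regime", "harvest")) %>%
    dplyr::summarise(annual_tdw = sum(.data$value) * scale,
                     .by = "genotype")
}

#' Annual crude-protein yield
#'
#' `CPY = annual_cp * annual_tdw * multiplier`: the annual crude-protein
#' content accumulation times the annual dry-matter yield, with an output
#' unit multiplier (the published tables mix t/ha and kg/ha scales, so the
#' unit is configuration, not inference).
#'
#' @param annual_cp Accumulated annual CP content; vectorized.
#' @param annual_tdw Annual dry-matter yield; vectorized.
#' @param multiplier Output unit multiplier, default 1.
#' @return CPY values.
#' @export
cpy <- function(annual_cp, annual_tdw, multiplier = 1) {
  if (any(annual_cp < 0) || any(annual_tdw < 0)) {
    abort("annual CP and TDW must be non-negative")
  }
  annual_cp * annual_tdw * multiplier
}

#' Annual yield and protein table per genotype
#'
#' Combines [annual_tdw()] with the same accumulation rule applied to crude
#' protein content and the CPY product.
#'
#' @inheritParams annual_tdw
#' @param cp_multiplier Output unit multiplier for CPY.
#' @return A tibble: `genotype`, `annual_tdw`, `annual_cp`, `cpy`. The CP
#'   columns are `NA` when the records carry no CP trait.
#' @export
annual_yield_table <- function(records, dry_regime, scale = 1,
                               cp_multiplier = 1) {
  out <- annual_tdw(records, dry_regime, scale = scale)
  if ("CP" %in% records$trait) {
    cp <- records %>%
      dplyr::filter(.data$trait == "CP",
                    .data$regime %in% c("wet", .env$dry_regime)) %>%
      dplyr::summarise(value = mean(.data$value),
                       .by = c("genotype", "regime", "harvest")) %>%
      dplyr::summarise(annual_cp = sum(.data$value), .by = "genotype")
    out <- dplyr::left_join(out, cp, by = "genotype")
    out$cpy <- cpy(out$annual_cp, out$annual_tdw, cp_multiplier)
  } else {
    out$annual_cp <- NA_real_
    out$cpy <- NA_real_
  }
  out
}

#' Summary statistics of the published annual-yield table
#'
#' Mean, minimum and maximum of the annual TDW column for the requested
#' stress regime(s) of the packaged 84-genotype table.
#'
#' @param table The tibble from [load_table5()].
#' @param regime `"MWS"`, `"SWS"` or both.
#' @return A tibble with one row per regime: `regime`, `mean`, `min`,
#'   `max`.
#' @export
#' @examples
#' table5_summary(load_table5())
table5_summary <- function(table, regime = c("MWS", "SWS")) {
  regime <- match.arg(regime, several.ok = TRUE)
  purrr::map_dfr(regime, function(rg) {
    col <- paste0(tolower(rg), "_tdw")
    if (!col %in% names(table)) abort(paste0("table has no column ", col))
    v <- table[[col]]
    tibble::tibble(regime = rg, mean = mean(v), min = min(v), max = max(v))
  })
}

#' Pearson correlation matrix with pairwise p-values
#'
#' Correlations between traits across genotypes, with two-sided p-values
#' from the t transform on `n - 2` degrees of freedom. Entries involving a
#' zero-variance trait are reported as `NA` with a warning; no
#' multiple-testing correction is applied.
#'
#' @param trait_table A data frame of numeric trait columns (one row per
#'   genotype).
#' @return A `trait_correlations` object with elements `r`, `p` (symmetric
#'   matrices) and `n`; [tidy()] returns the lower triangle as a long
#'   tibble.
#' @export
pearson_matrix <- function(trait_table) {
  x <- as.matrix(dplyr::select(tibble::as_tibble(trait_table),
                               dplyr::where(is.numeric)))
  n <- nrow(x)
  if (n < 3) abort("at least 3 genotypes are required")
  if (ncol(x) < 2) abort("at least 2 numeric traits are required")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("zero-variance trait(s): ",
                paste(colnames(x)[sds == 0], collapse = ", "),
                "; correlations reported as NA"))
  }
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Pearson correlations over", x$n, "genotypes\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Tidy a trait correlation matrix
#'
#' @param x A `trait_correlations` object.
#' @param ... Unused.
#' @return A long tibble of the distinct trait pairs: `trait1`, `trait2`,
#'   `r`, `p.value`.
#' @export
tidy.trait_correlations <- function(x, ...) {
  traits <- colnames(x$r)
  idx <- which(lower.tri(x$r), arr.ind = TRUE)
  tibble::tibble(trait1 = traits[idx[, 2]], trait2 = traits[idx[, 1]],
                 r = x$r[idx], p.value = x$p[idx])
}

#' Principal component analysis on the trait correlation matrix
#'
#' Eigendecomposition of the Pearson correlation matrix of the traits
#' (equivalently, PCA of the z-scored trait table). Constant traits are
#' dropped with a warning. Variance-explained fractions sum to one and the
#' loadings are orthonormal.
#'
#' @param trait_table A data frame of numeric trait columns, one row per
#'   genotype.
#' @param ids Optional genotype labels for the score rows.
#' @return A `trait_pca` object: `scores` (tibble, one row per genotype),
#'   `loadings` (orthonormal matrix, traits x components),
#'   `var_explained`, `sdev`.
#' @export
correlation_pca <- function(trait_table, ids = NULL) {
  x <- as.matrix(dplyr::select(tibble::as_tibble(trait_table),
                               dplyr::where(is.numeric)))
  if (nrow(x) < 3) abort("at least 3 genotypes are required")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("dropping constant trait(s): ",
                paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2) abort("at least 2 traits with nonzero variance are required")
  z <- scale(x)
  ed <- eigen(stats::cor(x), symmetric = TRUE)
  vals <- pmax(ed$values, 0)
  load <- ed$vectors
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  scores <- z %*% load
  scr <- tibble::as_tibble(scores)
  scr <- dplyr::mutate(scr,
                       id = if (is.null(ids)) paste0("g", seq_len(nrow(z))) else ids,
                       .before = 1)
  structure(list(scores = scr, loadings = load,
                 var_explained = vals / sum(vals), sdev = sqrt(vals)),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("PCA on the trait correlation matrix:",
      nrow(x$loadings), "traits,", nrow(x$scores), "genotypes\n")
  ve <- round(100 * x$var_explained, 1)
  cat("variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

#' Glance at a trait PCA
#'
#' @param x A `trait_pca` object.
#' @param ... Unused.
#' @return A one-row tibble with the shares of the first two components
#'   and their sum.
#' @export
glance.trait_pca <- function(x, ...) {
  ve <- x$var_explained
  tibble::tibble(
    n_components = length(ve),
    prop_pc1 = ve[1],
    prop_pc2 = if (length(ve) > 1) ve[2] else NA_real_,
    prop_first_two = sum(ve[seq_len(min(2, length(ve)))])
  )
}
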