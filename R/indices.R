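#' Water-use efficiency
#'
#' Dry weight produced per unit of irrigation water applied.
#'
#' @param total_dry_weight Dry weight per plant (mass units); vectorized.
#' @param irrigation_volume Irrigation water applied per plant (volume
#'   units); must be positive.
#' @return WUE, in mass/volume units.
#' @export
wue <- function(total_dry_weight, irrigation_volume) {
  if (any(irrigation_volume <= 0)) abort("irrigation volume must be positive")
  if (any(total_dry_weight < 0)) abort("dry weight must be non-negative")
  total_dry_weight / irrigation_volume
}

#' Stress tolerance index
#'
#' `STI = (Yp * Ys) / Xp^2`: the product of a genotype's yield under
#' optimal (`Yp`) and stress (`Ys`) conditions, normalized by the squared
#' grand mean of optimal-condition yields (`Xp`). Dimensionless; high STI
#' means high yield under both conditions.
#'
#' @param Yp Yield under optimal (wet) conditions; vectorized.
#' @param Ys Yield under stress; vectorized.
#' @param Xp Grand mean yield under optimal conditions (positive scalar).
#' @return STI values.
#' @export
sti <- function(Yp, Ys, Xp) {
  if (length(Xp) != 1 || Xp <= 0) abort("Xp must be a single positive mean yield")
  if (any(Yp < 0) || any(Ys < 0)) abort("yields must be non-negative")
  (Yp * Ys) / Xp^2
}

#' Per-genotype drought index table
#'
#' Builds, for one stress regime, the genotype table used for tolerance
#' screening: wet-season mean TDW (`Yp`), stress mean TDW (`Ys`), the
#' wet grand mean (`Xp`), the stress tolerance index, and WUE under stress
#' from the irrigation volume applied per plant in that regime.
#'
#' @param records Long-format trial records containing wet and stress TDW.
#' @param regime Stress regime (`MWS` or `SWS`).
#' @param irrigation_volume Water applied per plant under `regime`
#'   (volume units); WUE is `Ys / irrigation_volume`.
#' @param trait Yield trait, default `TDW`.
#' @return A tibble: `genotype`, `Yp`, `Ys`, `Xp`, `STI`, `WUE`.
#' @export
drought_index_table <- function(records, regime, irrigation_volume = 1,
                                trait = "TDW") {
  records <- validate_trial_records(records)
  dat <- dplyr::filter(records, .data$trait == .env$trait,
                       .data$regime %in% c("wet", .env$regime))
  wet <- dat %>%
    dplyr::filter(.data$regime == "wet") %>%
    dplyr::summarise(Yp = mean(.data$value), .by = "genotype")
  str <- dat %>%
    dplyr::filter(.data$regime == .env$regime) %>%
    dplyr::summarise(Ys = mean(.data$value), .by = "genotype")
  if (nrow(wet) == 0 || nrow(str) == 0) {
    abort(paste0("need both wet and ", regime, " observations of ", trait))
  }
  tab <- dplyr::inner_join(wet, str, by = "genotype")
  if (nrow(tab) == 0) abort("no genotype has both wet and stress records")
  xp_mean <- mean(tab$Yp)
  dplyr::mutate(tab,
                Xp = xp_mean,
                STI = sti(.data$Yp, .data$Ys, xp_mean),
                WUE = wue(pmax(.data$Ys, 0), irrigation_volume))
}

#' Classify genotypes into drought-tolerance groups
#'
#' Hierarchical clustering of genotypes on standardized STI, WUE and
#' stress-season TDW: Manhattan (city-block) distance, average linkage,
#' tree cut at `k` groups. Groups are labelled `highly_tolerant`,
#' `moderately_tolerant`, `susceptible` by descending group-mean STI (with
#' `k` other than 3, groups are labelled `group1..k` in the same order).
#' Features are z-scored first because STI, WUE and TDW live on
#' incommensurate scales and raw city-block distance would be dominated by
#' the largest-scale trait.
#'
#' @param table An index table from [drought_index_table()] (columns `STI`,
#'   `WUE`, `Ys`).
#' @param k Number of tolerance groups, default 3.
#' @return The input tibble with a `cluster` factor column added, plus the
#'   fitted tree in attribute `"hclust"`.
#' @export
classify_tolerance <- function(table, k = 3) {
  feats <- c("STI", "WUE", "Ys")
  if (!all(feats %in% names(table))) {
    abort("table must carry STI, WUE and Ys columns")
  }
  n <- nrow(table)
  if (k > n) abort("more groups requested than genotypes available")
  x <- as.matrix(table[feats])
  if (any(!is.finite(x))) abort("index features must be finite")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) {
    warn("all genotypes identical: tolerance grouping is degenerate")
    z <- x * 0
  } else {
    z <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }
  hc <- stats::hclust(stats::dist(z, method = "manhattan"), method = "average")
  grp <- stats::cutree(hc, k = k)
  mean_sti <- tapply(table$STI, grp, mean)
  ord <- order(mean_sti, decreasing = TRUE)
  lab <- if (k == 3) c("highly_tolerant", "moderately_tolerant", "susceptible")
         else paste0("group", seq_len(k))
  relabel <- stats::setNames(lab, names(mean_sti)[ord])
  out <- dplyr::mutate(table, cluster = factor(relabel[as.character(grp)],
                                               levels = lab))
  attr(out, "hclust") <- hc
  out
}

#' Export a tolerance dendrogram as Newick text
#'
#' Serializes the tree attached by [classify_tolerance()] for inspection in
#' standard phylogenetic viewers.
#'
#' @param table A classified index table (output of [classify_tolerance()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tolerance_newick <- function(table, path) {
  hc <- attr(table, "hclust")
  if (is.null(hc)) abort("table carries no clustering; run classify_tolerance() first")
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  hc$labels <- table$genotype
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' PCA of the drought-index features
#'
#' Principal components of the correlation matrix of STI, WUE and
#' stress-season TDW across genotypes; used to display the tolerance
#' gradient (PC1 typically orders genotypes from susceptible to tolerant).
#' Zero-variance features are dropped with a warning.
#'
#' @param table An index table from [drought_index_table()].
#' @return A `trait_pca` object; see [correlation_pca()].
#' @export
tolerance_pca <- function(table) {
  feats <- c("STI", "WUE", "Ys")
  if (!all(feats %in% names(table))) {
    abort("table must carry STI, WUE and Ys columns")
  }
  if (nrow(table) < 3) abort("at least 3 genotypes are required")
  wide <- tibble::as_tibble(table[feats])
  wide <- dplyr::rename(wide, TDW = "Ys")
  correlation_pca(wide, ids = table$genotype)
}
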