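#' Run the full trial analysis pipeline
#'
#' Orchestrates every stage end-to-end: obtain trial records (from a file
#' or by simulation), factorial ANOVA over the dry-season regimes, genetic
#' variation summaries, drought-index screening with tolerance
#' classification, AMMI stability ranking per regime, and annual yield
#' accumulation. Each stage's table is written as CSV into `out_dir`
#' together with a run log (seed, config hash, package version). Given the
#' same config and seed, outputs are byte-identical across runs.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognized fields:
#'   * `input`: path to a long-format trial CSV, or
#'   * `simulation`: arguments for [simulation_spec()] plus optional
#'     `stress_yield_multiplier`, `tolerance_fraction`,
#'     `tolerance_attenuation` for [generate_paired_stress_trial()];
#'   * `regimes`: stress regimes to analyse (required);
#'   * `trait`: yield trait (default `"TDW"`);
#'   * `irrigation_volume`: named per-regime volumes for WUE (default 1);
#'   * `yield_scale`: unit factor for annual yields (default 1).
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a named list of the stage tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  if (is.null(config$regimes)) {
    abort("config validation: 'regimes' must name the stress regimes to analyse")
  }
  regimes <- intersect(config$regimes, c("MWS", "SWS"))
  if (length(regimes) == 0) abort("config validation: no stress regime among MWS, SWS")
  trait <- config$trait %||% "TDW"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  records <- stage("input", {
    if (!is.null(config$input)) {
      read_trial_table(config$input)
    } else if (!is.null(config$simulation)) {
      sim_cfg <- config$simulation
      extra <- intersect(names(sim_cfg),
                         c("stress_yield_multiplier", "tolerance_fraction",
                           "tolerance_attenuation"))
      spec <- do.call(simulation_spec,
                      sim_cfg[setdiff(names(sim_cfg), extra)])
      args <- c(list(spec = spec), sim_cfg[extra])
      if (!is.null(args$stress_yield_multiplier)) {
        args$stress_yield_multiplier <- unlist(args$stress_yield_multiplier)
      }
      do.call(generate_paired_stress_trial, args)$records
    } else {
      abort("config names neither 'input' nor 'simulation'")
    }
  })
  out <- list(records = records)

  out$anova <- stage("anova", {
    dry <- dplyr::filter(records, .data$regime %in% regimes,
                         .data$trait == .env$trait)
    fit_factorial_anova(dry, trait)
  })

  out$genetics <- stage("genetics", {
    purrr::map_dfr(intersect(unique(records$regime), c("wet", regimes)),
                   ~ genetic_summary(records, trait, .x))
  })

  vols <- config$irrigation_volume %||% stats::setNames(rep(1, length(regimes)), regimes)
  out$indices <- stage("indices", {
    purrr::map(stats::setNames(regimes, regimes), function(rg) {
      tab <- drought_index_table(records, rg,
                                 irrigation_volume = vols[[rg]] %||% 1,
                                 trait = trait)
      classify_tolerance(tab)
    })
  })

  out$stability <- stage("ammi", {
    purrr::map(stats::setNames(regimes, regimes), function(rg) {
      fit <- fit_ammi(cell_means(records, trait = trait, regime = rg))
      list(anova = ammi_anova(fit), ranking = stability_ranking(fit),
           biplot = ammi_biplot_scores(fit))
    })
  })

  out$annual <- stage("summary", {
    purrr::map_dfr(regimes, function(rg) {
      dplyr::mutate(
        annual_yield_table(records, rg, scale = config$yield_scale %||% 1),
        regime = rg, .after = "genotype")
    })
  })

  stage("write", {
    wr <- function(x, f) readr::write_csv(x, file.path(out_dir, f))
    wr(records, "records.csv")
    wr(out$anova, "anova.csv")
    wr(out$genetics, "genetics.csv")
    for (rg in regimes) {
      wr(dplyr::select(out$indices[[rg]], -dplyr::any_of("hclust")),
         paste0("indices_", rg, ".csv"))
      wr(out$stability[[rg]]$anova, paste0("ammi_anova_", rg, ".csv"))
      wr(out$stability[[rg]]$ranking, paste0("stability_", rg, ".csv"))
      wr(out$stability[[rg]]$biplot, paste0("ammi_biplot_", rg, ".csv"))
      if (requireNamespace("ape", quietly = TRUE)) {
        write_tolerance_newick(out$indices[[rg]],
                               file.path(out_dir, paste0("dendrogram_", rg, ".nwk")))
      }
    }
    wr(out$annual, "annual_yield.csv")
    log <- c(
      paste0("seed: ", config$simulation$seed %||% NA),
      paste0("config_hash: ", rlang::hash(config)),
      paste0("metstab_version: ", as.character(utils::packageVersion("metstab"))),
      paste0("r_version: ", R.version.string)
    )
    writeLines(log, file.path(out_dir, "run_log.txt"))
  })
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
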