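#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr %>%
NULL

regime_levels <- c("wet", "MWS", "SWS")

trial_key_cols <- c("genotype", "regime", "harvest", "replicate", "trait")

#' Validate a long-format trial table
#'
#' Checks the invariants every downstream stage relies on: the five key
#' columns plus `value` are present, `(genotype, regime, harvest, replicate,
#' trait)` is unique, regimes are one of `wet`, `MWS`, `SWS`, and every value
#' is finite (missing observations are absent rows, never `NA` placeholders).
#'
#' @param records A data frame of trial observations.
#' @return The input as a tibble, invisibly unchanged, for use in pipes.
#' @export
validate_trial_records <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c(trial_key_cols, "value")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_regime <- setdiff(unique(records$regime), regime_levels)
  if (length(bad_regime) > 0) {
    abort(paste0("unknown regime level(s): ", paste(bad_regime, collapse = ", "),
                 " (expected wet, MWS, SWS)"))
  }
  if (!is.numeric(records$value) || any(!is.finite(records$value))) {
    n_bad <- if (is.numeric(records$value)) sum(!is.finite(records$value)) else nrow(records)
    abort(paste0("trial values must be finite numbers; ", n_bad,
                 " value(s) are missing or non-finite"))
  }
  dup <- duplicated(records[trial_key_cols])
  if (any(dup)) {
    first <- records[which(dup)[1], trial_key_cols]
    abort(paste0("duplicate observation key: (",
                 paste(unlist(first), collapse = ", "),
                 ") appears more than once"))
  }
  records
}

#' Read a long-format trial table
#'
#' Reads delimited text with columns `genotype, regime, harvest, replicate,
#' trait, value` (one observation per row) and validates the dataset
#' invariants. Row order is preserved.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; defaults to comma.
#' @return A tibble of trial records.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("genotype,regime,harvest,replicate,trait,value",
#'              "g1,wet,1,1,TDW,4.2"), f)
#' read_trial_table(f)
read_trial_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  records <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      genotype = readr::col_character(),
      regime = readr::col_character(),
      harvest = readr::col_integer(),
      replicate = readr::col_integer(),
      trait = readr::col_character(),
      value = readr::col_character()
    )
  )
  if (!"value" %in% names(records)) abort("trial table has no 'value' column")
  v <- suppressWarnings(as.numeric(records$value))
  bad <- which(is.na(v) & !is.na(records$value))
  if (length(bad) > 0) {
    abort(paste0("malformed numeric value '", records$value[bad[1]],
                 "' at data row ", bad[1]))
  }
  records$value <- v
  validate_trial_records(records)
}

#' Write a long-format trial table
#'
#' @param records Trial records (validated before writing).
#' @param path Output path.
#' @param delim Field delimiter; defaults to comma.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(records, path, delim = ",") {
  records <- validate_trial_records(records)
  readr::write_delim(records, path, delim = delim)
  invisible(path)
}

#' Parse a published table cell with significance letters
#'
#' Agronomy tables print Fisher-LSD mean-separation groups as lowercase
#' letter suffixes on each cell (e.g. `"48.48ij"`). This splits a cell into
#' its numeric value and its letter group; leading genotype footnote markers
#' (`*`, `**`) are stripped before parsing.
#'
#' @param raw Character vector of printed cells.
#' @return A tibble with columns `raw`, `value`, `letters` (empty string when
#'   the cell carries no letters).
#' @export
#' @examples
#' parse_published_value(c("68.05a", "18.9p", "42klmn"))
parse_published_value <- function(raw) {
  if (length(raw) == 0) abort("no cells to parse")
  stripped <- trimws(gsub("\\*", "", raw))
  m <- regmatches(stripped, regexec("^([0-9]+(?:\\.[0-9]+)?)([a-z]*)$", stripped))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(paste0("cell does not begin with a decimal number: '",
                 raw[which(bad)[1]], "'"))
  }
  tibble::tibble(
    raw = raw,
    value = vapply(m, function(x) as.numeric(x[2]), numeric(1)),
    letters = vapply(m, function(x) x[3], character(1))
  )
}

#' Load the packaged 84-genotype annual-yield table
#'
#' Loads the transcription of the published annual total dry weight (TDW)
#' and crude protein yield (CPY) table for 84 Napier grass genotypes grown
#' under moderate (MWS) and severe (SWS) water stress. Cells are stored as
#' printed, with significance-letter suffixes; this parses each of the eight
#' numeric columns with [parse_published_value()] and exposes the footnote
#' markers as top-CPY flags.
#'
#' @param path Path to the fixture CSV; defaults to the copy shipped with
#'   the package.
#' @return A tibble with 84 rows and columns `genotype`, `mws_tdw`,
#'   `mws_tdw_letters`, `mws_cpy`, `mws_cpy_letters`, `sws_tdw`,
#'   `sws_tdw_letters`, `sws_cpy`, `sws_cpy_letters`, `top_cpy_mws`,
#'   `top_cpy_sws`.
#' @export
load_table5 <- function(path = system.file("extdata", "table5_annual_yield.csv",
                                           package = "metstab")) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  raw$marker[is.na(raw$marker)] <- ""
  if (nrow(raw) != 84) {
    abort(paste0("annual-yield table must have 84 genotypes, found ", nrow(raw)))
  }
  if (anyDuplicated(raw$genotype)) abort("duplicate genotype in annual-yield table")
  out <- tibble::tibble(genotype = raw$genotype)
  for (col in c("mws_tdw", "mws_cpy", "sws_tdw", "sws_cpy")) {
    parsed <- parse_published_value(raw[[col]])
    out[[col]] <- parsed$value
    out[[paste0(col, "_letters")]] <- parsed$letters
  }
  # "**" marks top CPY producers under both regimes, "*" under MWS only
  out$top_cpy_mws <- raw$marker %in% c("*", "**")
  out$top_cpy_sws <- raw$marker == "**"
  out[c("genotype",
        "mws_tdw", "mws_tdw_letters", "mws_cpy", "mws_cpy_letters",
        "sws_tdw", "sws_tdw_letters", "sws_cpy", "sws_cpy_letters",
        "top_cpy_mws", "top_cpy_sws")]
}
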