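#' Read a preferred-term to system-organ-class mapping
#'
#' Two-column delimited text (`pt`, `soc`), one primary SOC per preferred
#' term. Gzip-compressed files are accepted. Duplicate PTs are an error:
#' the MedDRA hierarchy assigns a single primary SOC per PT.
#'
#' @param path Path to a delimited text file (tab or comma separated,
#'   header row `pt`, `soc`).
#' @return A `meddra_map` object (data.table with columns `pt`, `soc`).
#' @export
read_meddra_map <- function(path) {
  .pv_assert(file.exists(path), "MedDRA map file not found: ", path)
  dt <- data.table::fread(path, colClasses = "character")
  .pv_assert(all(c("pt", "soc") %in% names(dt)),
             "MedDRA map must have columns 'pt' and 'soc'",
             class = "pv_config_error")
  dt <- dt[, .(pt, soc)]
  dup <- dt[, .N, by = .(key_ = tolower(pt))][N > 1L]
  .pv_assert(nrow(dup) == 0L,
             "MedDRA map assigns more than one SOC to: ",
             paste(head(dup$key_, 5), collapse = ", "),
             class = "pv_config_error")
  data.table::setattr(dt, "class", c("meddra_map", class(dt)))
  dt[]
}

#' Bundled synthetic PT to SOC map
#'
#' A small illustrative mapping shipped with the package for tests and
#' examples. It follows MedDRA's primary-SOC convention but is *not* the
#' licensed dictionary; real analyses should supply their own map via
#' [read_meddra_map()].
#'
#' @return A `meddra_map` object.
#' @export
default_meddra_map <- function() {
  read_meddra_map(system.file("extdata", "pt_soc_map_synthetic.tsv",
                              package = "pvsignal", mustWork = TRUE))
}

#' Read an ATC substance catalogue
#'
#' Delimited text with columns `substance`, `atc_code`, `chemical_subgroup`,
#' `era` and optionally `weight` (relative reporting frequency, used as the
#' default substance sampling weight by the simulator). `era` must be one of
#' `old`, `new`, `unclassified`; `chemical_subgroup` one of the eight ATC
#' N03A chemical subgroups.
#'
#' @param path Path to the catalogue file.
#' @return An `atc_catalogue` object (data.table).
#' @export
read_atc_catalogue <- function(path) {
  .pv_assert(file.exists(path), "ATC catalogue file not found: ", path)
  dt <- data.table::fread(path)
  need <- c("substance", "atc_code", "chemical_subgroup", "era")
  miss <- setdiff(need, names(dt))
  .pv_assert(length(miss) == 0L,
             "ATC catalogue missing column(s): ", paste(miss, collapse = ", "),
             class = "pv_config_error")
  .pv_assert(all(dt$era %in% pv_era_levels),
             "ATC catalogue 'era' must be old/new/unclassified",
             class = "pv_config_error")
  .pv_assert(all(dt$chemical_subgroup %in% pv_subgroup_levels),
             "ATC catalogue has unknown chemical_subgroup values",
             class = "pv_config_error")
  if (!"weight" %in% names(dt)) dt[, weight := 1]
  data.table::setattr(dt, "class", c("atc_catalogue", class(dt)))
  dt[]
}

#' Bundled ATC N03A antiseizure-medication catalogue
#'
#' The 44 N03A substances with their chemical subgroup and marketing era
#' ("old" = marketed before 1990, "new" = 1990 or later). Cannabidiol is
#' deliberately `unclassified`: it entered the market recently but is
#' conventionally excluded from old/new era comparisons. ATC codes are
#' given at subgroup level (e.g. `N03AA` for barbiturates); the full
#' seven-character codes require the official ATC index.
#'
#' @return An `atc_catalogue` object.
#' @export
default_atc_catalogue <- function() {
  read_atc_catalogue(system.file("extdata", "atc_n03a_catalogue.csv",
                                 package = "pvsignal", mustWork = TRUE))
}

# bundled synonym table: salt forms and trade spellings folded to one substance
.pv_synonyms <- function() {
  data.table::fread(system.file("extdata", "substance_synonyms.csv",
                                package = "pvsignal", mustWork = TRUE),
                    colClasses = "character")
}

#' Normalize a substance name
#'
#' Case-insensitive lookup against the catalogue with salt-form folding via
#' the bundled synonym table ("Sodium Valproate" and "Valproic acid" are one
#' substance). Names absent from both tables are returned title-trimmed and
#' will classify as `unclassified`.
#'
#' @param x Character vector of raw substance names.
#' @param catalogue An `atc_catalogue`.
#' @return Character vector of normalized substance names.
#' @export
normalize_substance <- function(x, catalogue = default_atc_catalogue()) {
  syn <- .pv_synonyms()
  key <- tolower(trimws(x))
  m <- match(key, syn$synonym)
  key[!is.na(m)] <- tolower(syn$substance[m[!is.na(m)]])
  cm <- match(key, tolower(catalogue$substance))
  out <- trimws(x)
  out[!is.na(cm)] <- catalogue$substance[cm[!is.na(cm)]]
  out
}
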