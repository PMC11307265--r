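# Reading and normalising line-listing exports.

# Vectorised core of the packed reaction-field parser. `packed` is one string
# per input row; returns a data.table with a `row` index column.
.parse_reactions_vec <- function(packed, dialect) {
  packed[is.na(packed)] <- ""
  entries <- strsplit(packed, dialect$entry_sep, fixed = TRUE)
  n <- lengths(entries)
  flat <- trimws(unlist(entries, use.names = FALSE))
  row <- rep(seq_along(packed), n)
  keep <- flat != ""
  flat <- flat[keep]; row <- row[keep]
  if (!length(flat)) {
    return(data.table::data.table(row = integer(), pt = character(),
                                  duration = character(), outcome = character(),
                                  seriousness = character(),
                                  malformed = logical(), raw = character()))
  }

  # split "PT (inner)": the sub-field block is the LAST parenthesized group
  # at the end of the entry; PT names may themselves contain (balanced)
  # parentheses, e.g. "Neoplasms ... (incl. cysts and polyps)". Entries
  # whose remaining PT has unbalanced parentheses, or no PT at all, are
  # flagged malformed with the raw text preserved.
  has_trail <- grepl("\\([^()]*\\)\\s*$", flat)
  pt <- flat
  pt[has_trail] <- sub("\\s*\\([^()]*\\)\\s*$", "", flat[has_trail])
  pt <- trimws(pt)
  inner <- rep(NA_character_, length(flat))
  inner[has_trail] <- sub("^.*\\(([^()]*)\\)\\s*$", "\\1", flat[has_trail])
  n_open <- nchar(gsub("[^(]", "", pt))
  n_close <- nchar(gsub("[^)]", "", pt))
  malformed <- (n_open != n_close) | pt == ""
  inner[malformed] <- NA_character_  # no sub-field decoding of broken entries

  fields <- strsplit(ifelse(is.na(inner), "", inner),
                     dialect$field_sep, fixed = TRUE)
  fld <- function(k) trimws(vapply(fields, function(f)
    if (length(f) >= k) f[[k]] else NA_character_, character(1)))
  duration <- fld(1L)
  duration[duration %in% c("", "n/a", "N/A")] <- NA_character_

  outcome_raw <- fld(2L)
  outcome <- .pv_decode(outcome_raw, .pv_outcome_labels, .pv_outcome_aliases)
  unknown_out <- !is.na(outcome_raw) & trimws(outcome_raw) != "" &
    tolower(trimws(outcome_raw)) != "n/a" & is.na(outcome)
  if (any(unknown_out))
    .pv_warn(sum(unknown_out), " unknown outcome token(s) mapped to unspecified",
             " (e.g. '", outcome_raw[which(unknown_out)[1]], "')")
  outcome[is.na(outcome)] <- "unspecified"

  ser_raw <- fld(3L)
  ser_parts <- strsplit(ifelse(is.na(ser_raw), "", ser_raw),
                        dialect$serious_sep, fixed = TRUE)
  n_unknown_ser <- 0L
  seriousness <- vapply(ser_parts, function(p) {
    p <- trimws(p); p <- p[p != ""]
    if (!length(p)) return("unspecified")
    tok <- .pv_decode(p, .pv_seriousness_labels, .pv_serious_aliases)
    if (anyNA(tok)) n_unknown_ser <<- n_unknown_ser + sum(is.na(tok))
    tok <- unique(tok[!is.na(tok)])
    tok <- setdiff(tok, "unspecified")
    if (!length(tok)) "unspecified" else paste(sort(tok), collapse = ";")
  }, character(1))
  if (n_unknown_ser > 0L)
    .pv_warn(n_unknown_ser, " unknown seriousness token(s) dropped as unspecified")

  data.table::data.table(row = row, pt = pt, duration = duration,
                         outcome = outcome, seriousness = seriousness,
                         malformed = malformed,
                         raw = ifelse(malformed, flat, NA_character_))
}

#' Parse a packed reaction-list field
#'
#' One cell of a line listing packs every reaction of a report as
#' `"PT (duration - outcome - seriousness1; seriousness2)"`, entries
#' separated by the dialect's entry separator. Missing sub-fields map to
#' `unspecified`; seriousness is split into a multi-label set; entries that
#' cannot be parsed are flagged `malformed` with the raw text preserved,
#' never dropped.
#'
#' @param packed A single packed string.
#' @param dialect An [ll_dialect()].
#' @return A data.table of reaction records (possibly zero rows) with
#'   columns `pt`, `duration`, `outcome`, `seriousness`, `malformed`, `raw`.
#' @export
#' @examples
#' parse_reaction_list(
#'   "Seizure (n/a – Recovered/Resolved – Caused/Prolonged Hospitalisation)")
parse_reaction_list <- function(packed, dialect = ll_dialect()) {
  .pv_assert(is.character(packed) && length(packed) == 1L,
             "packed must be a single string")
  out <- .parse_reactions_vec(packed, dialect)
  out[, row := NULL]
  out[]
}

#' Parse a line-listing export into an ICSR dataset
#'
#' Reads a delimited text export (optionally gzip-compressed), one row per
#' individual case safety report, unpacks the suspect-drug and reaction
#' cells, and normalises every categorical field to the package's
#' controlled vocabulary. Rows whose mandatory fields (`report_id`,
#' `receipt_date`, drugs, reactions) cannot be parsed are collected into
#' the returned object's `rejects` table -- never silently skipped.
#'
#' @param path Path to the listing file.
#' @param dialect An [ll_dialect()] describing the format.
#' @param years Optional inclusive receipt-year window, e.g.
#'   `c(2012, 2021)`; `NULL` keeps all years.
#' @return An [icsr_set()]. Drug era/subgroup and reaction SOC are not yet
#'   assigned; follow with [classify_drugs()] and [assign_soc()].
#' @export
parse_line_listing <- function(path, dialect = ll_dialect(), years = NULL) {
  .pv_assert(file.exists(path), "input file not found: ", path)
  src <- path
  if (grepl("\\.gz$", path)) {
    # inflate to a temp file; fread's own gz path needs an extra package
    src <- tempfile(fileext = ".txt")
    con <- gzfile(path, "rb")
    on.exit(close(con), add = TRUE)
    writeBin(readBin(con, "raw", n = 512 * 1024 * 1024), src)
  }
  raw <- data.table::fread(src, sep = dialect$delim, header = TRUE,
                           colClasses = "character", quote = "\"",
                           blank.lines.skip = TRUE)
  cols <- dialect$columns
  mandatory <- cols[c("report_id", "receipt_date", "drugs", "reactions")]
  miss <- setdiff(unname(mandatory), names(raw))
  .pv_assert(length(miss) == 0L,
             "missing mandatory column(s): ", paste(miss, collapse = ", "),
             class = "pv_config_error")
  if (nrow(raw) == 0L) {
    .pv_warn("empty line listing: ", path)
    empty <- data.table::data.table(report_id = character())
    return(icsr_set(
      data.table::data.table(report_id = character(), receipt_year = integer(),
                             sex = character(), age_group = character(),
                             reporter = character(), region = character()),
      data.table::data.table(report_id = character(), substance = character()),
      data.table::data.table(report_id = character(), pt = character(),
                             outcome = character(), seriousness = character())))
  }

  get_col <- function(role, default = NA_character_) {
    nm <- cols[[role]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }

  id <- trimws(get_col("report_id"))
  year <- suppressWarnings(
    as.integer(sub("^(\\d{4}).*$", "\\1", trimws(get_col("receipt_date")))))
  drugs_raw <- get_col("drugs")
  rxn_raw <- get_col("reactions")

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(id) | id == ""] <- "missing report_id"
  dup <- duplicated(id) & !is.na(id) & id != ""
  reason[dup & is.na(reason)] <- "duplicate report_id"
  reason[is.na(reason) & (is.na(year) | year < 1900 | year > 2100)] <-
    "unparseable receipt_date"
  reason[is.na(reason) & (is.na(drugs_raw) | trimws(drugs_raw) == "")] <-
    "no suspect drugs"
  reason[is.na(reason) & (is.na(rxn_raw) | trimws(rxn_raw) == "")] <-
    "no reactions"
  ok <- is.na(reason)

  rejects <- NULL
  if (any(!ok)) {
    rejects <- data.table::data.table(row = which(!ok), report_id = id[!ok],
                                      reason = reason[!ok])
    .pv_warn(sum(!ok), " of ", nrow(raw), " row(s) rejected at ingestion")
  }

  idx <- which(ok)
  reports <- data.table::data.table(
    report_id = id[idx],
    receipt_year = year[idx],
    sex = .pv_fill(.pv_decode(get_col("sex")[idx], .pv_sex_labels, .pv_sex_aliases)),
    age_group = .pv_fill(.pv_decode(get_col("age_group")[idx], .pv_age_labels,
                                    .pv_age_aliases)),
    reporter = .pv_fill(.pv_decode(get_col("reporter")[idx],
                                   .pv_reporter_labels, .pv_reporter_aliases)),
    region = .pv_fill(.pv_decode(get_col("region")[idx], .pv_region_labels,
                                 .pv_region_aliases))
  )

  dl <- strsplit(drugs_raw[idx], dialect$drug_sep, fixed = TRUE)
  drugs <- data.table::data.table(
    report_id = rep(reports$report_id, lengths(dl)),
    substance = trimws(unlist(dl, use.names = FALSE)))
  drugs <- drugs[substance != ""]

  rx <- .parse_reactions_vec(rxn_raw[idx], dialect)
  rx[, report_id := reports$report_id[row]]
  rx[, row := NULL]

  # rows whose reaction field parsed to nothing at all are rejected too
  no_rxn <- setdiff(reports$report_id, rx$report_id)
  no_drug <- setdiff(reports$report_id, drugs$report_id)
  bad <- union(no_rxn, no_drug)
  if (length(bad)) {
    extra <- data.table::data.table(row = NA_integer_, report_id = bad,
                                    reason = "no parseable drugs/reactions")
    rejects <- data.table::rbindlist(list(rejects, extra), use.names = TRUE)
    reports <- reports[!report_id %in% bad]
    drugs <- drugs[!report_id %in% bad]
    rx <- rx[!report_id %in% bad]
  }

  out <- icsr_set(reports, drugs, rx, rejects = rejects)
  message(sprintf("ingested %d report(s), rejected %d row(s)",
                  nrow(out$reports),
                  if (is.null(rejects)) 0L else nrow(rejects)))
  if (!is.null(years)) out <- filter_years(out, years)
  out
}

.pv_fill <- function(x) { x[is.na(x)] <- "unspecified"; x }

#' Write an ICSR dataset as a line listing
#'
#' Inverse of [parse_line_listing()]: serialises a dataset back to the
#' dialect's delimited format, packing reactions and joining drug names.
#' Canonical tokens are rendered with their display labels, so a written
#' file round-trips through the parser to identical normalized records.
#' Paths ending in `.gz` are gzip-compressed.
#'
#' @param x An `icsr_set`.
#' @param path Output path.
#' @param dialect An [ll_dialect()].
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(x, path, dialect = ll_dialect()) {
  .pv_assert(inherits(x, "icsr_set"), "x must be an icsr_set")
  rxn <- data.table::copy(x$reactions)
  lab <- function(tok, labels) unname(labels[tok])
  rxn[, packed := paste0(
    pt, " (", data.table::fifelse(is.na(duration), "n/a", duration),
    " ", dialect$field_sep, " ", lab(outcome, .pv_outcome_labels),
    " ", dialect$field_sep, " ",
    vapply(strsplit(seriousness, ";", fixed = TRUE), function(s)
      paste(unname(.pv_seriousness_labels[s]),
            collapse = paste0(dialect$serious_sep, " ")), character(1)),
    ")")]
  packed <- rxn[, .(reaction_list = paste(packed, collapse = dialect$entry_sep)),
                by = report_id]
  dstr <- x$drugs[, .(suspect_drugs = paste(substance,
                                            collapse = paste0(dialect$drug_sep, " "))),
                  by = report_id]
  out <- merge(merge(x$reports, dstr, by = "report_id"),
               packed, by = "report_id")
  out <- out[, .(
    report_id,
    receipt_date = sprintf("%04d-06-15", receipt_year),
    sex = unname(.pv_sex_labels[sex]),
    age_group = unname(.pv_age_labels[age_group]),
    reporter_qualification = unname(.pv_reporter_labels[reporter]),
    region = unname(.pv_region_labels[region]),
    suspect_drugs, reaction_list)]
  data.table::setnames(out, old = c("report_id", "receipt_date", "sex",
                                    "age_group", "reporter_qualification",
                                    "region", "suspect_drugs", "reaction_list"),
                       new = unname(dialect$columns[c("report_id", "receipt_date",
                                                      "sex", "age_group", "reporter",
                                                      "region", "drugs", "reactions")]))
  data.table::setorderv(out, dialect$columns[["report_id"]])
  data.table::fwrite(out, path, sep = dialect$delim, quote = TRUE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Classify drug exposures by ATC subgroup and marketing era
#'
#' Fills `atc_code`, `chemical_subgroup` and `era` on every drug exposure
#' via case-insensitive, salt-folding substance lookup in the catalogue.
#' Substances absent from the catalogue are flagged `era = "unclassified"`
#' with a logged warning -- never dropped.
#'
#' @param x An `icsr_set`.
#' @param catalogue An [read_atc_catalogue()] object; defaults to the
#'   bundled N03A catalogue.
#' @return The dataset with classified drug exposures.
#' @export
classify_drugs <- function(x, catalogue = default_atc_catalogue()) {
  .pv_assert(inherits(x, "icsr_set"), "x must be an icsr_set")
  drugs <- data.table::copy(x$drugs)
  drugs[, substance := normalize_substance(substance, catalogue)]
  m <- match(tolower(drugs$substance), tolower(catalogue$substance))
  drugs[, atc_code := catalogue$atc_code[m]]
  drugs[, chemical_subgroup := catalogue$chemical_subgroup[m]]
  drugs[, era := data.table::fifelse(is.na(m), "unclassified",
                                     catalogue$era[m])]
  n_unk <- sum(is.na(m))
  if (n_unk > 0L)
    .pv_warn(n_unk, " drug exposure(s) with substances not in the catalogue ",
             "classified as era=unclassified")
  icsr_set(x$reports, drugs, x$reactions, rejects = x$rejects)
}

#' Assign system organ classes to reaction records
#'
#' Total function: every record receives exactly one SOC -- the map's
#' primary SOC for its PT, or `"Not Specified"` when the PT is unmapped
#' (counted, warned, never an error). Idempotent.
#'
#' @param x An `icsr_set` or a data.table of reaction records with a `pt`
#'   column.
#' @param map A [read_meddra_map()] object; defaults to the bundled
#'   synthetic map.
#' @return Object of the same type with `soc` populated.
#' @export
assign_soc <- function(x, map = default_meddra_map()) {
  if (inherits(x, "icsr_set")) {
    rxn <- .assign_soc_dt(data.table::copy(x$reactions), map)
    return(icsr_set(x$reports, x$drugs, rxn, rejects = x$rejects))
  }
  .assign_soc_dt(data.table::copy(data.table::as.data.table(x)), map)
}

.assign_soc_dt <- function(rxn, map) {
  m <- match(tolower(rxn$pt), tolower(map$pt))
  rxn[, soc := data.table::fifelse(is.na(m), "Not Specified", map$soc[m])]
  n_unmapped <- sum(is.na(m))
  if (n_unmapped > 0L)
    .pv_warn(n_unmapped, " reaction record(s) with unmapped PTs assigned ",
             "SOC 'Not Specified'")
  rxn[]
}

utils::globalVariables(c("packed", "suspect_drugs", "reaction_list", "N"))
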