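#' Construct an ICSR dataset
#'
#' The in-memory container used throughout the package: three linked
#' data.tables in a relational layout, one row per report, per drug
#' exposure, and per reaction record respectively.
#'
#' @param reports data.table with columns `report_id`, `receipt_year`,
#'   `sex`, `age_group`, `reporter`, `region`.
#' @param drugs data.table with columns `report_id`, `substance` and
#'   (after [classify_drugs()]) `atc_code`, `chemical_subgroup`, `era`.
#' @param reactions data.table with columns `report_id`, `pt`, `soc`,
#'   `outcome`, `seriousness` (";"-joined canonical tokens), `duration`,
#'   `malformed`, `raw`.
#' @param rejects Optional data.table of rejected input rows with a
#'   `reason` column.
#' @return An object of class `icsr_set`.
#' @export
icsr_set <- function(reports, drugs, reactions, rejects = NULL) {
  reports <- data.table::as.data.table(reports)
  drugs <- data.table::as.data.table(drugs)
  reactions <- data.table::as.data.table(reactions)
  .pv_assert(!anyDuplicated(reports$report_id),
             "report_id must be unique within a dataset",
             class = "pv_data_error")
  .pv_assert(all(drugs$report_id %in% reports$report_id) &&
               all(reactions$report_id %in% reports$report_id),
             "drugs/reactions reference unknown report_id",
             class = "pv_data_error")
  missing_drug <- setdiff(reports$report_id, drugs$report_id)
  missing_rxn <- setdiff(reports$report_id, reactions$report_id)
  .pv_assert(length(missing_drug) == 0L,
             "every report needs at least one drug exposure; missing for ",
             length(missing_drug), " report(s)", class = "pv_data_error")
  .pv_assert(length(missing_rxn) == 0L,
             "every report needs at least one reaction; missing for ",
             length(missing_rxn), " report(s)", class = "pv_data_error")
  for (col in c("atc_code", "chemical_subgroup", "era")) {
    if (!col %in% names(drugs)) drugs[, (col) := NA_character_]
  }
  for (col in c("soc", "duration")) {
    if (!col %in% names(reactions)) reactions[, (col) := NA_character_]
  }
  if (!"malformed" %in% names(reactions)) reactions[, malformed := FALSE]
  if (!"raw" %in% names(reactions)) reactions[, raw := NA_character_]
  structure(list(reports = reports[], drugs = drugs[], reactions = reactions[],
                 rejects = rejects),
            class = "icsr_set")
}

#' @export
print.icsr_set <- function(x, ...) {
  cat(sprintf("<icsr_set> %s reports, %s drug exposures, %s reaction records\n",
              format(nrow(x$reports), big.mark = ","),
              format(nrow(x$drugs), big.mark = ","),
              format(nrow(x$reactions), big.mark = ",")))
  if (!is.null(x$rejects) && nrow(x$rejects))
    cat(sprintf("  (%d input row(s) rejected at ingestion)\n", nrow(x$rejects)))
  yrs <- range(x$reports$receipt_year, na.rm = TRUE)
  cat(sprintf("  receipt years %d-%d\n", yrs[1], yrs[2]))
  invisible(x)
}

#' Flatten a dataset to the PT-occurrence level
#'
#' Joins reactions with drug exposures and report demographics into one
#' flat table, the counting frame used by all association scans. Under
#' `attribution = "all_suspected"` every reaction is credited to every
#' suspected drug in its report (the semantics of per-drug line listings,
#' where one report appears once per drug); `"first_listed"` credits each
#' reaction only to the first-listed drug.
#'
#' @param x An `icsr_set`.
#' @param attribution `"all_suspected"` (default) or `"first_listed"`.
#' @param include_malformed Keep reaction records flagged malformed
#'   (default `FALSE`).
#' @return A data.table with one row per (report, drug, reaction) triple
#'   and columns `report_id`, demographics, `substance`,
#'   `chemical_subgroup`, `era`, `pt`, `soc`, `outcome`, `seriousness`.
#' @export
pt_frame <- function(x, attribution = c("all_suspected", "first_listed"),
                     include_malformed = FALSE) {
  .pv_assert(inherits(x, "icsr_set"), "x must be an icsr_set")
  attribution <- match.arg(attribution)
  drugs <- x$drugs
  if (attribution == "first_listed")
    drugs <- drugs[, head(.SD, 1L), by = report_id]
  rxn <- x$reactions
  if (!include_malformed) rxn <- rxn[malformed == FALSE | is.na(malformed)]
  fr <- merge(rxn, drugs, by = "report_id", allow.cartesian = TRUE)
  fr <- merge(fr, x$reports, by = "report_id")
  data.table::setorder(fr, report_id, substance, pt)
  fr[]
}

#' Restrict a dataset to a receipt-year window
#'
#' @param x An `icsr_set`.
#' @param years Inclusive integer year range, default `c(2012, 2021)`.
#' @return A filtered `icsr_set`.
#' @export
filter_years <- function(x, years = c(2012, 2021)) {
  .pv_assert(inherits(x, "icsr_set"), "x must be an icsr_set")
  keep <- x$reports[receipt_year >= years[1] & receipt_year <= years[2],
                    report_id]
  icsr_set(x$reports[report_id %in% keep],
           x$drugs[report_id %in% keep],
           x$reactions[report_id %in% keep],
           rejects = x$rejects)
}
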