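#' Line-listing format dialect
#'
#' EudraVigilance-style exports vary in delimiter, column naming and in how
#' the per-reaction sub-fields are packed into a single cell. A dialect
#' object captures those choices. The default mirrors the public
#' line-listing convention: one row per case report, a `;`-separated
#' suspect-drug cell, and a reaction cell packing one entry per reaction as
#' `"PT (duration - outcome - seriousness1; seriousness2)"` with entries
#' separated by `",\n"` (comma + newline; the cell is quoted in the file).
#'
#' @param delim Field delimiter of the listing file (`","` or `"\t"`).
#' @param entry_sep Separator between packed reaction entries.
#' @param field_sep Separator between sub-fields inside one reaction entry
#'   (an en dash in real exports).
#' @param serious_sep Separator between seriousness criteria.
#' @param drug_sep Separator between suspect drug names.
#' @param columns Named character vector mapping the canonical roles
#'   (`report_id`, `receipt_date`, `sex`, `age_group`, `reporter`, `region`,
#'   `drugs`, `reactions`) to column names in the file.
#' @return An object of class `ll_dialect`.
#' @export
ll_dialect <- function(delim = ",",
                       entry_sep = ",\n",
                       field_sep = "–",
                       serious_sep = ";",
                       drug_sep = ";",
                       columns = NULL) {
  default_cols <- c(report_id = "report_id", receipt_date = "receipt_date",
                    sex = "sex", age_group = "age_group",
                    reporter = "reporter_qualification", region = "region",
                    drugs = "suspect_drugs", reactions = "reaction_list")
  if (!is.null(columns)) {
    .pv_assert(all(names(columns) %in% names(default_cols)),
               "unknown column role(s): ",
               paste(setdiff(names(columns), names(default_cols)), collapse = ", "),
               class = "pv_config_error")
    default_cols[names(columns)] <- columns
  }
  structure(list(delim = delim, entry_sep = entry_sep, field_sep = field_sep,
                 serious_sep = serious_sep, drug_sep = drug_sep,
                 columns = default_cols),
            class = "ll_dialect")
}
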