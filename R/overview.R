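#' Report-level overview table
#'
#' Counts and percentages of reports by demographic fields, chemical
#' subgroup and substance (percent of the total report count, two
#' decimals, half-up). Demographic sections zero-fill absent levels.
#' A report naming drugs in several subgroups is counted once per
#' subgroup, so subgroup counts may sum above the report total.
#'
#' @param x An `icsr_set` (drugs classified for the subgroup/substance
#'   sections to be meaningful).
#' @return A data.table with columns `section`, `level`, `count`,
#'   `percent`.
#' @export
summarize_reports <- function(x) {
  .pv_assert(inherits(x, "icsr_set"), "x must be an icsr_set")
  total <- nrow(x$reports)
  pct <- function(n) if (total == 0L) 0 else round_half_up(100 * n / total, 2)

  enum_section <- function(col, levels) {
    cnt <- x$reports[, .N, by = c(col)]
    data.table::setnames(cnt, col, "level")
    full <- data.table::data.table(level = levels)
    cnt <- merge(full, cnt, by = "level", all.x = TRUE)
    cnt[is.na(N), N := 0L]
    cnt[, .(level = factor(level, levels = levels), count = N)][order(level)]
  }

  sections <- list(
    sex = enum_section("sex", pv_sex_levels),
    age_group = enum_section("age_group", pv_age_levels),
    reporter = enum_section("reporter", pv_reporter_levels),
    region = enum_section("region", pv_region_levels)
  )

  drug_section <- function(col) {
    d <- unique(x$drugs[!is.na(get(col)), c("report_id", col), with = FALSE])
    cnt <- d[, .(count = .N), by = c(col)]
    data.table::setnames(cnt, col, "level")
    cnt[order(level)]
  }

  out <- data.table::rbindlist(c(
    list(total = data.table::data.table(level = "all_reports", count = total)),
    lapply(sections, function(s) s[, .(level = as.character(level), count)]),
    list(era = drug_section("era"),
         chemical_subgroup = drug_section("chemical_subgroup"),
         substance = drug_section("substance"))
  ), idcol = "section")
  out[, percent := pct(count)]
  out[]
}
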