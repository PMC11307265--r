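# The analyses as composable scan stages. Every stage flattens the dataset
# to a counting frame (pt_frame), derives exposure groups from the grouping
# choice, builds one 2x2 table per (exposure, event) pair and attaches the
# full set of disproportionality statistics.

.scan_groupings <- c("era_old_vs_new", "subgroup_vs_rest", "substance_vs_rest")

# exposure groups for a grouping choice; returns list(frame, groups) where
# groups is a named list of logical exposure vectors over the frame rows
.scan_groups <- function(frame, grouping) {
  if (grouping == "era_old_vs_new") {
    dropped <- sum(!frame$era %in% c("old", "new"), na.rm = TRUE) +
      sum(is.na(frame$era))
    if (dropped > 0L)
      message(sprintf("era scan: %d unclassified-era PT row(s) excluded", dropped))
    frame <- frame[era %in% c("old", "new")]
    groups <- list(old = frame$era == "old")
  } else if (grouping == "subgroup_vs_rest") {
    lv <- sort(unique(frame$chemical_subgroup[!is.na(frame$chemical_subgroup)]))
    groups <- lapply(lv, function(g) frame$chemical_subgroup == g & !is.na(frame$chemical_subgroup))
    names(groups) <- lv
  } else if (grouping == "substance_vs_rest") {
    lv <- sort(unique(frame$substance))
    groups <- lapply(lv, function(g) frame$substance == g)
    names(groups) <- lv
  } else {
    .pv_assert(FALSE, "unknown grouping: ", grouping, class = "pv_config_error")
  }
  list(frame = frame, groups = groups)
}

# core scan: events is a named list of logical event vectors
.run_scan <- function(frame, grouping, events, unit, scan_name,
                      strata = NULL) {
  gg <- .scan_groups(frame, grouping)
  frame <- gg$frame
  rows <- list()
  for (ex_label in names(gg$groups)) {
    expo <- gg$groups[[ex_label]]
    for (ev_label in names(events)) {
      ev <- events[[ev_label]]
      .pv_assert(length(ev) == nrow(frame),
                 "internal: event vector length mismatch")
      tab <- build_table(frame, expo, ev, exposure_label = ex_label,
                         event_label = ev_label, unit = unit)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        exposure = ex_label, event = ev_label, .dispro_row(dispro(tab)))
    }
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(exposure = character(), event = character())
  data.table::setorder(out, exposure, event)
  data.table::setattr(out, "scan_spec",
                      list(scan = scan_name, grouping = grouping, unit = unit,
                           strata = strata,
                           n_frame = nrow(frame),
                           timestamp = format(Sys.time(), tz = "UTC")))
  data.table::setattr(out, "class", c("scan_result", class(out)))
  out[]
}

.scan_frame <- function(x, strata, attribution) {
  frame <- pt_frame(x, attribution = attribution)
  apply_strata(frame, parse_strata_if_chr(strata))
}

parse_strata_if_chr <- function(strata) {
  if (is.character(strata)) parse_strata(strata) else strata
}

# recompute event vectors against a (possibly grouping-filtered) frame:
# events are expressed as predicate functions so .run_scan can re-evaluate
# them after the era filter. We instead pre-filter here for simplicity.
.soc_events <- function(frame) {
  lv <- sort(unique(frame$soc))
  ev <- lapply(lv, function(s) frame$soc == s)
  names(ev) <- lv
  ev
}

#' Per-SOC disproportionality scan
#'
#' One row per system organ class present in the dataset (including
#' `"Not Specified"`). Under the era grouping each SOC's table is
#' (old-era PTs in the SOC, other old PTs, new-era PTs in the SOC, other
#' new PTs); unclassified-era rows are excluded from both arms with a
#' logged count.
#'
#' @param x An `icsr_set` with SOCs assigned and drugs classified.
#' @param grouping `"era_old_vs_new"` (default), `"subgroup_vs_rest"` or
#'   `"substance_vs_rest"`.
#' @param strata Optional strata filter (string or [parse_strata()] list).
#' @param unit Counting unit, `"pt"` (default) or `"report"`.
#' @param attribution PT attribution in multi-drug reports, see
#'   [pt_frame()].
#' @return A `scan_result` data.table: `exposure`, `event`, the four
#'   cells, ROR/PRR with 95% CIs, chi-square, p, `n_cases`, `countable`,
#'   SDR flags.
#' @export
soc_scan <- function(x, grouping = "era_old_vs_new", strata = NULL,
                     unit = c("pt", "report"),
                     attribution = "all_suspected") {
  unit <- match.arg(unit)
  grouping <- match.arg(grouping, .scan_groupings)
  frame <- .scan_frame(x, strata, attribution)
  if (grouping == "era_old_vs_new") frame <- frame[era %in% c("old", "new")]
  .run_scan(frame, grouping, .soc_events(frame), unit, "soc", strata)
}

#' Seriousness-criterion disproportionality scan
#'
#' One row per seriousness criterion. Seriousness is multi-label: a PT
#' carrying k criteria contributes to the event cell of k rows. PTs with
#' wholly unspecified seriousness stay in the frame (they count in the
#' b/d cells); set `drop_unspecified = TRUE` to exclude them.
#'
#' @inheritParams soc_scan
#' @param drop_unspecified Exclude PTs with no reported seriousness from
#'   the frame entirely (default `FALSE`).
#' @return A `scan_result` data.table.
#' @export
seriousness_scan <- function(x, grouping = "era_old_vs_new", strata = NULL,
                             unit = c("pt", "report"),
                             attribution = "all_suspected",
                             drop_unspecified = FALSE) {
  unit <- match.arg(unit)
  grouping <- match.arg(grouping, .scan_groupings)
  frame <- .scan_frame(x, strata, attribution)
  if (drop_unspecified) frame <- frame[seriousness != "unspecified"]
  if (grouping == "era_old_vs_new") frame <- frame[era %in% c("old", "new")]
  crit <- setdiff(seriousness_levels(), "unspecified")
  events <- lapply(crit, function(cr)
    grepl(paste0("(^|;)", cr, "(;|$)"), frame$seriousness))
  names(events) <- crit
  .run_scan(frame, grouping, events, unit, "seriousness", strata)
}

#' Outcome disproportionality scan
#'
#' One row per outcome category. Outcome is single-label, so the event
#' cells of the five named categories partition the PTs with a known
#' outcome; `unspecified` PTs remain in the b/d cells.
#'
#' @inheritParams soc_scan
#' @return A `scan_result` data.table.
#' @export
outcome_scan <- function(x, grouping = "era_old_vs_new", strata = NULL,
                         unit = c("pt", "report"),
                         attribution = "all_suspected") {
  unit <- match.arg(unit)
  grouping <- match.arg(grouping, .scan_groupings)
  frame <- .scan_frame(x, strata, attribution)
  if (grouping == "era_old_vs_new") frame <- frame[era %in% c("old", "new")]
  lv <- setdiff(outcome_levels(), "unspecified")
  events <- lapply(lv, function(o) frame$outcome == o)
  names(events) <- lv
  .run_scan(frame, grouping, events, unit, "outcome", strata)
}

#' SUDEP single-event scan
#'
#' Sudden unexpected death in epilepsy analysed as a single-event signal,
#' by era, chemical subgroup and substance. The matching PT label list is
#' configurable because reporting dialects use both "unexpected" and
#' "unexplained".
#'
#' @inheritParams soc_scan
#' @param grouping One of the three groupings or `"all"` (default) to
#'   stack era, subgroup and substance rows into one table.
#' @param sudep_pts Character vector of PT names counted as SUDEP
#'   (matched case-insensitively, exact).
#' @return A `scan_result` data.table with a `grouping` column.
#' @export
sudep_scan <- function(x, grouping = "all", strata = NULL,
                       unit = c("pt", "report"),
                       attribution = "all_suspected",
                       sudep_pts = "Sudden unexplained death in epilepsy") {
  unit <- match.arg(unit)
  grouping <- match.arg(grouping, c("all", .scan_groupings))
  frame0 <- .scan_frame(x, strata, attribution)
  groupings <- if (grouping == "all") .scan_groupings else grouping
  parts <- lapply(groupings, function(g) {
    frame <- frame0
    if (g == "era_old_vs_new") frame <- frame[era %in% c("old", "new")]
    ev <- list(SUDEP = tolower(frame$pt) %in% tolower(sudep_pts))
    res <- .run_scan(frame, g, ev, unit, "sudep", strata)
    res[, grouping := g]
    res
  })
  out <- data.table::rbindlist(parts)
  data.table::setcolorder(out, "grouping")
  data.table::setattr(out, "scan_spec",
                      list(scan = "sudep", grouping = grouping, unit = unit,
                           strata = strata, sudep_pts = sudep_pts,
                           timestamp = format(Sys.time(), tz = "UTC")))
  data.table::setattr(out, "class", c("scan_result", class(out)))
  out[]
}

#' Most frequently reported preferred terms
#'
#' @inheritParams soc_scan
#' @param n Number of PTs to return (ties broken alphabetically; `n`
#'   larger than the vocabulary returns the full list).
#' @return A data.table `pt`, `count`, `percent` (percent of the total
#'   PT count, two decimals, half-up), ranked by descending count.
#' @export
top_pt_table <- function(x, n = 10, strata = NULL,
                         attribution = "all_suspected") {
  frame <- .scan_frame(x, strata, attribution)
  if (nrow(frame) == 0L || n <= 0)
    return(data.table::data.table(pt = character(), count = integer(),
                                  percent = numeric()))
  cnt <- frame[, .(count = .N), by = pt]
  total <- nrow(frame)
  data.table::setorder(cnt, -count, pt)
  cnt <- head(cnt, n)
  cnt[, percent := round_half_up(100 * count / total, 2)]
  cnt[]
}

#' Per-year, per-SOC PT counts
#'
#' Complete year-by-SOC grid (zero-filled) of PT-occurrence counts, the
#' tabular equivalent of a reporting-trend figure.
#'
#' @inheritParams soc_scan
#' @return A data.table `year`, `soc`, `count`; yearly sums equal the
#'   frame's per-year totals.
#' @export
yearly_soc_series <- function(x, strata = NULL,
                              attribution = "all_suspected") {
  frame <- .scan_frame(x, strata, attribution)
  if (nrow(frame) == 0L)
    return(data.table::data.table(year = integer(), soc = character(),
                                  count = integer()))
  cnt <- frame[, .(count = .N), by = .(year = receipt_year, soc)]
  grid <- data.table::CJ(year = sort(unique(frame$receipt_year)),
                         soc = sort(unique(frame$soc)))
  out <- merge(grid, cnt, by = c("year", "soc"), all.x = TRUE)
  out[is.na(count), count := 0L]
  data.table::setorder(out, year, soc)
  out[]
}

#' Demographic dependence tests
#'
#' Uncorrected Pearson chi-square tests of the demographic associations:
#' * `era_by_sex`: marketing era (old/new) against sex on PT-occurrence
#'   counts, *including* the unspecified-sex column (2x3);
#' * `sudep_by_sex`: SUDEP occurrence against sex on report counts,
#'   *excluding* unspecified sex (2x2);
#' * `sudep_by_age`: SUDEP occurrence against the five age groups on
#'   report counts (2x5).
#'
#' The include/exclude conventions for the unspecified columns follow
#' standard reporting practice for these two tests.
#'
#' @inheritParams sudep_scan
#' @return A data.table `test`, `chi2`, `dof`, `p`, `n`, `countable`.
#' @export
demographic_tests <- function(x, attribution = "all_suspected",
                              sudep_pts = "Sudden unexplained death in epilepsy") {
  frame <- pt_frame(x, attribution = attribution)

  # era x sex on PT counts, unspecified sex kept
  ef <- frame[era %in% c("old", "new")]
  m1 <- as.matrix(data.table::dcast(
    ef[, .N, by = .(era, sex)], era ~ sex, value.var = "N", fill = 0L),
    rownames = "era")
  t1 <- if (nrow(m1) == 2 && ncol(m1) >= 2) chi_square_rxc(m1) else
    list(chi2 = NA_real_, dof = NA_integer_, p = NA_real_, n = sum(m1),
         countable = FALSE)

  # report-level SUDEP indicator
  sudep_ids <- unique(frame[tolower(pt) %in% tolower(sudep_pts), report_id])
  rep_dt <- data.table::copy(x$reports)
  rep_dt[, sudep := report_id %in% sudep_ids]

  sex_dt <- rep_dt[sex %in% c("male", "female")]
  m2 <- as.matrix(data.table::dcast(
    sex_dt[, .N, by = .(sudep, sex)], sudep ~ sex, value.var = "N", fill = 0L),
    rownames = "sudep")
  t2 <- if (nrow(m2) == 2 && ncol(m2) == 2) chi_square_rxc(m2) else
    list(chi2 = NA_real_, dof = NA_integer_, p = NA_real_, n = sum(m2),
         countable = FALSE)

  m3 <- as.matrix(data.table::dcast(
    rep_dt[, .N, by = .(sudep, age_group)], sudep ~ age_group,
    value.var = "N", fill = 0L), rownames = "sudep")
  t3 <- if (nrow(m3) == 2 && ncol(m3) >= 2) chi_square_rxc(m3) else
    list(chi2 = NA_real_, dof = NA_integer_, p = NA_real_, n = sum(m3),
         countable = FALSE)

  data.table::data.table(
    test = c("era_by_sex", "sudep_by_sex", "sudep_by_age"),
    chi2 = c(t1$chi2, t2$chi2, t3$chi2),
    dof = c(t1$dof, t2$dof, t3$dof),
    p = c(t1$p, t2$p, t3$p),
    n = c(t1$n, t2$n, t3$n),
    countable = c(t1$countable, t2$countable, t3$countable))
}

utils::globalVariables(c("sudep"))
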