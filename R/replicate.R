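#' Replicate printed margins as an exact dataset
#'
#' Deterministically constructs a dataset whose PT-level counts equal the
#' requested (exposure, event) cells exactly -- no sampling. Used to turn
#' published contingency margins into fixtures on which the scan stages
#' reproduce published statistics.
#'
#' @param cells A data.frame/data.table with columns `exposure` (an era
#'   level), `event` (a SOC label) and `count`.
#' @param exposure_totals Optional named vector of per-exposure totals;
#'   if supplied, each exposure's cell counts must sum to its total
#'   (inconsistent margins are an error naming the violated sum).
#' @param reactions_per_report Packing density: how many reaction records
#'   to place in one synthetic report (default 200; the choice does not
#'   affect PT-unit scans).
#' @return An [icsr_set()] of synthetic reports. Each event label becomes
#'   both the SOC and a synthetic PT `"<event> [synthetic PT]"`.
#' @export
replicate_margins <- function(cells, exposure_totals = NULL,
                              reactions_per_report = 200L) {
  cells <- data.table::as.data.table(cells)
  .pv_assert(all(c("exposure", "event", "count") %in% names(cells)),
             "cells needs columns exposure, event, count",
             class = "pv_config_error")
  .pv_assert(all(cells$count >= 0) &&
               all(abs(cells$count - round(cells$count)) < 1e-9),
             "counts must be non-negative integers",
             class = "pv_config_error")
  .pv_assert(sum(cells$count) > 0, "degenerate margin: zero total count",
             class = "pv_config_error")
  .pv_assert(all(cells$exposure %in% pv_era_levels),
             "exposure must be an era level", class = "pv_config_error")
  if (!is.null(exposure_totals)) {
    got <- cells[, .(s = sum(count)), by = exposure]
    for (i in seq_len(nrow(got))) {
      ex <- got$exposure[i]
      .pv_assert(!is.na(exposure_totals[ex]) &&
                   got$s[i] == exposure_totals[[ex]],
                 sprintf("margin mismatch for exposure '%s': cells sum to %d, total says %d",
                         ex, got$s[i], exposure_totals[[ex]]),
                 class = "pv_config_error")
    }
  }

  cells <- cells[count > 0]
  reps <- list(); drgs <- list(); rxns <- list()
  next_id <- 1L
  for (i in seq_len(nrow(cells))) {
    ex <- cells$exposure[i]; ev <- cells$event[i]; cnt <- cells$count[i]
    n_rep <- ceiling(cnt / reactions_per_report)
    sizes <- rep(reactions_per_report, n_rep)
    sizes[n_rep] <- cnt - reactions_per_report * (n_rep - 1L)
    ids <- sprintf("REP%08d", next_id:(next_id + n_rep - 1L))
    next_id <- next_id + n_rep
    reps[[i]] <- data.table::data.table(
      report_id = ids, receipt_year = 2016L, sex = "unspecified",
      age_group = "unspecified", reporter = "unspecified",
      region = "unspecified")
    drgs[[i]] <- data.table::data.table(
      report_id = ids,
      substance = paste0("Synthetic ", ex, " ASM"),
      atc_code = NA_character_, chemical_subgroup = NA_character_,
      era = ex)
    rxns[[i]] <- data.table::data.table(
      report_id = rep(ids, sizes),
      pt = paste0(ev, " [synthetic PT]"), soc = ev,
      outcome = "unspecified", seriousness = "unspecified",
      duration = NA_character_, malformed = FALSE)
  }
  icsr_set(data.table::rbindlist(reps), data.table::rbindlist(drgs),
           data.table::rbindlist(rxns))
}
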