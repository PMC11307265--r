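#' Construct a 2x2 contingency table
#'
#' The drug--event table feeding every disproportionality statistic:
#' `a` = exposure group with the event, `b` = exposure group without,
#' `c` = comparator with, `d` = comparator without.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param exposure,event Labels for the exposure and event margins.
#' @param unit Counting unit, `"pt"` (PT occurrences, the default for
#'   association scans) or `"report"`.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, exposure = "exposed",
                              event = "event", unit = c("pt", "report")) {
  unit <- match.arg(unit)
  cells <- c(a = a, b = b, c = c, d = d)
  .pv_assert(all(is.finite(cells)) && all(cells >= 0) &&
               all(abs(cells - round(cells)) < 1e-9),
             "cells a,b,c,d must be non-negative integers")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), exposure = exposure, event = event,
                 unit = unit),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c(x$exposure, "comparator"),
                              c(x$event, paste0("not ", x$event))))
  cat(sprintf("<contingency_table> unit=%s\n", x$unit))
  print(m)
  invisible(x)
}

#' Swap the exposure and comparator rows
#' @param x A `contingency_table`.
#' @return A `contingency_table` with (a,b) and (c,d) exchanged.
#' @export
swap_exposure <- function(x) {
  contingency_table(x$c, x$d, x$a, x$b,
                    exposure = paste0("not ", x$exposure),
                    event = x$event, unit = x$unit)
}

#' Build a contingency table from a counting frame
#'
#' Cross-classifies the rows of a PT-occurrence frame (see [pt_frame()])
#' by an exposure predicate and an event predicate. Under
#' `unit = "report"` the predicates are collapsed to the report level
#' first (a report is exposed / has the event if any of its rows does).
#'
#' @param frame A data.table, typically from [pt_frame()].
#' @param exposure,event Either logical vectors of length `nrow(frame)`
#'   or functions of the frame returning such vectors.
#' @param exposure_label,event_label Margin labels.
#' @param unit `"pt"` or `"report"`.
#' @return A [contingency_table()]. All four cells sum to the frame's
#'   total for the chosen unit.
#' @export
build_table <- function(frame, exposure, event,
                        exposure_label = "exposed", event_label = "event",
                        unit = c("pt", "report")) {
  unit <- match.arg(unit)
  if (is.function(exposure)) exposure <- exposure(frame)
  if (is.function(event)) event <- event(frame)
  .pv_assert(is.logical(exposure) && length(exposure) == nrow(frame),
             "exposure must be a logical vector over the frame rows")
  .pv_assert(is.logical(event) && length(event) == nrow(frame),
             "event must be a logical vector over the frame rows")
  exposure[is.na(exposure)] <- FALSE
  event[is.na(event)] <- FALSE
  if (unit == "report") {
    dt <- data.table::data.table(id = frame$report_id, e = exposure, v = event)
    dt <- dt[, .(e = any(e), v = any(v)), by = id]
    exposure <- dt$e; event <- dt$v
  }
  contingency_table(sum(exposure & event), sum(exposure & !event),
                    sum(!exposure & event), sum(!exposure & !event),
                    exposure = exposure_label, event = event_label,
                    unit = unit)
}

utils::globalVariables(c("e", "v", "id"))
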