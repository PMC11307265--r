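#' Parse a strata filter expression
#'
#' Mini-language for restricting scans, e.g.
#' `"sex=female,age=18-64,year=2012:2021"`. Recognised keys: `sex`,
#' `age` (or `age_group`), `year` (single year or `from:to` range),
#' `reporter`, `region`. Filters compose by conjunction.
#'
#' @param spec A filter string, or `NULL`/`""` for no filtering.
#' @return A named list understood by [apply_strata()], or `NULL`.
#' @export
parse_strata <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(NULL)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(trimws(p), "=", fixed = TRUE)[[1]]
    .pv_assert(length(kv) == 2L, "bad strata term: '", p, "'",
               class = "pv_config_error")
    key <- kv[1]; val <- kv[2]
    if (key == "age") key <- "age_group"
    .pv_assert(key %in% c("sex", "age_group", "year", "reporter", "region"),
               "unknown strata key: '", key, "'", class = "pv_config_error")
    if (key == "year") {
      yr <- suppressWarnings(as.integer(strsplit(val, ":", fixed = TRUE)[[1]]))
      .pv_assert(!anyNA(yr) && length(yr) %in% 1:2,
                 "bad year range: '", val, "'", class = "pv_config_error")
      if (length(yr) == 1L) yr <- c(yr, yr)
      out$year <- yr
    } else {
      out[[key]] <- val
    }
  }
  out
}

#' Apply a strata filter to a counting frame
#'
#' @param frame A data.table from [pt_frame()].
#' @param strata A list from [parse_strata()] (or `NULL`).
#' @return The filtered frame.
#' @export
apply_strata <- function(frame, strata) {
  if (is.null(strata)) return(frame)
  if (!is.null(strata$sex)) frame <- frame[sex == strata$sex]
  if (!is.null(strata$age_group)) frame <- frame[age_group == strata$age_group]
  if (!is.null(strata$reporter)) frame <- frame[reporter == strata$reporter]
  if (!is.null(strata$region)) frame <- frame[region == strata$region]
  if (!is.null(strata$year))
    frame <- frame[receipt_year >= strata$year[1] &
                     receipt_year <= strata$year[2]]
  frame
}
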