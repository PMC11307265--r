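#' @export
print.scan_result <- function(x, n = 10, ...) {
  spec <- attr(x, "scan_spec")
  if (!is.null(spec))
    cat(sprintf("<scan_result> scan=%s grouping=%s unit=%s (%d row(s))\n",
                spec$scan %||% "?", spec$grouping %||% "?",
                spec$unit %||% "?", nrow(x)))
  y <- data.table::copy(data.table::as.data.table(x))
  for (col in intersect(c("ror", "ror_l", "ror_u", "prr", "prr_l", "prr_u",
                          "chi2"), names(y)))
    y[[col]] <- round_half_up(y[[col]], 2)
  print(head(y, n))
  if (nrow(y) > n) cat(sprintf("  ... %d more row(s)\n", nrow(y) - n))
  invisible(x)
}

#' Write a scan result with its JSON sidecar
#'
#' The table is written at full precision; a `<path>.meta.json` sidecar
#' records the scan specification and (when given) the input hash, so a
#' result file is self-describing. Output is byte-stable across repeated
#' runs on the same input.
#'
#' @param x A `scan_result` (or any data.table).
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @param input_hash Optional hash string of the source dataset.
#' @return `path`, invisibly.
#' @export
write_scan_result <- function(x, path, format = c("csv", "tsv", "json"),
                              input_hash = NULL) {
  format <- match.arg(format)
  dt <- data.table::as.data.table(x)
  if (format == "json") {
    jsonlite::write_json(dt, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    data.table::fwrite(dt, path, sep = if (format == "tsv") "\t" else ",")
  }
  spec <- attr(x, "scan_spec")
  if (!is.null(spec)) {
    spec$timestamp <- NULL  # keep repeated runs byte-identical
    spec$input_hash <- input_hash
    jsonlite::write_json(spec, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}
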