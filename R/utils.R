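#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention used by most
#' spreadsheet software and regulatory tables), unlike [base::round()]'s
#' banker's rounding. Used for all percentages and ratios printed in
#' report output; full precision is always retained internally.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.125, 2)  # 2.13, where round() gives 2.12
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pv_assert <- function(cond, ..., class = "pv_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
  }
  invisible(TRUE)
}

.pv_warn <- function(...) warning(paste0(...), call. = FALSE)

# probability vector validation (sums to 1 within 1e-9 after normalisation off)
.pv_check_probs <- function(p, what) {
  .pv_assert(is.numeric(p) && all(p >= 0) && length(p) >= 1,
             what, " must be a non-negative numeric vector",
             class = "pv_config_error")
  .pv_assert(abs(sum(p) - 1) <= 1e-9,
             what, " must sum to 1 (got ", format(sum(p), digits = 12), ")",
             class = "pv_config_error")
  invisible(p)
}

# deterministic integer sub-seed derived from a master seed (kept < 2^31)
.pv_subseed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}
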