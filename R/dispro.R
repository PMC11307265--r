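# Disproportionality statistics: ROR, PRR, Woolf intervals, Pearson
# chi-square and the EMA signal-of-disproportionate-reporting rules.

.pv_z95 <- function() qnorm(0.975)  # 1.959964

.cells_of <- function(table, correction) {
  cells <- c(a = table$a, b = table$b, c = table$c, d = table$d)
  countable <- all(cells > 0)
  if (!countable && correction == "haldane") {
    cells <- cells + 0.5   # Haldane-Anscombe
    countable <- TRUE
  }
  list(cells = cells, countable = countable)
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' Point estimate `(a*d)/(b*c)` with the log-normal (Woolf) interval
#' `exp(log(ROR) +- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell makes
#' the result non-countable (estimate `NA`) under the default policy;
#' `correction = "haldane"` adds 0.5 to every cell instead.
#'
#' @param table A [contingency_table()].
#' @param correction `"none"` (default) or `"haldane"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A list with `estimate`, `lower`, `upper`, `se_log`,
#'   `countable`.
#' @export
ror <- function(table, correction = c("none", "haldane"), conf_level = 0.95) {
  correction <- match.arg(correction)
  cc <- .cells_of(table, correction)
  if (!cc$countable) {
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                se_log = NA_real_, countable = FALSE))
  }
  k <- cc$cells
  est <- (k["a"] * k["d"]) / (k["b"] * k["c"])
  se <- sqrt(sum(1 / k))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(estimate = unname(est),
       lower = unname(exp(log(est) - z * se)),
       upper = unname(exp(log(est) + z * se)),
       se_log = unname(se), countable = TRUE)
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' Point estimate `(a/(a+b)) / (c/(c+d))` with the log-normal interval
#' `exp(log(PRR) +- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#'
#' @inheritParams ror
#' @return A list with `estimate`, `lower`, `upper`, `se_log`,
#'   `countable`.
#' @export
prr <- function(table, correction = c("none", "haldane"), conf_level = 0.95) {
  correction <- match.arg(correction)
  cc <- .cells_of(table, correction)
  if (!cc$countable) {
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                se_log = NA_real_, countable = FALSE))
  }
  k <- cc$cells
  est <- (k["a"] / (k["a"] + k["b"])) / (k["c"] / (k["c"] + k["d"]))
  se <- sqrt(1 / k["a"] - 1 / (k["a"] + k["b"]) +
               1 / k["c"] - 1 / (k["c"] + k["d"]))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(estimate = unname(est),
       lower = unname(exp(log(est) - z * se)),
       upper = unname(exp(log(est) + z * se)),
       se_log = unname(se), countable = TRUE)
}

#' Pearson chi-square test for an r x c count matrix
#'
#' Uncorrected Pearson statistic `sum((O-E)^2 / E)` with expected counts
#' from the row/column margins, `dof = (r-1)(c-1)` and an upper-tail
#' p-value. A zero row or column margin makes the test non-countable.
#'
#' @param m Numeric matrix of counts, at least 2x2.
#' @param correction Apply the Yates continuity correction (2x2 only).
#' @return A list with `chi2`, `dof`, `p`, `n`, `countable`.
#' @export
chi_square_rxc <- function(m, correction = FALSE) {
  m <- as.matrix(m)
  .pv_assert(nrow(m) >= 2 && ncol(m) >= 2, "matrix must be at least 2x2")
  .pv_assert(all(m >= 0) && all(is.finite(m)), "counts must be non-negative")
  n <- sum(m)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0) || n == 0) {
    return(list(chi2 = NA_real_, dof = NA_integer_, p = NA_real_,
                n = n, countable = FALSE))
  }
  expected <- outer(rs, cs) / n
  dev <- abs(m - expected)
  if (correction && nrow(m) == 2 && ncol(m) == 2)
    dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  dof <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(chi2 = chi2, dof = dof, p = pchisq(chi2, dof, lower.tail = FALSE),
       n = n, countable = TRUE)
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' @param table A [contingency_table()].
#' @param correction Apply the Yates continuity correction (default
#'   `FALSE`; the uncorrected statistic is the package's reporting
#'   convention).
#' @return As [chi_square_rxc()].
#' @export
chi_square <- function(table, correction = FALSE) {
  m <- matrix(c(table$a, table$b, table$c, table$d), 2, 2, byrow = TRUE)
  chi_square_rxc(m, correction = correction)
}

#' Evaluate the EMA signal-of-disproportionate-reporting rules
#'
#' Two flags, applied with the regulatory inequalities exactly:
#' * `ci_rule`: PRR 95% CI lower bound >= 1 AND number of cases >= 3;
#' * `chi2_rule`: PRR > 2 AND chi-square > 4 (both strict).
#'
#' @param x A `dispro_result` (from [dispro()]) or a list with elements
#'   `prr`, `prr_l`, `chi2`, `n_cases` and optionally `countable`.
#' @return A list with logicals `ci_rule`, `chi2_rule` and a `reason`
#'   string (`"ok"`, or why both flags are forced false).
#' @export
sdr_evaluate <- function(x) {
  if (inherits(x, "dispro_result")) {
    vals <- list(prr = x$prr$estimate, prr_l = x$prr$lower,
                 chi2 = x$chi2$chi2, n_cases = x$n_cases,
                 countable = x$countable)
  } else {
    vals <- x
    vals$countable <- vals$countable %||% TRUE
  }
  if (!isTRUE(vals$countable) || is.na(vals$prr)) {
    return(list(ci_rule = FALSE, chi2_rule = FALSE, reason = "not countable"))
  }
  ci_rule <- isTRUE(vals$prr_l >= 1) && isTRUE(vals$n_cases >= 3)
  chi2_rule <- isTRUE(vals$prr > 2) && isTRUE(!is.na(vals$chi2) && vals$chi2 > 4)
  list(ci_rule = ci_rule, chi2_rule = chi2_rule, reason = "ok")
}

#' All disproportionality statistics for one table
#'
#' Computes ROR, PRR, their Woolf intervals, the uncorrected Pearson
#' chi-square with p-value, and the SDR flags in one call.
#'
#' @inheritParams ror
#' @param yates Use the Yates continuity correction for the chi-square.
#' @return A `dispro_result`: list with `table`, `ror`, `prr`, `chi2`,
#'   `n_cases` (= a), `countable`, `sdr`.
#' @export
dispro <- function(table, correction = c("none", "haldane"), yates = FALSE,
                   conf_level = 0.95) {
  correction <- match.arg(correction)
  r <- ror(table, correction, conf_level)
  p <- prr(table, correction, conf_level)
  x2 <- chi_square(table, correction = yates)
  res <- structure(list(table = table, ror = r, prr = p, chi2 = x2,
                        n_cases = table$a, countable = r$countable),
                   class = "dispro_result")
  res$sdr <- sdr_evaluate(res)
  res
}

#' @export
print.dispro_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "N/C" else sprintf("%.2f", round_half_up(v, 2))
  pfmt <- function(p) if (is.na(p)) "N/C" else if (p < 1e-4) "<0.0001" else sprintf("%.4f", p)
  cat(sprintf("%s vs comparator | %s (unit=%s)\n",
              x$table$exposure, x$table$event, x$table$unit))
  cat(sprintf("  a=%g b=%g c=%g d=%g\n", x$table$a, x$table$b, x$table$c,
              x$table$d))
  cat(sprintf("  ROR %s [%s, %s]  PRR %s [%s, %s]\n",
              fmt(x$ror$estimate), fmt(x$ror$lower), fmt(x$ror$upper),
              fmt(x$prr$estimate), fmt(x$prr$lower), fmt(x$prr$upper)))
  cat(sprintf("  chi2 %s (dof %s) p %s  n_cases %d  SDR ci=%s chi2=%s\n",
              fmt(x$chi2$chi2), x$chi2$dof %||% NA, pfmt(x$chi2$p),
              as.integer(x$n_cases), x$sdr$ci_rule, x$sdr$chi2_rule))
  invisible(x)
}

# one flat row per result, used by the scan stages and serialisers
.dispro_row <- function(res) {
  t <- res$table
  data.table::data.table(
    a = t$a, b = t$b, c = t$c, d = t$d,
    ror = res$ror$estimate, ror_l = res$ror$lower, ror_u = res$ror$upper,
    prr = res$prr$estimate, prr_l = res$prr$lower, prr_u = res$prr$upper,
    chi2 = res$chi2$chi2, dof = res$chi2$dof, p = res$chi2$p,
    n_cases = res$n_cases, countable = res$countable,
    sdr_ci_rule = res$sdr$ci_rule, sdr_chi2_rule = res$sdr$chi2_rule)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: `p_(i) * m / i` with a cumulative minimum
#' from the largest p downwards, capped at 1. Provided as an opt-in;
#' no multiplicity correction is applied by the scan stages themselves.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s passed through).
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  .pv_assert(is.numeric(p), "p must be numeric")
  ok <- !is.na(p)
  .pv_assert(all(p[ok] >= 0 & p[ok] <= 1), "p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(pv[o] * m / (m - seq_len(m) + 1L)))
    out[ok] <- adj[ro]
  }
  out
}
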