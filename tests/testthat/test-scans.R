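# scan_pipeline: scan stages, conservation/determinism properties,
# demographic tests

test_that("soc_scan cells partition the era totals and handle single-SOC data", {
  x <- generate_dataset(sim_config(n_reports = 600, seed = 21))
  s <- soc_scan(x)
  fr <- pt_frame(x)[era %in% c("old", "new")]
  # per-SOC a-cells sum to the old-era PT total; a+c to each SOC's total
  expect_equal(sum(s$a), sum(fr$era == "old"))
  expect_equal(sum(s$a + s$c), nrow(fr))
  soc_tot <- fr[, .N, by = soc][order(soc)]
  expect_equal(s[order(event), a + c], soc_tot$N)
  # conservation: every row's cells sum to the frame total
  expect_true(all(s$a + s$b + s$c + s$d == nrow(fr)))

  # single SOC -> comparator event cells zero -> non-countable
  y <- toy_set()
  y$reactions[, soc := "Nervous system disorders"]
  y <- icsr_set(y$reports, y$drugs, y$reactions)
  s1 <- soc_scan(y)
  expect_false(s1$countable)
})

test_that("era scans exclude unclassified-era rows from both arms", {
  x <- toy_set()
  x$drugs[1, `:=`(era = "unclassified", substance = "Cannabidiol")]
  x <- icsr_set(x$reports, x$drugs, x$reactions)
  s <- suppressMessages(soc_scan(x))
  expect_equal(unique(s$a + s$b + s$c + s$d), 3)
})

test_that("seriousness scan is multi-label and unspecified stays in the denominator", {
  x <- toy_set()  # T1 carries death AND life_threatening; T3 unspecified
  s <- seriousness_scan(x)
  expect_equal(s[event == "death", a], 1)              # T1 (old arm)
  expect_equal(s[event == "life_threatening", a], 1)   # same PT counted again
  expect_equal(s[event == "death", c], 1)              # T4 (new arm)
  # all four PT rows stay in the frame: cells always sum to 4
  expect_true(all(s$a + s$b + s$c + s$d == 4))
  sd <- seriousness_scan(x, drop_unspecified = TRUE)
  expect_true(all(sd$a + sd$b + sd$c + sd$d == 3))

  # all-unspecified seriousness -> every criterion row non-countable
  y <- toy_set()
  y$reactions[, seriousness := "unspecified"]
  y <- icsr_set(y$reports, y$drugs, y$reactions)
  expect_true(all(!seriousness_scan(y)$countable))
})

test_that("outcome scan matches hand computation and partitions known outcomes", {
  x <- toy_set()
  s <- outcome_scan(x)
  # fatal vs rest by era: old arm has T2 recovered + T1 fatal; new arm
  # T3 recovered + T4 fatal -> table (1,1,1,1)
  f <- s[event == "fatal"]
  expect_equal(c(f$a, f$b, f$c, f$d), c(1, 1, 1, 1))
  expect_equal(f$ror, 1)
  # outcome a+c cells over categories partition PTs with known outcome
  fr <- pt_frame(x)
  expect_equal(sum(s$a + s$c) / 1L, sum(fr$outcome != "unspecified") *
                 nrow(s) / nrow(s))
  expect_equal(sum(s[, a + c]), sum(fr$outcome != "unspecified"))
})

test_that("empty strata give empty results, no error", {
  x <- toy_set()
  s <- outcome_scan(x, strata = "year=1999")
  expect_true(all(s$a + s$b + s$c + s$d == 0) || nrow(s) == 0)
  expect_s3_class(top_pt_table(x, 5, strata = "year=1999"), "data.table")
})

test_that("sudep_scan: zero-SUDEP data non-countable; substance cells sum to total", {
  x <- toy_set()
  s <- sudep_scan(x)
  expect_true(all(!s$countable))
  expect_setequal(unique(s$grouping),
                  c("era_old_vs_new", "subgroup_vs_rest", "substance_vs_rest"))

  # plant SUDEP rows in single-drug reports
  y <- toy_set()
  y$reactions[1:2, pt := "Sudden unexplained death in epilepsy"]
  y <- icsr_set(y$reports, y$drugs, y$reactions)
  s2 <- sudep_scan(y)
  per_sub <- s2[grouping == "substance_vs_rest"]
  expect_equal(sum(per_sub$a), 2)
  # custom PT list is honoured
  s3 <- sudep_scan(y, sudep_pts = "Sudden unexpected death in epilepsy")
  expect_true(all(s3$a == 0))
})

test_that("top_pt_table ranks with alphabetical tie-break and exact percent", {
  x <- toy_set()   # Seizure x2, Hepatotoxicity, Rash
  tp <- top_pt_table(x, 10)
  expect_equal(tp$pt[1], "Seizure")
  expect_equal(tp$count[1], 2L)
  expect_equal(tp$percent[1], 50)
  # tie between Hepatotoxicity and Rash -> alphabetical
  expect_equal(tp$pt[2:3], c("Hepatotoxicity", "Rash"))
  expect_equal(nrow(top_pt_table(x, 0)), 0L)
  expect_equal(nrow(top_pt_table(x, 99)), 3L)
})

test_that("yearly_soc_series zero-fills and is consistent with soc_scan", {
  x <- generate_dataset(sim_config(n_reports = 500, seed = 31))
  ys <- yearly_soc_series(x)
  fr <- pt_frame(x)
  # complete grid
  expect_equal(nrow(ys),
               data.table::uniqueN(fr$receipt_year) * data.table::uniqueN(fr$soc))
  # yearly totals conserved
  yr_tot <- fr[, .N, by = .(year = receipt_year)][order(year)]
  expect_equal(ys[, .(count = sum(count)), by = year][order(year)]$count,
               yr_tot$N)
  # column sums over years equal soc_scan totals (no unclassified era here
  # by construction of the default catalogue draw)
  s <- soc_scan(x)
  soc_tot <- ys[, .(count = sum(count)), by = soc][order(soc)]
  expect_equal(s[order(event), a + c], soc_tot$count)
})

test_that("scans are deterministic under permuted input row order", {
  x <- generate_dataset(sim_config(n_reports = 300, seed = 41))
  set.seed(99)
  perm <- function(dt) dt[sample(.N)]
  y <- icsr_set(perm(x$reports), perm(x$drugs), perm(x$reactions))
  strip <- function(r) {
    r <- as.data.table(r)
    data.table::setattr(r, "scan_spec", NULL)  # timestamp differs by design
    data.table::setattr(r, "class", c("data.table", "data.frame"))
    r
  }
  for (f in list(soc_scan, seriousness_scan, outcome_scan)) {
    expect_equal(strip(f(x)), strip(f(y)))
  }
  expect_equal(top_pt_table(x, 10), top_pt_table(y, 10))
})

test_that("stratified cells sum over a partitioning stratum to the unstratified cells", {
  x <- generate_dataset(sim_config(n_reports = 400, seed = 51))
  whole <- as.data.table(soc_scan(x))[, .(event, a, c)]
  parts <- lapply(c("male", "female", "unspecified"), function(sx)
    as.data.table(soc_scan(x, strata = paste0("sex=", sx)))[, .(event, a, c)])
  summed <- data.table::rbindlist(parts)[, .(a = sum(a), c = sum(c)),
                                         by = event][order(event)]
  merged <- merge(whole, summed, by = "event", all = TRUE)
  merged[is.na(merged)] <- 0
  expect_equal(merged$a.x, merged$a.y)
  expect_equal(merged$c.x, merged$c.y)
})

test_that("demographic_tests match the reference chi-square on a hand dataset", {
  x <- generate_dataset(sim_config(n_reports = 800, seed = 61))
  dt <- demographic_tests(x)
  expect_equal(dt$test, c("era_by_sex", "sudep_by_sex", "sudep_by_age"))
  # reproduce era_by_sex with an independent oracle
  fr <- pt_frame(x)[era %in% c("old", "new")]
  m <- table(fr$era, fr$sex)
  ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  expect_equal(dt[test == "era_by_sex", chi2], unname(ref$statistic))
  expect_equal(dt[test == "era_by_sex", dof], unname(ref$parameter))
  expect_equal(dt[test == "era_by_sex", n], sum(m))
})

test_that("era_by_sex p-values are approximately uniform under permuted sex labels", {
  x <- generate_dataset(sim_config(n_reports = 1200, seed = 71))
  fr <- pt_frame(x)[era %in% c("old", "new")]
  base_sex <- fr$sex
  set.seed(72)
  ps <- replicate(200, {
    m <- table(fr$era, sample(base_sex))
    chi_square_rxc(m)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("strata parser validates and composes", {
  s <- parse_strata("sex=female,age=18-64,year=2012:2021")
  expect_equal(s$sex, "female")
  expect_equal(s$age_group, "18-64")
  expect_equal(s$year, c(2012L, 2021L))
  expect_null(parse_strata(""))
  expect_error(parse_strata("planet=mars"), class = "pv_config_error")
  expect_error(parse_strata("year=20xx"), class = "pv_config_error")
})
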