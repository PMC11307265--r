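# reference_and_ingest: parsers, classification, SOC assignment, overview

test_that("parse_reaction_list handles the packed format", {
  r <- parse_reaction_list(
    "Seizure (n/a – Recovered/Resolved – Caused/Prolonged Hospitalisation)")
  expect_equal(nrow(r), 1L)
  expect_equal(r$pt, "Seizure")
  expect_equal(r$outcome, "recovered")
  expect_equal(r$seriousness, "hospitalisation")
  expect_true(is.na(r$duration))

  r2 <- parse_reaction_list("Rash (2d – Fatal – Results in Death; Life Threatening)")
  expect_equal(r2$outcome, "fatal")
  expect_setequal(strsplit(r2$seriousness, ";")[[1]],
                  c("death", "life_threatening"))
  expect_equal(r2$duration, "2d")

  expect_equal(nrow(parse_reaction_list("")), 0L)

  # missing sub-fields -> unspecified; bare PT is valid
  r3 <- parse_reaction_list("Somnolence")
  expect_equal(r3$outcome, "unspecified")
  expect_equal(r3$seriousness, "unspecified")
  expect_false(r3$malformed)
})

test_that("malformed entries are flagged with raw text preserved, unknown tokens warn", {
  r <- parse_reaction_list("Seizure (2d – Fatal – Results in Death,\nBroken (entry (n/a – x – y)")
  expect_equal(nrow(r), 2L)
  expect_true(any(r$malformed))
  expect_true(any(!is.na(r$raw)))

  expect_warning(r2 <- parse_reaction_list("Seizure (n/a – Exploded – )"),
                 "unknown outcome")
  expect_equal(r2$outcome, "unspecified")
})

test_that("parse_line_listing ingests the 3-row fixture", {
  f <- write_fixture_listing()
  x <- suppressMessages(parse_line_listing(f))
  expect_s3_class(x, "icsr_set")
  expect_equal(nrow(x$reports), 3L)
  expect_equal(nrow(x$drugs[report_id == "R2"]), 2L)
  expect_equal(nrow(x$reactions), 4L)
  expect_equal(x$reports[report_id == "R1", receipt_year], 2015L)
  expect_equal(x$reports[report_id == "R3", sex], "unspecified")
  expect_equal(x$reports[report_id == "R2", age_group], "65plus")
})

test_that("missing mandatory column is a configuration error naming it", {
  f <- tempfile(fileext = ".csv")
  fwrite(data.table(report_id = "R1", sex = "Male"), f)
  expect_error(parse_line_listing(f), "receipt_date",
               class = "pv_config_error")
})

test_that("empty file yields an empty dataset with a warning", {
  f <- tempfile(fileext = ".csv")
  writeLines("report_id,receipt_date,suspect_drugs,reaction_list", f)
  expect_warning(x <- parse_line_listing(f), "empty")
  expect_equal(nrow(x$reports), 0L)
})

test_that("rows with unparseable mandatory fields are rejected, not dropped silently", {
  f <- tempfile(fileext = ".csv")
  fwrite(data.table(
    report_id = c("A", "", "C", "A", "E"),
    receipt_date = c("2015-01-01", "2015-01-01", "not-a-date", "2016-01-01",
                     "2017-05-05"),
    suspect_drugs = c("Phenytoin", "Phenytoin", "Phenytoin", "Phenytoin", ""),
    reaction_list = rep("Seizure (n/a – Fatal – )", 5)), f, quote = TRUE)
  expect_warning(x <- suppressMessages(parse_line_listing(f)), "rejected")
  expect_equal(nrow(x$reports), 1L)
  expect_equal(nrow(x$rejects), 4L)
  expect_setequal(x$rejects$reason,
                  c("missing report_id", "unparseable receipt_date",
                    "duplicate report_id", "no suspect drugs"))
})

test_that("round trip write -> parse -> write is stable", {
  f <- write_fixture_listing()
  x <- suppressMessages(assign_soc(classify_drugs(parse_line_listing(f))))
  out1 <- tempfile(fileext = ".csv")
  write_line_listing(x, out1)
  y <- suppressMessages(assign_soc(classify_drugs(parse_line_listing(out1))))
  for (part in c("reports", "drugs")) {
    a <- data.table::setorderv(copy(x[[part]]), names(x[[part]]))
    b <- data.table::setorderv(copy(y[[part]]), names(y[[part]]))
    expect_equal(a, b, info = part)
  }
  ax <- x$reactions[order(report_id, pt), .(report_id, pt, soc, outcome, seriousness, duration)]
  ay <- y$reactions[order(report_id, pt), .(report_id, pt, soc, outcome, seriousness, duration)]
  expect_equal(ax, ay)
  # byte-identical second write
  out2 <- tempfile(fileext = ".csv")
  write_line_listing(y, out2)
  expect_identical(unname(tools::md5sum(out1)), unname(tools::md5sum(out2)))
})

test_that("gzip-compressed listings round trip", {
  f <- write_fixture_listing()
  x <- suppressMessages(parse_line_listing(f))
  gz <- tempfile(fileext = ".csv.gz")
  write_line_listing(x, gz)
  y <- suppressMessages(parse_line_listing(gz))
  expect_equal(nrow(y$reports), 3L)
  expect_equal(sort(y$reactions$pt), sort(x$reactions$pt))
})

test_that("classify_drugs resolves era and subgroup, folding salt forms", {
  f <- write_fixture_listing()
  x <- suppressMessages(classify_drugs(parse_line_listing(f)))
  d <- x$drugs
  expect_equal(d[substance == "Phenobarbital",
                 .(chemical_subgroup, era)],
               data.table(chemical_subgroup = "barbiturates", era = "old"))
  expect_equal(d[substance == "Brivaracetam", era], "new")
  expect_equal(d[substance == "Brivaracetam", chemical_subgroup],
               "other_antiepileptics")
  # salt folding: Sodium Valproate became Valproic acid
  expect_true("Valproic acid" %in% d$substance)
  expect_false("Sodium Valproate" %in% d$substance)
  expect_equal(d[substance == "Valproic acid", era], "old")
})

test_that("cannabidiol and unknown substances classify as unclassified", {
  cat <- default_atc_catalogue()
  expect_equal(cat[substance == "Cannabidiol", era], "unclassified")
  x <- toy_set()
  x$drugs[1, substance := "Mystery compound"]
  expect_warning(y <- classify_drugs(icsr_set(x$reports, x$drugs, x$reactions)),
                 "unclassified")
  expect_equal(y$drugs[substance == "Mystery compound", era], "unclassified")
})

test_that("assign_soc is total and idempotent", {
  rxn <- data.table(pt = c("Seizure", "Totally novel event"),
                    outcome = "unspecified", seriousness = "unspecified")
  expect_warning(out <- assign_soc(rxn), "unmapped")
  expect_equal(out$soc, c("Nervous system disorders", "Not Specified"))
  out2 <- suppressWarnings(assign_soc(out))
  expect_equal(out2$soc, out$soc)
})

test_that("summarize_reports counts, percentages, and empty strata", {
  x <- toy_set()
  s <- summarize_reports(x)
  expect_equal(s[section == "sex" & level == "female", count], 2L)
  expect_equal(s[section == "sex" & level == "female", percent], 50)
  # empty stratum present with 0 (0.00), no division error
  expect_equal(s[section == "sex" & level == "unspecified", .(count, percent)],
               data.table(count = 0L, percent = 0))
  expect_equal(s[section == "chemical_subgroup" & level == "barbiturates",
                 count], 2L)
  expect_equal(s[section == "total", count], 4L)
})

test_that("partition and totality invariants hold on simulated data", {
  x <- generate_dataset(sim_config(n_reports = 400, seed = 11))
  fr <- pt_frame(x)
  # era partition over attributed PT rows
  expect_equal(sum(fr$era == "old") + sum(fr$era == "new") +
                 sum(fr$era == "unclassified"), nrow(fr))
  # SOC totality: every record one soc; per-SOC counts sum to total
  expect_false(anyNA(fr$soc))
  expect_equal(sum(table(fr$soc)), nrow(fr))
  # outcome single-label partition
  expect_equal(sum(table(fr$outcome)), nrow(fr))
  expect_true(all(fr$outcome %in% outcome_levels()))
  # seriousness multi-label: criterion mentions >= records carrying any
  n_tokens <- sum(lengths(strsplit(fr$seriousness, ";", fixed = TRUE)))
  expect_gte(n_tokens, nrow(fr))
})

test_that("pt_frame attribution modes differ only for multi-drug reports", {
  f <- write_fixture_listing()
  x <- suppressMessages(assign_soc(classify_drugs(parse_line_listing(f))))
  all_susp <- pt_frame(x, "all_suspected")
  first <- pt_frame(x, "first_listed")
  # R2 has 2 drugs x 2 reactions -> 4 rows under all_suspected, 2 under first
  expect_equal(nrow(all_susp[report_id == "R2"]), 4L)
  expect_equal(nrow(first[report_id == "R2"]), 2L)
  expect_equal(nrow(all_susp[report_id == "R1"]),
               nrow(first[report_id == "R1"]))
})

test_that("filter_years restricts to the inclusive window", {
  x <- toy_set()
  y <- filter_years(x, c(2014, 2014))
  expect_equal(nrow(y$reports), 2L)
  expect_true(all(y$reports$receipt_year == 2014L))
})
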