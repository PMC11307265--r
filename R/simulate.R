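# Seeded synthetic ICSR generator. The generator emulates the statistical
# structure the scans assume -- report demographics, 1..k suspected drugs,
# 1..m reaction PTs with multi-label seriousness and single-label outcome,
# and planted drug-event odds ratios -- not the full joint distribution of
# any real database.

#' Per-draw event probability for a planted odds ratio
#'
#' Solves `p/(1-p) = rho * q/(1-q)` for the exposed-arm per-draw event
#' probability `p`, so that the PT-level 2x2 odds ratio converges to the
#' planted `rho` as the sample grows.
#'
#' @param base_prob Baseline per-draw probability `q`, `0 < q < 1`.
#' @param target_or Planted odds ratio `rho > 0`.
#' @return The exposed per-draw probability `p`.
#' @export
#' @examples
#' solve_event_prob(0.1, 4)  # 4/13
solve_event_prob <- function(base_prob, target_or) {
  .pv_assert(is.numeric(base_prob) && base_prob > 0 && base_prob < 1,
             "base_prob must be in (0, 1)")
  .pv_assert(is.numeric(target_or) && target_or > 0 && is.finite(target_or),
             "target_or must be a positive finite number")
  odds <- target_or * base_prob / (1 - base_prob)
  p <- odds / (1 + odds)
  .pv_assert(p < 1, "implied exposed probability >= 1")
  p
}

# default PT vocabulary: the bundled synthetic map with reporting-frequency
# weights for the most common terms (SUDEP kept rare), remainder uniform
.default_vocabulary <- function() {
  map <- default_meddra_map()
  top <- c("Seizure" = 0.0349, "Drug ineffective" = 0.0246,
           "Somnolence" = 0.0132, "Dizziness" = 0.0129,
           "Off label use" = 0.0114, "Rash" = 0.0103, "Pain" = 0.0098,
           "Fatigue" = 0.0095, "Toxicity to various agents" = 0.0093,
           "Drug interaction" = 0.0093,
           "Sudden unexplained death in epilepsy" = 0.0004)
  prob <- rep(NA_real_, nrow(map))
  m <- match(names(top), map$pt)
  prob[m] <- unname(top)
  rest <- is.na(prob)
  prob[rest] <- (1 - sum(top)) / sum(rest)
  data.table::data.table(pt = map$pt, soc = map$soc, prob = prob)
}

#' Simulation configuration
#'
#' Validated parameter bundle for [generate_dataset()]. Defaults emulate a
#' decade of antiseizure-medication reporting: two-thirds of reaction
#' volume on new-era drugs, female-majority reporting, a 18--64-dominated
#' age profile, about 3.8 PTs per report, and rising yearly volume.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer RNG seed.
#' @param era_probs Named probabilities over marketing eras (default
#'   `c(old = 0.355, new = 0.645)`).
#' @param p_second_drug Probability a report lists a second suspected drug
#'   (drawn from the same era; default 0.1).
#' @param sex_probs,age_probs,reporter_probs,region_probs Named
#'   probability vectors over the respective vocabularies.
#' @param years Integer vector of receipt years.
#' @param year_weights Sampling weights over `years` (normalised
#'   internally).
#' @param lambda_pts Poisson mean of the *extra* PT count per report: a
#'   report draws `1 + Poisson(lambda_pts)` PTs (then deduplicates).
#' @param pt_vocabulary data.table `pt`, `soc`, `prob` (probabilities sum
#'   to 1); default built from the bundled synthetic map.
#' @param seriousness_probs Named per-criterion Bernoulli probabilities
#'   (independent draws; an empty set becomes `unspecified`).
#' @param outcome_probs Named probabilities over outcome categories.
#' @param planted_signals List of planted drug-event signals, each
#'   `list(event_pt =, exposure = "era=old" (or subgroup=/substance=),
#'   target_or =)`.
#' @param catalogue ATC catalogue supplying the substance pool and
#'   per-substance sampling weights.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_reports = 1000L,
                       seed = 1L,
                       era_probs = c(old = 0.355, new = 0.645),
                       p_second_drug = 0.1,
                       sex_probs = c(male = 0.3861, female = 0.5383,
                                     unspecified = 0.0756),
                       age_probs = c("0-2" = 0.0324, "3-17" = 0.0896,
                                     "18-64" = 0.477, "65plus" = 0.1818,
                                     "unspecified" = 0.2192),
                       reporter_probs = c(healthcare_professional = 0.7227,
                                          non_healthcare_professional = 0.27,
                                          unspecified = 0.0073),
                       region_probs = c(EEA = 0.3587, non_EEA = 0.6407,
                                        unspecified = 0.0006),
                       years = 2012:2021,
                       year_weights = c(86654, 92612, 94280, 89579, 82233,
                                        120695, 95674, 120163, 118565, 150689),
                       lambda_pts = 2.8,
                       pt_vocabulary = NULL,
                       seriousness_probs = c(other_medically_important = 0.597,
                                             hospitalisation = 0.349,
                                             congenital_anomaly = 0.041,
                                             disabling = 0.035,
                                             life_threatening = 0.046,
                                             death = 0.056),
                       outcome_probs = c(fatal = 0.0396,
                                         not_recovered = 0.1311,
                                         recovered = 0.2095,
                                         recovered_with_sequelae = 0.0047,
                                         recovering = 0.0839,
                                         unspecified = 0.5312),
                       planted_signals = list(),
                       catalogue = default_atc_catalogue()) {
  .pv_assert(is.numeric(n_reports) && n_reports >= 1,
             "n_reports must be >= 1", class = "pv_config_error")
  .pv_assert(is.numeric(lambda_pts) && lambda_pts > 0,
             "lambda_pts must be > 0", class = "pv_config_error")
  .pv_assert(is.numeric(p_second_drug) && p_second_drug >= 0 &&
               p_second_drug <= 1, "p_second_drug must be in [0, 1]",
             class = "pv_config_error")
  .pv_check_probs(era_probs, "era_probs")
  .pv_assert(all(names(era_probs) %in% pv_era_levels),
             "era_probs names must be era levels", class = "pv_config_error")
  .pv_check_probs(sex_probs, "sex_probs")
  .pv_check_probs(age_probs, "age_probs")
  .pv_check_probs(reporter_probs, "reporter_probs")
  .pv_check_probs(region_probs, "region_probs")
  .pv_check_probs(outcome_probs, "outcome_probs")
  .pv_assert(length(years) == length(year_weights) && all(year_weights >= 0),
             "year_weights must match years", class = "pv_config_error")
  .pv_assert(all(seriousness_probs >= 0 & seriousness_probs <= 1) &&
               all(names(seriousness_probs) %in% seriousness_levels()),
             "seriousness_probs must be named per-criterion probabilities",
             class = "pv_config_error")
  if (is.null(pt_vocabulary)) pt_vocabulary <- .default_vocabulary()
  pt_vocabulary <- data.table::as.data.table(pt_vocabulary)
  .pv_assert(all(c("pt", "soc", "prob") %in% names(pt_vocabulary)),
             "pt_vocabulary needs columns pt, soc, prob",
             class = "pv_config_error")
  .pv_check_probs(pt_vocabulary$prob, "pt_vocabulary$prob")

  for (s in planted_signals) {
    .pv_assert(all(c("event_pt", "exposure", "target_or") %in% names(s)),
               "each planted signal needs event_pt, exposure, target_or",
               class = "pv_config_error")
    .pv_assert(s$event_pt %in% pt_vocabulary$pt,
               "planted signal PT not in vocabulary: ", s$event_pt,
               class = "pv_config_error")
    ex <- .parse_exposure(s$exposure)
    ok <- switch(ex$field,
                 era = ex$value %in% names(era_probs),
                 subgroup = ex$value %in% catalogue$chemical_subgroup,
                 substance = ex$value %in% catalogue$substance)
    .pv_assert(isTRUE(ok), "planted signal exposure not in config: ",
               s$exposure, class = "pv_config_error")
    q <- pt_vocabulary[pt == s$event_pt, prob]
    solve_event_prob(q, s$target_or)  # errors early if unattainable
  }

  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 era_probs = era_probs, p_second_drug = p_second_drug,
                 sex_probs = sex_probs, age_probs = age_probs,
                 reporter_probs = reporter_probs, region_probs = region_probs,
                 years = as.integer(years),
                 year_weights = year_weights / sum(year_weights),
                 lambda_pts = lambda_pts, pt_vocabulary = pt_vocabulary,
                 seriousness_probs = seriousness_probs,
                 outcome_probs = outcome_probs,
                 planted_signals = planted_signals, catalogue = catalogue),
            class = "sim_config")
}

# "era=old" / "subgroup=hydantoins" / "substance=Valproic acid"
.parse_exposure <- function(x) {
  if (is.list(x)) return(x)
  kv <- strsplit(x, "=", fixed = TRUE)[[1]]
  .pv_assert(length(kv) == 2L && kv[1] %in% c("era", "subgroup", "substance"),
             "exposure must be 'era=..', 'subgroup=..' or 'substance=..'",
             class = "pv_config_error")
  list(field = kv[1], value = kv[2])
}

#' Generate a synthetic ICSR dataset
#'
#' Fully seeded and reproducible: each report draws era, substance(s),
#' demographics, a PT count (`1 + Poisson(lambda)`), PTs (with per-draw
#' event probabilities adjusted for planted signals in exposed reports,
#' then deduplicated within the report), and a seriousness set plus an
#' outcome per PT. The RNG state of the caller is restored on exit.
#'
#' @param config A [sim_config()].
#' @return An [icsr_set()] with drugs classified and SOCs assigned; the
#'   planted signals are attached as `attr(, "truth")`.
#' @export
generate_dataset <- function(config) {
  .pv_assert(inherits(config, "sim_config"),
             "config must be a sim_config", class = "pv_config_error")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_reports
  cat_tab <- config$catalogue
  rid <- sprintf("SIM%07d", seq_len(n))

  era <- sample(names(config$era_probs), n, TRUE, config$era_probs)
  draw_substance <- function(eras) {
    out <- character(length(eras))
    for (ev in unique(eras)) {
      pool <- cat_tab[cat_tab$era == ev]
      .pv_assert(nrow(pool) > 0, "no catalogue substances with era=", ev,
                 class = "pv_config_error")
      idx <- which(eras == ev)
      out[idx] <- sample(pool$substance, length(idx), TRUE, pool$weight)
    }
    out
  }
  drug1 <- draw_substance(era)
  second <- runif(n) < config$p_second_drug
  drug2 <- rep(NA_character_, n)
  drug2[second] <- draw_substance(era[second])

  reports <- data.table::data.table(
    report_id = rid,
    receipt_year = sample(config$years, n, TRUE, config$year_weights),
    sex = sample(names(config$sex_probs), n, TRUE, config$sex_probs),
    age_group = sample(names(config$age_probs), n, TRUE, config$age_probs),
    reporter = sample(names(config$reporter_probs), n, TRUE,
                      config$reporter_probs),
    region = sample(names(config$region_probs), n, TRUE, config$region_probs))

  drugs <- data.table::rbindlist(list(
    data.table::data.table(report_id = rid, substance = drug1),
    data.table::data.table(report_id = rid[second],
                           substance = drug2[second])))

  # exposure pattern per report across planted signals
  vocab <- config$pt_vocabulary
  sig <- config$planted_signals
  exposed <- matrix(FALSE, n, length(sig))
  if (length(sig)) {
    sub1 <- cat_tab$chemical_subgroup[match(drug1, cat_tab$substance)]
    sub2 <- cat_tab$chemical_subgroup[match(drug2, cat_tab$substance)]
    for (j in seq_along(sig)) {
      ex <- .parse_exposure(sig[[j]]$exposure)
      exposed[, j] <- switch(ex$field,
        era = era == ex$value,
        subgroup = (!is.na(sub1) & sub1 == ex$value) |
          (!is.na(sub2) & sub2 == ex$value),
        substance = drug1 == ex$value |
          (!is.na(drug2) & drug2 == ex$value))
    }
  }
  pattern <- if (length(sig))
    apply(exposed, 1, function(z) paste(as.integer(z), collapse = "")) else
      rep("", n)

  # per-pattern adjusted vocabulary probabilities: the planted PT's
  # per-draw probability moves to solve_event_prob(q, rho); the remaining
  # mass is rescaled proportionally
  k_pts <- 1L + rpois(n, config$lambda_pts)
  rxn_report <- rep(rid, k_pts)
  rxn_pattern <- rep(pattern, k_pts)
  pt_idx <- integer(length(rxn_report))
  for (g in unique(pattern)) {
    prob <- vocab$prob
    if (length(sig)) {
      active <- which(strsplit(g, "")[[1]] == "1")
      for (j in active) {
        ev_i <- match(sig[[j]]$event_pt, vocab$pt)
        q <- prob[ev_i]
        p <- solve_event_prob(q, sig[[j]]$target_or)
        prob[-ev_i] <- prob[-ev_i] * (1 - p) / (1 - q)
        prob[ev_i] <- p
      }
    }
    gi <- which(rxn_pattern == g)
    pt_idx[gi] <- sample.int(nrow(vocab), length(gi), TRUE, prob)
  }

  reactions <- unique(data.table::data.table(report_id = rxn_report,
                                             pt = vocab$pt[pt_idx]))
  reactions[, soc := vocab$soc[match(pt, vocab$pt)]]
  nn <- nrow(reactions)

  crit <- sort(setdiff(names(config$seriousness_probs), "unspecified"))
  ser <- rep("", nn)
  for (cr in crit) {
    hit <- runif(nn) < config$seriousness_probs[[cr]]
    ser <- paste0(ser, data.table::fifelse(hit, paste0(cr, ";"), ""))
  }
  ser <- sub(";$", "", ser)
  ser[ser == ""] <- "unspecified"
  reactions[, seriousness := ser]
  reactions[, outcome := sample(names(config$outcome_probs), nn, TRUE,
                                config$outcome_probs)]
  reactions[, duration := NA_character_]
  reactions[, malformed := FALSE]

  out <- icsr_set(reports, drugs, reactions)
  out <- suppressWarnings(classify_drugs(out, cat_tab))
  data.table::setattr(out, "truth",
                      list(seed = config$seed, planted_signals = sig))
  out
}

#' Write the planted-truth sidecar for a simulated dataset
#'
#' @param config A [sim_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(config, path) {
  truth <- list(seed = config$seed, n_reports = config$n_reports,
                planted_signals = lapply(config$planted_signals, function(s) {
                  ex <- .parse_exposure(s$exposure)
                  list(event_pt = s$event_pt, exposure_field = ex$field,
                       exposure_value = ex$value, target_or = s$target_or)
                }))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
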