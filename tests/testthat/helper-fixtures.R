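suppressMessages(library(data.table))

# write a small line-listing fixture; returns the path
write_fixture_listing <- function(path = tempfile(fileext = ".csv")) {
  rows <- data.table(
    report_id = c("R1", "R2", "R3"),
    receipt_date = c("2015-03-02", "2018-11-20", "2021-01-05"),
    sex = c("Male", "Female", "Not Specified"),
    age_group = c("18-64 Years", "65 Years Or Older", "3-17 Years"),
    reporter_qualification = c("Healthcare Professional",
                               "Non Healthcare Professional",
                               "Healthcare Professional"),
    region = c("European Economic Area", "Non European Economic Area",
               "Not Specified"),
    suspect_drugs = c("Phenobarbital", "Sodium Valproate; Lamotrigine",
                      "Brivaracetam"),
    reaction_list = c(
      "Seizure (n/a – Recovered/Resolved – Caused/Prolonged Hospitalisation)",
      paste0("Rash (2d – Fatal – Results in Death; Life Threatening),\n",
             "Hepatotoxicity (n/a – Recovering/Resolving – Other Medically Important Condition)"),
      "Dizziness (1d – Recovered/Resolved – )"))
  fwrite(rows, path, quote = TRUE)
  path
}

# hand-built tiny dataset for hand-checked scan arithmetic:
# 4 single-drug, single-reaction reports
toy_set <- function() {
  reports <- data.table(
    report_id = paste0("T", 1:4), receipt_year = c(2014L, 2014L, 2015L, 2015L),
    sex = c("male", "female", "male", "female"),
    age_group = "18-64", reporter = "healthcare_professional", region = "EEA")
  drugs <- data.table(
    report_id = paste0("T", 1:4),
    substance = c("Phenobarbital", "Phenobarbital", "Levetiracetam",
                  "Levetiracetam"),
    atc_code = c("N03AA", "N03AA", "N03AX", "N03AX"),
    chemical_subgroup = c("barbiturates", "barbiturates",
                          "other_antiepileptics", "other_antiepileptics"),
    era = c("old", "old", "new", "new"))
  reactions <- data.table(
    report_id = paste0("T", 1:4),
    pt = c("Seizure", "Hepatotoxicity", "Seizure", "Rash"),
    soc = c("Nervous system disorders", "Hepatobiliary disorders",
            "Nervous system disorders", "Skin and subcutaneous tissue disorders"),
    outcome = c("fatal", "recovered", "recovered", "fatal"),
    seriousness = c("death;life_threatening", "hospitalisation",
                    "unspecified", "death"),
    duration = NA_character_, malformed = FALSE)
  icsr_set(reports, drugs, reactions)
}

# closed-form expected realized 2x2 under the generator's dedup:
# K = 1 + Poisson(lambda) PT draws per report, unique PTs kept.
# Returns expected OR for a planted signal at PT index ev_i.
oracle_expected_or <- function(vocab_prob, ev_i, rho, lambda,
                               soc_idx = NULL) {
  G <- function(s) s * exp(lambda * (s - 1))  # pgf of K at s
  q <- vocab_prob[ev_i]
  p <- solve_event_prob(q, rho)
  pe <- vocab_prob * (1 - p) / (1 - q)
  pe[ev_i] <- p
  pu <- vocab_prob
  ev <- if (is.null(soc_idx)) ev_i else soc_idx
  ea <- sum(1 - G(1 - pe[ev]));  eb <- sum(1 - G(1 - pe[-ev]))
  ec <- sum(1 - G(1 - pu[ev]));  ed <- sum(1 - G(1 - pu[-ev]))
  (ea * ed) / (eb * ec)
}

# the printed old-vs-new per-SOC cells used by the acceptance fixtures:
# a = old-era PTs in the SOC, c = new-era PTs in the SOC
published_soc_cells <- function() {
  data.table(
    event = c("Blood and lymphatic system disorders",
              "Congenital, familial and genetic disorders",
              "Hepatobiliary disorders", "Cardiac disorders",
              "Investigations", "Surgical and medical procedures"),
    a = c(8676, 11069, 6111, 6253, 26551, 1535),
    c = c(7538, 5575, 5490, 12454, 34183, 4943),
    ror_2dp = c(2.12, 3.69, 2.04, 0.91, 1.45, 0.56))
}

published_era_totals <- function() c(old = 372660, new = 678482)

# margin-replicated dataset carrying the six published SOC cells plus a
# per-era remainder so era totals are exact
replica_set <- function(reactions_per_report = 5000L) {
  cells <- published_soc_cells()
  totals <- published_era_totals()
  dt <- rbind(
    data.table(exposure = "old", event = cells$event, count = cells$a),
    data.table(exposure = "new", event = cells$event, count = cells$c),
    data.table(exposure = c("old", "new"), event = "Other SOCs (remainder)",
               count = c(totals["old"] - sum(cells$a),
                         totals["new"] - sum(cells$c))))
  replicate_margins(dt, exposure_totals = totals,
                    reactions_per_report = reactions_per_report)
}
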