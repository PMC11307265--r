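# Controlled vocabularies shared by the parser, the generator and the scans.
# Canonical tokens are lower_snake; display labels follow the EudraVigilance
# public-interface wording so that written listings look like real exports.

pv_sex_levels <- c("male", "female", "unspecified")

pv_age_levels <- c("0-2", "3-17", "18-64", "65plus", "unspecified")

pv_reporter_levels <- c("healthcare_professional", "non_healthcare_professional",
                        "unspecified")

pv_region_levels <- c("EEA", "non_EEA", "unspecified")

pv_era_levels <- c("old", "new", "unclassified")

pv_subgroup_levels <- c("barbiturates", "benzodiazepines", "carboxamides",
                        "fatty_acid_derivatives", "hydantoins",
                        "other_antiepileptics", "oxazolidines", "succinimides")

#' Seriousness criteria recognised by the package
#'
#' The six regulatory seriousness criteria (multi-label: one reaction may
#' carry several) plus the `unspecified` placeholder used when a reaction
#' reports no criterion.
#'
#' @return Character vector of canonical seriousness tokens.
#' @export
seriousness_levels <- function() {
  c("other_medically_important", "hospitalisation", "congenital_anomaly",
    "disabling", "life_threatening", "death", "unspecified")
}

#' Outcome categories recognised by the package
#'
#' Reaction outcome is single-label: exactly one of the five resolution
#' statuses, or `unspecified`.
#'
#' @return Character vector of canonical outcome tokens.
#' @export
outcome_levels <- function() {
  c("fatal", "not_recovered", "recovered", "recovered_with_sequelae",
    "recovering", "unspecified")
}

# display label <-> canonical token tables ----------------------------------

.pv_seriousness_labels <- c(
  other_medically_important = "Other Medically Important Condition",
  hospitalisation           = "Caused/Prolonged Hospitalisation",
  congenital_anomaly        = "Congenital Anomaly",
  disabling                 = "Disabling",
  life_threatening          = "Life Threatening",
  death                     = "Results in Death",
  unspecified               = "Not Specified/Unknown"
)

.pv_outcome_labels <- c(
  fatal                   = "Fatal",
  not_recovered           = "Not Recovered/Not Resolved",
  recovered               = "Recovered/Resolved",
  recovered_with_sequelae = "Recovered/Resolved With Sequelae",
  recovering              = "Recovering/Resolving",
  unspecified             = "Unknown"
)

.pv_sex_labels <- c(male = "Male", female = "Female", unspecified = "Not Specified")

.pv_age_labels <- c(`0-2` = "0-2 Years", `3-17` = "3-17 Years",
                    `18-64` = "18-64 Years", `65plus` = "65 Years Or Older",
                    unspecified = "Not Specified")

.pv_reporter_labels <- c(healthcare_professional = "Healthcare Professional",
                         non_healthcare_professional = "Non Healthcare Professional",
                         unspecified = "Not Specified")

.pv_region_labels <- c(EEA = "European Economic Area",
                       non_EEA = "Non European Economic Area",
                       unspecified = "Not Specified")

# Decode a free-text token to a canonical level. Matching is case-insensitive
# against both the canonical token and its display label; extra aliases cover
# spellings seen in public line listings. Unknown tokens become "unspecified"
# (with the caller deciding whether to warn), never an error.
.pv_decode <- function(x, labels, aliases = character()) {
  lut <- c(
    stats::setNames(names(labels), tolower(names(labels))),
    stats::setNames(names(labels), tolower(unname(labels))),
    aliases
  )
  key <- tolower(trimws(x))
  out <- lut[key]
  out[is.na(out) | key == "" | key == "n/a"] <- NA_character_
  unname(out)
}

.pv_sex_aliases <- c("m" = "male", "f" = "female", "not specified" = "unspecified",
                     "unknown" = "unspecified")

.pv_age_aliases <- c(
  "0-2 years" = "0-2", "0–2 years" = "0-2",
  "2 years or under" = "0-2",
  "3-17 years" = "3-17", "3–17 years" = "3-17", "2-17 years" = "3-17",
  "18-64 years" = "18-64", "18–64 years" = "18-64",
  ">64" = "65plus", "> 64" = "65plus", "over 64" = "65plus",
  "65 years or older" = "65plus", "65+" = "65plus",
  "not specified" = "unspecified", "unknown" = "unspecified"
)

.pv_reporter_aliases <- c("hcp" = "healthcare_professional",
                          "non hcp" = "non_healthcare_professional",
                          "non-healthcare professional" = "non_healthcare_professional",
                          "not specified" = "unspecified")

.pv_region_aliases <- c("eea" = "EEA", "non eea" = "non_EEA",
                        "non-eea" = "non_EEA",
                        "not specified" = "unspecified")

.pv_outcome_aliases <- c("recovered/resolved with sequelae" = "recovered_with_sequelae",
                         "unknown" = "unspecified", "not specified" = "unspecified",
                         "not specified/unknown" = "unspecified")

.pv_serious_aliases <- c("other medically important" = "other_medically_important",
                         "caused/prolonged hospitalization" = "hospitalisation",
                         "results in death" = "death",
                         "not specified" = "unspecified",
                         "unknown" = "unspecified")
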