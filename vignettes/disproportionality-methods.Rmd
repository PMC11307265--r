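---
title: "Disproportionality methods in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

# The model and its assumptions

Spontaneous-report databases have no exposure denominator: a drug–event
pair can only be judged against the reporting behaviour of the rest of the
database. `pvsignal` implements the standard frequentist disproportionality
toolkit on the 2×2 table (a, b, c, d) = (exposure group with event,
without event; comparator with, without):

* ROR = (a·d)/(b·c), Woolf CI `exp(log(ROR) ± z·√(1/a+1/b+1/c+1/d))`,
  z = qnorm(0.975) = 1.959964;
* PRR = [a/(a+b)]/[c/(c+d)], CI `exp(log(PRR) ± z·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`;
* uncorrected Pearson χ² with upper-tail p (Yates behind a flag);
* the EudraVigilance SDR rules: (PRR CI lower ≥ 1 AND a ≥ 3), and
  (PRR > 2 AND χ² > 4), with weak/strict inequalities exactly as the
  regulatory wording states them — the boundary cases PRR = 2 and χ² = 4
  do **not** fire, a = 3 and CI lower = 1 do.

The implicit assumptions are those of all disproportionality work: reports
are exchangeable within arms, reporting propensity differences between
arms act multiplicatively on all events alike, and a PT-occurrence is the
natural counting unit when the export is a per-drug line listing. None of
these are tested by the package; they are what the statistics *mean*.

## Counting unit and attribution

Line listings arrive one row per report, but a report carries several PTs
and possibly several suspected drugs. Scans default to `unit = "pt"`
(PT-occurrence counts; demographics summaries use report counts), and to
`attribution = "all_suspected"`: every PT is credited to every suspected
drug in its report, matching the semantics of per-drug line listings where
the same report appears once per drug. `attribution = "first_listed"` is
available for sensitivity analyses; whether a source database deduplicated
multi-drug reports is usually unknowable from the export alone, so both
behaviours are first-class.

## Era comparisons

The bundled ATC N03A catalogue labels each substance old (marketed before
1990) or new. Cannabidiol is deliberately `era = "unclassified"` — it
belongs to neither conventional list — and era scans drop unclassified-era
rows from *both* arms, with a logged count. Substance names fold
case-insensitively through a synonym table ("Sodium Valproate" and
"Valproic acid" are one substance). ATC codes are bundled at subgroup
level (N03AA…N03AX): the seven-character codes belong to the licensed ATC
index and add nothing to the analysis.

## Seriousness and outcome

Seriousness is a **set** per reaction (one PT may be simultaneously
life-threatening and fatal); the seriousness scan is therefore multi-label:
a PT carrying k criteria contributes to k event rows, and criterion totals
may legitimately exceed the PT total. Outcome is single-label. PTs with
wholly unspecified seriousness or outcome stay in the b/d cells by default
(`drop_unspecified = TRUE` excludes them): removing them would silently
change every denominator, and public listings do carry a
"not specified/unknown" bucket alongside the named criteria.

## Confidence intervals: a deliberate non-goal

Published per-SOC tables of this kind often print CIs roughly half the
width of the Woolf interval, without stating the convention. `pvsignal`
reports the Woolf interval only, and the package's own validation targets
are **point** RORs; no printed CI bound is treated as a reproduction
target. Zero cells yield "not countable" (N/C) results rather than errors,
mirroring reporting practice; `correction = "haldane"` (+0.5 on all cells)
is opt-in.

## Multiplicity

Scans report raw p-values — the screening tradition in this field applies
no multiplicity correction, and an SDR flag is a triage device, not a
confirmatory test. `bh_adjust()` provides Benjamini–Hochberg step-up
adjustment as an explicit opt-in for users who want FDR control across a
scan.

# Demographic dependence tests

`demographic_tests()` fixes two conventions that reproduce standard
reported values: the era × sex test runs on PT counts *including* the
unspecified-sex column (2×3, dof 2), while the SUDEP × sex test runs on
report counts *excluding* unspecified sex (2×2, dof 1). The SUDEP × age
test (2×5) is provided in shape; with five age strata and rare events its
value is sensitive to the unprintable underlying cross-table, so it is not
a validation target.

# The synthetic generator's stated world

`sim_config()` defaults describe a decade of ASM reporting:

| parameter | default | meaning |
|---|---|---|
| `era_probs` | old 0.355 / new 0.645 | share of reaction volume by era |
| `sex_probs` | m 0.3861 / f 0.5383 / unspec 0.0756 | report-level sex mix |
| `age_probs` | 0.0324 / 0.0896 / 0.477 / 0.1818 / 0.2192 | five age bins |
| `reporter_probs` | HCP 0.7227 | healthcare-professional share |
| `year_weights` | rising, 2012–2021 | yearly reporting volume |
| `lambda_pts` | 2.8 | mean *extra* PTs per report (1 + Poisson) |
| `p_second_drug` | 0.1 | polytherapy share (second same-era drug) |
| `seriousness_probs` | 0.597/0.349/0.041/0.035/0.046/0.056 | independent Bernoulli per criterion |
| `outcome_probs` | 0.0396/…/0.5312 | single draw over six categories |

Substance draws within an era are weighted by the catalogue's bundled
reporting-frequency weights. Seriousness criteria are sampled as
independent Bernoullis and an empty set becomes `unspecified` — this
reproduces the overlapping-criterion property (criterion totals sum above
the PT count) without modelling criterion correlations. These defaults are
the generator's stated world; tests never tune them toward a desired
outcome.

What the generator does **not** emulate: duplicate reports, secular
coding drift, drug–drug interaction structure, correlation between
seriousness criteria, or region-specific reporting cultures. A green
recovery test therefore establishes that the pipeline's arithmetic is
faithful, not that any real database satisfies the model.

## Planted signals and the deduplication oracle

A planted signal (event PT, exposure, target odds ratio ρ) adjusts the
per-draw probability of the event PT in exposed reports to
`solve_event_prob(q, ρ)`, the solution of p/(1−p) = ρ·q/(1−q), rescaling
the remaining vocabulary proportionally. PT draws are with replacement and
then deduplicated within a report (a listing names a PT once), which
shrinks the realized PT-level odds ratio below ρ as λ grows: at the
default λ = 2.8 and the default vocabulary, ρ = 3 realizes ≈ 2.84.

Recovery tests therefore compare the estimated log-ROR against a
closed-form independent oracle rather than against ρ naively: with
K = 1 + Poisson(λ) draws and per-draw probability vector p, the expected
realized presence of PT j in a report is 1 − G(1 − p_j), where
G(s) = s·e^{λ(s−1)} is the probability generating function of K; expected
cells (and their OR) follow by summation. The assertion is
|log ROR̂ − log OR_oracle| < 3 Woolf SE. One RNG stream drives the whole
generator (vectorised; no per-report sub-streams — there is no parallel
generation path to keep order-independent), and byte-identical output
under a fixed seed is tested.

## The margin replicator

`replicate_margins()` is the deterministic counterpart: given (exposure,
event, count) cells — e.g. published per-SOC counts with per-era totals —
it constructs a dataset whose PT-level counts equal the cells *exactly*
(no sampling), erroring on inconsistent margins with the violated sum
named. The acceptance tests run the real scan machinery over such
replicas, so published point statistics are reproduced by the same code
path users run, not by a formula shortcut.

# Numerical and formatting choices

* Report output rounds half-up to two decimals (`round_half_up`),
  matching regulatory-table convention; all stored values keep full
  precision.
* p-values display as "<0.0001" below 10⁻⁴ in printed output but are
  stored exactly.
* Scan rows are ordered by ascending exposure then event label, and
  result files omit timestamps, so repeated runs are byte-identical.
* Unknown vocabulary tokens (a novel outcome label, an unmapped PT, an
  uncatalogued substance) map to `unspecified` / `"Not Specified"` /
  `era = "unclassified"` with logged warnings — ingestion is total, and
  nothing is silently dropped.
* The packed reaction format is genuinely ambiguous for a bare PT ending
  in a parenthesized phrase with no sub-field block (it will be read as a
  sub-field block); the package's own writer always emits the sub-field
  block, so round trips are exact. Entries whose PT has unbalanced
  parentheses are flagged `malformed` with raw text preserved.

# Known limitations

* The bundled PT→SOC map is a small synthetic stand-in (MedDRA is
  licensed); real analyses must supply their own map.
* Only frequentist disproportionality: no IC/BCPNN or EBGM/MGPS, no
  time-to-onset, no duplicate detection.
* Subgroup-level scans inherit all reporting biases of spontaneous data;
  an SDR flag is not a causal claim.
* Published 2×2 margins of the kind replicated here can carry small
  internal inconsistencies (a gender breakdown summing two off its stated
  total); the package reports what the supplied data give and never
  reconciles totals silently.
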