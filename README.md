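# pvsignal

Disproportionality signal detection for spontaneous adverse-event reports,
with bundled reference tables for the ATC N03A antiseizure medications
(ASMs).

## What problem this solves, and for whom

Pharmacovigilance databases such as EudraVigilance collect individual case
safety reports (ICSRs): one spontaneous report per patient, naming one or
more suspected drugs and one or more adverse reactions coded as MedDRA
preferred terms (PTs). Because there is no denominator of drug users,
safety signals are screened by *disproportionality*: is a drug–event pair
reported more often than the rest of the database would predict?

`pvsignal` is for pharmacoepidemiologists and drug-safety analysts who work
with line-listing exports of such reports. It covers the full desk
workflow:

* **Ingest** delimited line listings (one row per report, a packed
  per-reaction cell carrying PT / duration / outcome / seriousness),
  normalising every field to a controlled vocabulary and rejecting — never
  silently dropping — unparseable rows.
* **Classify** suspected drugs against an ATC N03A catalogue (chemical
  subgroup; "old" era = marketed before 1990 vs "new"), and map PTs to
  their primary system organ class (SOC).
* **Test** drug–event pairs on 2×2 contingency tables, with composable
  scan stages over SOCs, seriousness criteria, outcomes, SUDEP (sudden
  unexpected death in epilepsy), yearly trends and demographics.
* **Simulate** seeded synthetic datasets with planted odds ratios, so
  every stage is testable without access to any real database.

## The statistics

For a drug (or drug group) *D* and event *E*, reports are pooled into

|            | E     | not E |
|------------|-------|-------|
| D          | a     | b     |
| comparator | c     | d     |

* **Reporting odds ratio** ROR = (a·d)/(b·c), with the Woolf (log-normal)
  95% CI: exp(ln ROR ± 1.959964·√(1/a + 1/b + 1/c + 1/d)).
* **Proportional reporting ratio** PRR = [a/(a+b)] / [c/(c+d)], with CI
  exp(ln PRR ± z·√(1/a − 1/(a+b) + 1/c − 1/(c+d))).
* **Pearson χ²** (uncorrected by default) with upper-tail p-value.
* **EMA signal of disproportionate reporting (SDR)**, two rules applied
  with the regulatory inequalities exactly:
  (i) PRR 95% CI lower bound ≥ 1 **and** a ≥ 3 cases;
  (ii) PRR > 2 **and** χ² > 4.

A zero cell makes a pair "not countable" (N/C) rather than an error; the
Haldane–Anscombe +0.5 correction is available behind a flag.

## Worked example

```r
library(pvsignal)

# a seeded synthetic dataset with a planted 3-fold hepatotoxicity signal
# on old-era drugs
cfg <- sim_config(n_reports = 5000, seed = 7,
                  planted_signals = list(list(event_pt = "Hepatotoxicity",
                                              exposure = "era=old",
                                              target_or = 3)))
x <- generate_dataset(cfg)
x
#> <icsr_set> 5,000 reports, 5,516 drug exposures, 18,499 reaction records
#>   receipt years 2012-2021

scan <- soc_scan(x, grouping = "era_old_vs_new")
scan[scan$event == "Hepatobiliary disorders"]
#>    exposure                   event     a     b     c     d   ror ror_l ror_u
#> 1:      old Hepatobiliary disorders   588  6605   604 12597  1.86  1.65  2.09
#>      prr prr_l prr_u  chi2   dof            p n_cases countable sdr_ci_rule
#> 1:  1.79   1.6  1.99 109.6     1 1.199192e-25     588      TRUE        TRUE
```

The planted PT sits inside a SOC with two unrelated PTs, so the SOC-level
ROR (1.86 [1.65, 2.09]) is attenuated below the planted PT-level 3.0 —
the dilution any SOC-level scan applies to a single-PT signal. The SDR
CI-rule fires (lower bound 1.65 ≥ 1, 588 cases ≥ 3); the χ²-rule does not
(PRR 1.79 is not > 2).

Published margins can be fed in directly:

```r
tab <- contingency_table(8676, 372660 - 8676, 7538, 678482 - 7538,
                         exposure = "old ASMs",
                         event = "Blood and lymphatic system disorders")
dispro(tab)
#> old ASMs vs comparator | Blood and lymphatic system disorders (unit=pt)
#>   a=8676 b=363984 c=7538 d=670944
#>   ROR 2.12 [2.06, 2.19]  PRR 2.10 [2.03, 2.16]
#>   chi2 2346.27 (dof 1) p <0.0001  n_cases 8676  SDR ci=TRUE chi2=TRUE
```

Old-era ASMs show twice the reporting odds of blood/lymphatic events
relative to new-era ASMs, and the pair meets both SDR rules.

## Command line

```sh
inst/exec/pvsignal simulate --out sim.csv --truth-out truth.json --seed 42
inst/exec/pvsignal ingest   --input sim.csv --outdir norm/
inst/exec/pvsignal analyze  --input sim.csv --outdir out/ --by soc --grouping era
inst/exec/pvsignal signal   --input out/soc_scan.csv --out flagged.csv
```

Exit codes: 0 success, 2 usage/configuration error, 3 data validation
failure. Outputs are byte-stable given fixed inputs and seed; every result
file carries a JSON sidecar with the scan specification and input hash.

## More

See the methods vignette
(`vignettes/disproportionality-methods.Rmd`) for the model, the design
decisions, the synthetic generator's stated world, and known limitations
(notably: the bundled PT→SOC map is a small synthetic stand-in for the
licensed MedDRA dictionary).
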