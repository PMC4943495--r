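# trialdeid

De-identification of patient-level clinical trial datasets for sharing with
third-party researchers.

Data holders who share individual participant data (IPD) from clinical
trials must transform it so that patients are not identifiable while the
data remain useful for secondary research. `trialdeid` implements a HIPAA
Safe Harbor oriented workflow with further generalisation and masking of
indirect identifiers, on multi-domain tabular studies in the CDISC SDTM
style (DM/AE/VS/LB/DS CSV files sharing a subject key):

- a registry of the **18 Safe Harbor direct-identifier classes** (A–R) with
  a regex **scanner** for identifier-like values (emails, phones, SSN-like,
  URLs, IPs, ZIPs, ISO dates) in any cell;
- **pseudonymisation**: subject and site codes replaced by a uniformly
  random injection — never a hash — applied consistently across all tables
  and extension studies, with a code key whose lifecycle (store securely or
  destroy, with attestation) is an explicit, mandatory decision;
- **date transforms**: date of birth → age in completed years; all other
  patient dates → SDTM study day (day 1 = reference date, no day 0;
  `AESTDTC` → `AESTDY`) or per-subject random **offset dates** preserving
  within-subject intervals, optionally constrained to the trial date range;
  optional month/season retention for seasonal disease;
- **generalisation**: age top-coding (`>89`) and 5-year binning, race
  mapping onto the five FDA categories, ethnicity removal, pooling of
  sites/countries with few distinct subjects, anthropometry binning, ZIP
  truncation to three digits when permitted;
- **free-text scrubbing**: verbatim terms dropped or blanked while the
  dictionary-coded term (e.g. MedDRA PT) is retained untouched, or a
  review mode that blanks only scanner-flagged cells;
- **risk assessment** on the data as shared: equivalence classes over
  declared quasi-identifiers, **k-anonymity** (k = minimum class size),
  unique-subject counts, and the small-cell screens (category populations
  < 100, event terms in < 3 distinct subjects — strict, advisory, never
  auto-deleted);
- a **transformation report** (JSON + Markdown) and an adversarial **QC
  step** that re-derives every change from an input/output diff and fails
  the run on any silent or missing transformation;
- a **synthetic trial generator** with a ground-truth manifest of planted
  identifiers, so every rule is testable without real patient data.

## Worked example

```r
library(trialdeid)

g <- generate_study(n_subjects = 200, n_sites = 6, seed = 101,
                    options = list(rare_events = list("Angioedema" = 2)))
res <- run_deidentify(g$study, default_pipeline_config(seed = 2024))

res$risk
#> <risk_report> n=200 classes=55 k=1 uniques=21 flags=56

head(res$study$tables$DM[, c("SUBJID","SITEID","COUNTRY","SEX","RACE","AGE","WEIGHT")], 4)
#>   SUBJID SITEID COUNTRY SEX                             RACE   AGE  WEIGHT
#> 1 S83694   T732     USA   F                            Asian 70-74 90-99.9
#> 2 S32086   T732     USA   F                            White   >89 50-59.9
#> 3 S68036   T475     ITA   M American Indian or Alaska Native 65-69 70-79.9
#> 4 S69817   T732     USA   F                            White 30-34 90-99.9

res$risk$flags[res$risk$flags$kind == "numerator", ]
#>         kind                    cell count threshold
#> 56 numerator AE.AEDECOD = Angioedema     2         3
```

What the numbers mean: subject codes (`S83694`) and site codes (`T732`)
are fresh random injections; date of birth has become a 5-year age band
with ages over 89 collapsed to `>89`; race is mapped to FDA categories;
weight is binned. The risk report says that on the quasi-identifiers
sex × race × country the least populated equivalence class has k = 1 — 21
subjects are unique on those attributes — and the planted rare adverse
event (2 carriers < 3) is flagged as a small numerator but deliberately
*not* deleted. `res$qc` holds the five QC checks; `qc_passed(res$qc)` is
`TRUE` for this run. All adverse-event dates now read as study days
(`AESTDY`), and the verbatim `AETERM` is gone while `AEDECOD` survives
byte-identical.

A thin command-line wrapper ships in `inst/cli/trialdeid`
(`simulate`, `scan`, `run`; exit code 2 on QC failure).

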