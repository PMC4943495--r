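---
title: "De-identifying patient-level clinical trial data with trialdeid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identifying patient-level clinical trial data with trialdeid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sharing patient-level data from clinical trials with third-party researchers
requires transforming the data so that individual participants are not
identifiable, while keeping enough structure for meaningful re-analysis.
Over-aggressive reduction destroys scientific utility — and for safety data
can even be a public-health problem if it produces misleading re-analyses —
while under-treatment risks patient privacy. trialdeid implements a
pragmatic middle path built on the HIPAA Safe Harbor identifier classes with
additional generalisation and masking of indirect identifiers, the approach
best suited to semi-automated, uniform processing of many studies (as
opposed to per-study statistical Expert Determination, whose non-uniqueness
guarantees are known to collapse on high-dimensional trial data: the ratio
of fields to subjects is large, and rare adverse events are inherently
unique but scientifically essential).

The package operates on multi-domain tabular studies in the style of CDISC
SDTM (DM demographics, AE adverse events, VS vitals, LB labs, DS
disposition): one CSV per domain, sharing a subject key. All cell values
are kept as text internally with declared value kinds (`text`, `integer`,
`decimal`, `calendar-date`, `partial-date`); nothing is ever silently
coerced, and values that violate their declared kind are loaded verbatim
with a warning.

## The workflow

`run_deidentify()` applies the stages in a fixed order:

1. **Classification.** Every variable receives a role, a HIPAA class
   (direct / indirect / none) and a retention policy, driven by explicit
   declarations. Undeclared variables default to *keep* but are surfaced in
   a "needs manual review" list — automation never removes the obligation
   to look for unexpected identifiers. The scanner
   (`scan_free_values()`) flags identifier-like strings (emails, phone
   numbers, URLs, IP addresses, SSN-like and ZIP-like codes, ISO dates) in
   any cell, with a deliberately conservative bias: its findings feed a
   review list, never automatic deletion, and it never reclassifies a
   variable on its own. Name detection is handled by role declaration and
   the verbatim-text policy, not by named-entity recognition, which is
   unreliable without training data and out of scope here.
2. **Direct-identifier removal** for variables whose policy is *remove*.
3. **Pseudonymisation.** Subject and site codes are replaced by a uniformly
   random injection into a configurable template space (`"S#####"` by
   default), consistently across every table. New codes are *never* derived
   from old codes or record content — hashed codes are dictionary-attackable
   and would make the new identifier depend on the data. Supplying a prior
   code key keeps extension studies consistent; whether site keys reuse a
   prior key is likewise a config choice, since practice varies. The seed
   enters the stored code key only as a one-way FNV-1a fingerprint, so the
   key file proves which run produced it without disclosing the seed.
   Key *disposition* (store or destroy) is a mandatory config field with no
   default: destroying or securing the code key is an accountability
   decision the data holder must take explicitly. Encryption of a stored
   key is a deployment concern: the package writes only where the caller
   designates and records an attestation trail.
4. **Dates.** Date of birth becomes age in completed years at the
   reference date (a Feb 29 birthday is deemed reached on Feb 28 of
   non-leap years — a convention had to be fixed, and this one never
   understates age by more than the alternative by one day). All other
   patient dates — including death dates, which follow the general rule —
   are replaced by the **study day** under the SDTM `--DY` convention (day
   1 is the reference date; no day 0; earlier dates are negative), or
   optionally by **offset dates**: one random nonzero offset per subject,
   shifting all of that subject's dates rigidly so within-subject intervals
   are preserved exactly. Study-day is the default method because it
   retains most of the scientific value of dates while avoiding the less
   well-understood residual risk of offsets. With
   `constrain_to_trial_range` the offset is drawn only from values that
   keep the subject inside the original trial-wide date range; when no such
   offset exists (a subject spanning the whole range, with zero excluded)
   the subject's dates are blanked and logged as a study-day fallback
   rather than silently shifted out of range — mixing day numbers into a
   calendar-date column would corrupt its value kind, so the blank-and-log
   route keeps the column honest and the report complete. For seasonal
   disease, `retain_season()` derives month (1–12) or meteorological
   season (DJF/MAM/JJA/SON) before the raw date is transformed away.
   Partial dates (`YYYY` or `YYYY-MM`) are pervasive in trial data; the
   policy is explicit config: `none` (hard error — silence must not become
   silent data loss), `month-midpoint` (impute the 15th, or July 1 for
   year-only, logged), or `conservative-drop` (set missing, logged).
5. **Generalisation.** Ages above 89 collapse to a single `">89"` category
   (the "90 or older" wording is available as a config label — the two
   denote the same set); optional fixed-width binning (default width 5
   years, left-closed right-open so 65 falls in `65-69`). Race is mapped
   onto the five FDA categories via an editable resource table of common
   collected spellings; unmapped values are never guessed — they become
   missing and land on a review list. Ethnicity is removed. Sites or
   countries with fewer than `min_count` *distinct subjects* (default 5,
   disclosed in the report; no externally mandated value exists) are pooled
   into one category — counting patients, not rows, because the risk
   attaches to people. Anthropometry (weight, height) is kept — it is
   dosing-critical — with optional binning. US ZIP codes are truncated to
   three digits (`021**`) only when retention is declared permissible,
   otherwise removed.
6. **Verbatim text.** Free-text variables are dropped (default), blanked,
   or — in review mode — scanned, with only the finding-bearing cells
   blanked and a review report emitted. A dictionary-coded counterpart
   (e.g. a MedDRA preferred term for an adverse event) must exist when
   named and is retained byte-identical.
7. **Subsetting.** Sharing everything versus a research-proposal subset is
   a mandatory, explicit config field; either way the report carries a
   note, because providing full data increases re-identification risk and
   the choice must be documented.
8. **Risk assessment.** On the data *as shared*: equivalence classes over
   the declared quasi-identifiers (missing is its own category —
   missingness patterns can identify), k-anonymity (k = minimum class
   size), the count of unique subjects, and the two small-cell screens —
   category combinations with fewer than 100 subjects (small denominators)
   and event terms carried by fewer than 3 distinct subjects (small
   numerators), both strict inequalities. Flags are advisory only:
   rare-event rows are exactly what safety re-analyses need, so nothing is
   auto-deleted, and the acceptable residual risk threshold remains the
   data holder's decision. No l-diversity/t-closeness machinery is
   provided, for the high-dimensionality reasons above.
9. **Report and QC.** The transformation log renders to `report.json` and
   `report.md`: per table, what was removed, altered and how, the pooled
   labels, the date method, thresholds, seed fingerprints and the Safe
   Harbor attestation line. Timestamps are pinned by config so regenerated
   reports are byte-identical. `qc_verify()` is deliberately *adversarial*:
   it compares input to output directly instead of trusting the log, and
   checks that no direct identifier survives, no raw calendar dates remain,
   subject codes overlap the originals nowhere, verbatim targets are gone
   or clean, and every observed change is covered by a log entry. Any
   `fail` finding means the run must not ship (the CLI exits 2).

## The synthetic trial generator

`generate_study()` emulates the data landscape these rules face: a
multi-domain trial with planted name/email/phone/SSN-like/ZIP columns,
free-text adverse-event verbatims carrying planted identifier strings at a
configurable rate (default 0.2 — high enough that a 50-subject fixture
reliably contains plants, low enough that most verbatims stay clean),
per-subject reference and event dates, and an exact-count rare-event plan.
Every plant is recorded in a ground-truth manifest, so scanner recall and
precision are measurable, not asserted. Defaults are chosen to hit rule
boundaries rather than to be clinically realistic: ages uniform on 18–95
(so the over-89 cap fires), a fixed four-visit grid with ±3-day jitter,
0–3 adverse events per subject, 5% deaths. What the generator does *not*
emulate: realistic treatment effects or correlated safety signals,
CDISC-conformant controlled terminology, multi-row reference-date
ambiguity, or messy legacy formats. Passing tests therefore demonstrate
that the rules are applied correctly and completely on well-formed input —
not that any particular real legacy study is safe to share without the
manual review the workflow itself insists on.

## Numerical and design choices

- Problem sizes in the test suite: oracle-equivalence sweeps use 200
  random studies of up to 200 subjects against brute-force
  re-implementations; pseudonymisation properties (including the
  permutation test for content independence, 1000 resamples at α = 0.01)
  use a 500-subject fixture; end-to-end QC and fault-injection use
  40–50-subject fixtures. These sizes exercise every code path while
  keeping the default suite fast.
- CSV dialect is RFC 4180, UTF-8, header mandatory, missing serialised as
  the empty string; subject-key matching is exact string equality (codes
  are codes, not words).
- The random-injection sampler rejects candidate codes colliding with
  prior draws or original codes; the template space must exceed the
  identifier count or the run aborts with advice to widen the template.
- `study_day()` is strictly monotone and never 0; offsets exclude 0 by
  default (a zero offset would leak true dates).
- Degenerate inputs: header-only tables round-trip; a single-site study
  gets a one-entry code key; pooling a sole category warns that it is
  vacuous; destroying a destroyed key is a warning no-op.

## Known limitations

- No SAS Transport (XPT) or Dataset-XML ingestion; convert to CSV first.
- The scanner is regex-based by design; prose identifiers (names,
  addresses) are handled by variable-level policy, not detection.
- Tables must fit in memory; no streaming.
- Genetic data are out of scope entirely — their re-identification risk
  profile (every genome unique) is not addressable by these techniques.
- Document redaction (CSRs, protocols), data sharing agreements and secure
  hosting are process obligations outside a data-transformation package.
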