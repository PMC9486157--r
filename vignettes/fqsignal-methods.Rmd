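---
title: "Disproportionality analysis of fluoroquinolone tendon injury in FAERS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of fluoroquinolone tendon injury in FAERS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqsignal)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary reports of suspected adverse drug
reactions. They have no exposure denominator, so incidence cannot be
estimated; what can be estimated is *disproportionality* — whether a drug
and an adverse event are reported together more often than the rest of the
database would predict. `fqsignal` implements a complete
pharmacovigilance pipeline for one such question: the association of the
systemic fluoroquinolones ciprofloxacin, levofloxacin and moxifloxacin
with tendonitis (MedDRA PT 10043255) and tendon rupture (PT 10043248),
together with the descriptive surfaces a safety assessment needs
(clinical characteristics, serious outcomes, time to onset, and
oral-versus-intravenous comparison).

Every stage runs on FAERS ASCII quarterly archives, and every stage is
testable without a FAERS download through the packaged synthetic-quarter
generator.

## Data model and ingestion

A FAERS quarterly package carries six `$`-delimited tables — DEMO
(demographics and receipt dates), DRUG (one row per reported drug, with a
role code: PS primary suspect, SS secondary suspect, C concomitant, I
interacting), REAC (MedDRA Preferred Terms), OUTC (outcome codes DE, LT,
HO, DS, CA, RI, OT), THER (therapy start/end dates) and INDI
(indications) — plus, inconsistently, a deleted-case list.
`read_quarter()` parses the 2016+ (PRIMARYID-era) layout only. The
dialect has no quoting and `$` cannot occur inside a field, so naive
per-line splitting is exact; rows with a wrong field count, invalid
enumerated codes, missing keys, or no parent DEMO row are dropped and
tallied, never repaired, so parsed rows plus logged drops always equal the
raw line count.

Dates in FAERS are raw 4/6/8-digit strings, frequently truncated or
impossible. They are stored raw and parsed lazily by
`parse_partial_date()`, which is total: every string maps to exactly one
of day, month, year or invalid precision. Different analyses need
different precision (deduplication needs any parseable receipt date; time
to onset needs full day precision), which is why parsing is deferred to
the consumer.

## Deduplication

FAERS carries multiple versions of one case. Following the
FDA-recommended rule, `deduplicate()` keeps, per CASEID, the version with
the latest FDA receipt date, breaking ties by the numerically higher
PRIMARYID, and removes cases on the deleted list last. The operation is
idempotent and invariant to input row order, and all removals are counted
outcomes (duplicates, deleted, unparseable receipt dates) that sum with
the retained rows to the input size.

## Cohort extraction

A report enters the analysis cohort iff (i) at least one DRUG row has
role code PS *and* matches the study-drug lexicon and (ii) at least one
REAC PT equals a target-event PT. Matching details that were genuinely
open, and how they were fixed:

* **Drug matching** is exact-token against an explicit lexicon (generic
  names plus the US trade names CIPRO, CILOXAN, LEVAQUIN, QUIXIN, AVELOX,
  MOXEZA, VIGAMOX, ...): a verbatim name matches when it equals a lexicon
  name after normalisation, or starts with one at a word boundary so that
  dose decorations (`"CIPRO 500MG TAB"`) are ignored. Substring matching
  is rejected — `CIPROFIBRATE` must not match `CIPRO`. The active
  ingredient field is consulted when the verbatim name fails. A name
  listed under two drug keys is a fatal lexicon error.
* **Event matching** is by PT name equality (case-insensitive), with the
  PT code carried as metadata, because FAERS REAC files store names, not
  codes.
* **Report-level counting**: a report counts once per drug–event pair no
  matter how many PS rows match, since published signal tables count
  reports.
* **Routes** are classed oral / intravenous / other / unknown from the
  verbatim route of the matched PS row; when several matched PS rows
  conflict, the precedence oral > intravenous > other > unknown applies.
* **Ages** harmonize to years by unit code (YR ×1, DEC ×10, MON ÷12, WK
  ÷52.143, DY ÷365.25, HR ÷8766); a value with a missing unit is treated
  as years, and results outside [0, 120] become missing. Age bands are
  <18, 18–65 (both bounds inclusive), >65, unknown.
* **Indications** class as `infections` (PT contains the token
  "infection" or is on a packaged infection-PT list), `unknown-indication`
  ("Product used for unknown indication" or absent), else `other`.
* **Regions** come from a packaged country-to-continent table; unmapped
  strings are Unknown.

## The disproportionality statistics

For a drug–event pair, the deduplicated report universe is cross-
classified as

|                 | event | other events |
|-----------------|-------|--------------|
| **drug (PS)**   | a     | b            |
| **other drugs** | c     | d            |

with $N = a+b+c+d$ and expected count $E = (a+b)(a+c)/N$. Four statistics
are computed in their standard published forms:

* **ROR** $= ad/bc$ with the log-normal 95% CI
  $\exp(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$;
* **PRR** $= [a/(a+b)]/[c/(c+d)]$ with the Yates-corrected chi-square
  $\sum (\lvert O-E_\text{cell}\rvert - 0.5)^2 / E_\text{cell}$, each
  cell's correction floored at zero (this matches `chisq.test(correct =
  TRUE)`, which is used as an independent oracle in the tests);
* **IC** $= \log_2\frac{a+0.5}{E+0.5}$ with the lower credibility bound
  approximation $\mathrm{IC025} = \mathrm{IC} - 3.3(a+0.5)^{-1/2} -
  2.0(a+0.5)^{-3/2}$;
* **EBGM** $= a/E$ in closed form with
  $\mathrm{EBGM05} = \mathrm{EBGM}\,e^{-1.64\sqrt{1/a+1/b+1/c+1/d}}$.

Full MGPS — an EM fit of a two-component gamma mixture prior over all
drug–event pairs of the database — is deliberately not implemented: it
requires the whole-database pair table, shrinks materially only at small
counts, and its absence is recorded in every result's method metadata so
EBGM values are never mistaken for shrunk ones. The IC and EBGM variants
in the published literature differ between sources; the constants used
here (3.3/2.0; z = 1.64) live in the method metadata that
`run_pipeline()` writes.

**Degenerate tables.** A zero cell makes ROR (and the EBGM bound)
undefined; `c = 0` makes PRR undefined. Undefined is an explicit `NA`
state — no Haldane 0.5 correction is applied — and an undefined statistic
can never flag positive. IC is total because of its 0.5 smoothing. At
exact row-proportionality the statistics hit their independence limits
(ROR = PRR = EBGM = 1, IC = 0, the smoothing terms cancelling at E = a).

**Positivity criteria** (defaults, all configurable): ROR requires n ≥ 3
and CI lower bound > 1; PRR requires n ≥ 3, PRR ≥ 2 and chi-square ≥ 4;
IC requires IC025 > 0; EBGM requires EBGM05 > 2. A pair is a combined
positive signal when any one criterion holds.

**Stratification.** Sex and age strata restrict the universe, so b, c
and d are recomputed against the stratum's own background —
disproportionality against the whole database would confound the stratum
effect with the stratum's reporting mix. A route stratum instead
restricts the *drug* flag (exposure by that route) while keeping the full
background, mirroring how oral and intravenous rows of a published route
comparison share one denominator.

Statistics are kept at full precision internally; `print()` and the
output tables round to 2 decimals.

## Time to onset and descriptive surfaces

Onset is the calendar-day difference between the event date and the
matched drug's therapy start. A record is retained only when both dates
have day precision and the difference is non-negative; same-day onset is
kept as 0 days because only a strictly earlier event date is an input
error. Exclusions are tallied by reason (missing, partial precision,
negative) and conserve the input count.

Quartiles use the **median-of-halves** rule: the median of the lower and
upper halves, the halves excluding the middle element for odd n. The rule
was chosen because published onset tables of this kind print half-integer
quartiles (9.5, 16.5), which sort-index methods without interpolation
cannot produce on integer day counts; the rule in force is recorded in
the pipeline metadata. Histograms bin left-closed right-open.

The characteristics table reports counts and percentages (2 decimals) per
drug–event group and pooled, for sex, age bands (plus mean harmonized
age, missing ignored, no imputation), indication classes, outcome codes,
regions, reporter occupations and reporting years (derived from the
retained version's receipt date). Outcome proportions divide by the group
total, so they may sum above 100% because one report can carry several
outcome codes.

## The synthetic-quarter generator

`generate_quarter()` emulates what the pipeline actually consumes: the
FAERS relational structure (versioned cases, drug roles, multiple PTs,
outcome codes, therapy dates), partial and missing dates, duplicate
versions resolvable by the FDA rule, and a controlled signal structure.
Each report draws one PS drug from a pool (three study drugs plus a
Zipf-weighted background pool), then includes each target event with
probability $\min(1, \lambda p_e)$ — $\lambda > 1$ only for planted
drug–event pairs — plus 1–3 Zipf-drawn background PTs. Because the target
events are independent Bernoulli draws given the PS drug, the expected
2×2 cells have the exact closed form in `expected_contingency()`, which
the calibration tests check against Monte-Carlo cell means.

Defaults were fixed once to resemble the study's reporting structure and
are conditions, not tunables: study-drug exposure of 0.4–1.0% of reports,
target-event background rates of 0.25–0.4%, planted $\lambda$ between 15
and 50 across the six pairs, ~90% oral routes among exposed reports,
onset log-normals with medians of 3–18 days (dispersion 1.2), ~54%
female, age bands 1/60/20/19%, a 10% duplicate rate, and 15% of event
dates truncated to month precision. Therapy starts are uniform in the
quarter and event dates are start plus the log-normal delay rounded to
days.

What the generator does **not** emulate: MedDRA's hierarchy (background
PTs are abstract labels), correlated drug co-prescription, reporting
waves and stimulated reporting, cross-CASEID duplicates that the FDA rule
cannot resolve, country-specific reporting cultures, and free-text dose
fields. Passing tests therefore demonstrate the pipeline's correctness
and calibration under a clean reporting model, not robustness to every
real-data pathology.

## Numerical and design choices

* Dedup sort keys: receipt dates compare after padding month/year
  precision to the period start; primaryids compare numerically.
* Empty strata and empty cells produce undefined markers with false
  flags, never errors, inside a screen; an entirely empty universe is an
  error.
* `write_table()` emits RFC-4180 CSV; the pipeline is bitwise
  reproducible on identical inputs, and the generator is byte-identical
  for identical config and seed.
* Test problem sizes: property suites run on quarters of 800–12,000
  reports, the oracle grid covers 2×2 cells up to 30, interval
  calibration uses 2,000 margin-fixed null tables (via
  `stats::r2dtable`), and Monte-Carlo generator calibration averages 50
  replicate quarters of 9,000 reports.

## Limitations

Disproportionality is association, not causality, and FAERS has no
denominator: none of the statistics estimate incidence. The closed-form
EBGM is unshrunk (see above) and IC025 uses an approximation rather than
full posterior quantiles, so at very small counts both bounds are less
conservative than their full-Bayes counterparts — one reason the
combined criterion also carries count-gated ROR/PRR tests. Reproducing
any published whole-database signal table numerically requires the
complete multi-year FAERS download; this package ships the pipeline and
its verification, and treats the real download as an optional input path.
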