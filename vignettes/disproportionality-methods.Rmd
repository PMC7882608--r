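---
title: "Case/non-case disproportionality analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems (SRS) such as the FDA Adverse Event Reporting
System collect voluntary reports of suspected drug adverse events. They have
no denominator — we never observe the population of treated patients, only
the reports — so incidence cannot be estimated. What *can* be estimated is
disproportionality: whether a given event is reported more often with a
given drug than the rest of the database would lead one to expect. The
motivating application for this package is the question whether primary
malignant lung cancer is disproportionally reported among users of
angiotensin-converting enzyme inhibitors (ACEIs), a drug class under
long-standing suspicion because ACE inhibition leads to pulmonary
accumulation of bradykinin and substance P, both plausibly
tumour-promoting. The package is, however, generic over any drug class and
any MedDRA-style composite event.

## Case/non-case design

Within a cleaned report database, *cases* are reports carrying the event of
interest, *non-cases* are all other reports; *exposed* reports mention the
drug (class) of interest in any role — suspected, interacting or
concomitant. That yields the 2×2 table of report counts

|            | event (case) | no event |
|------------|--------------|----------|
| drug       | a            | b        |
| other drugs| c            | d        |

All counting is report-level: a report counts once no matter how many
qualifying reaction terms or class drug mentions it carries. This is the
convention under which published class-level counts (e.g. 622 cases among
197,320 exposed reports in a database of 7,861,515) reconstruct their
printed statistics exactly.

### Event definition

An event is one Higher Level Term (HLT) minus an explicit set of excluded
Preferred Terms (PTs). For primary malignant lung cancer, the lower
respiratory tract neoplasm HLT is restricted by excluding the six terms
that are not primary malignancies (pulmonary carcinoid, pulmonary leukaemic
infiltration, endobronchial lipoma, two benign neoplasm terms, and lung
metastases). A report whose only target-HLT terms are excluded is a
non-case. The packaged vocabulary is a miniature: it carries the full
target HLT (twelve PTs) plus decoy HLTs for background reactions and
indications. The *logic* — hierarchy lookup, exclusion, report-level
aggregation — is what the package contributes; swapping in a licensed
MedDRA extract is a matter of replacing one TSV.

### Drug resolution

Verbatim drug strings are uppercased, stripped of punctuation, numbers and
dose/route/salt tokens, then looked up exactly in a synonym dictionary
(generic and brand names for the ten FDA-approved ACEIs, irbesartan,
thiazides, an antidiabetic class and decoys). There is deliberately no
fuzzy matching: it would make classification non-deterministic and
untestable, and real-world string fuzz is out of scope.

## Statistics

**Reporting odds ratio.** ROR = (a/b)/(c/d), with the Woolf (log-scale)
interval $\exp(\ln \mathrm{ROR} \pm z_{\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$.
If any cell is zero the Haldane–Anscombe correction adds ½ to every cell
and the result is flagged; with the correction disabled the result is an
undefined-marker, never a silent infinity.

**Information component.** IC = $\log_2\frac{a + 1/2}{E + 1/2}$ with
$E = n_{drug} \, n_{event} / n_{total}$, the BCPNN-style half-count
shrinkage. The default interval is the normal approximation
$\mathrm{IC} \pm z_{\alpha/2}/(\ln 2 \sqrt{a})$. This choice deserves a
note: several IC interval formulas circulate, and the exact variant behind
any given publication is often unstated. The normal approximation above
reproduces the published class-level interval (0.17–0.39 from the counts
above) and is therefore the default; the Norén posterior
credibility-bound approximation (IC025/IC975) is available via
`compute_ic(..., ci_method = "noren")` for sensitivity.

**Signal criteria.** A pair signals when *either* the ROR criterion fires
(lower 95% bound > 1 and a ≥ 3 exposed cases) *or* the IC criterion fires
(lower IC bound > 0). These defaults follow common pharmacovigilance
practice and reproduce the published class-level, female-stratum and
male-stratum calls; both thresholds are configurable via
`signal_criteria()`.

**Adjusted ROR.** Logistic regression of case status on exposure among
reports mentioning either the exposure class or a named reference class
(thiazides by default — a comparator class without an established lung
cancer association), controlling for sex, age group and reporting year.
Implementation is iteratively reweighted least squares with step-halving
(which makes the log-likelihood provably non-decreasing per iteration — an
asserted invariant), convergence when the largest score component or the
relative log-likelihood change falls below `tol = 1e-8`, Wald intervals on
the log scale. Design-matrix baselines: male sex, age 45–64, earliest
reporting year; year is coded categorically by default (a linear coding is
available, since publications rarely state which was used). Reports with
unknown sex or age group are excluded from the fit, mirroring the standard
missing-covariate exclusion; reports mentioning both the exposure and the
reference class are excluded by default (`overlap = "as_exposed"` counts
them as exposed), because published analyses do not state the overlap rule.
Coefficients beyond ±15 raise a quasi-separation warning; Wald intervals
are meaningless in that regime and fits on sparse strata should be treated
accordingly.

## Cleaning and deduplication

Cleaning removes, in order: reports with no drug mention or no reaction
term ("missing data" — demographic unknowns are *retained*, because
published characteristics tables report unknown strata), reports outside
the study window (year–quarter bounds), superseded report versions (highest
version per report id wins), and field-match duplicates. The field-match
rule — identical sex, age group, country, year, quarter, sorted generic
drug set and sorted reaction set, first occurrence kept — approximates
regulator-side duplicate detection, whose exact algorithm is not public;
it is deliberately conservative and can be disabled. The provenance log
reconciles exactly: output count plus per-rule removals equals input
count, and `clean()` is idempotent.

Age, if supplied raw, is binned with left-closed boundaries 18/45/65/75;
an age of exactly 75 goes to the older (">75") group. Published tables do
not state their boundary convention, so the boundary vector is an argument.

## Strata and sensitivity analyses

`stratum_spec()` expresses subsets as declarative (field, op, value)
clauses — pure predicates, AND-composed. Three interpretation choices are
worth making explicit:

- *Region removal* (`region != "Europe"`) removes only reports positively
  known to be European; unknown-region reports stay, since removing them
  would silently shrink the comparator.
- *Excluding non-small cell lung cancer subjects* defaults to adding the
  NSCLC PT to the exclusion set, so carriers become non-cases but remain
  in the database; `drop_extra_pt_reports = TRUE` removes them entirely.
  Both readings are defensible from typical published phrasing.
- *Diabetes restriction* uses an indication-PT-or-antidiabetic-drug proxy,
  the standard workaround for SRS data having no diagnosis table.
- Gender strata restrict the comparator as well (female cases vs female
  non-cases), which is the assumption made here since publications rarely
  state it.

`run_panel()` re-runs the full computation per (drug × stratum) with a
deterministic row order; strata with empty margins yield undefined-marker
rows rather than disappearing.

## The synthetic-report generator

Every stage is tested against `generate_reports()`, which simulates a
FAERS-like population with *known* ground truth: covariates from
categorical margins loosely matching large SRS databases (46/46/8%
male/female/unknown sex; age mode 45–64; ~60% US reporting), per-class
exposures and the target event from logistic models, optional confounding
terms that shift both exposure and event odds, optional per-sex odds
ratios, excluded-PT coding (a latent event coded with an excluded term, so
it never surfaces as a case), decoy reactions and drugs, covariate
missingness, and exact-copy duplicate injection under fresh report ids.

Two generator defaults are deliberate calibrations rather than empirical
claims:

- `baseline_event_odds = 0.02`. Real lung-cancer reporting odds in a
  multi-million-report database are ~0.003; simulating at that rate at
  desk scale (10⁵–5×10⁵ reports) would leave single-digit exposed-case
  counts and make every stratum estimate degenerate. 0.02 puts simulated
  collections in the count regime of the published class-level analysis
  (hundreds of exposed cases) — in particular, a sex stratum of a
  500,000-report collection holds ≈135 exposed cases, which gives >90%
  power to detect an odds ratio of 1.36, the regime the subset analyses
  operate in.
- Exposure prevalences (ACEI 2.5%, thiazide 2%, irbesartan 0.5%) match the
  published class-level proportion (197,320/7,861,515 ≈ 2.5%).

What the generator does *not* emulate: reporting-behaviour phenomena
(Weber effect, masking/competition bias), drug–drug interaction effects on
reporting, duplicate records that differ in a field (only exact copies are
injected), and informative missingness. Passing tests therefore demonstrate
correctness of the computation under a well-behaved reporting process, not
robustness to those biases in real data.

## Problem sizes and numerical choices

The test suite exercises parameter recovery at 200 replicates per injected
odds ratio (0.5, 1, 1.5, 2) on 200,000-report collections — enough for
95% CI coverage to be tested within 3 Monte-Carlo standard errors — and the
sex-specific pattern at 500,000 reports. Confounding recovery uses a
120,000-report collection with a sex term shifting both exposure
(log-odds +1.2) and event (+1.0), true conditional OR 1.5. Display
rounding is half-away-from-zero (2 dp for estimates, 1 dp for
percentages); a truncation switch exists for percentage tables because at
least one published table (24/622 printed as 3.8%) is consistent with
truncation but not with rounding. All randomness flows from a single seed
per generator run; identical seeds produce byte-identical collections and
output files.

## Known limitations

- The miniature vocabulary and dictionary cover the analysis classes plus
  decoys, not the long tail of real drug strings; unresolvable mentions
  are treated as non-exposure, which in real data would dilute estimates.
- Crude and adjusted RORs measure reporting association, not causation or
  risk; nothing in this package corrects for SRS reporting biases.
- The adjusted model is a plain logistic fit: no Firth correction for
  sparse strata, no propensity scores, no mixed models.
- Field-match deduplication can, on principle, merge genuinely distinct
  reports that coincide on every key field; at realistic field
  cardinalities this is rare, and the provenance log makes every removal
  auditable.
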