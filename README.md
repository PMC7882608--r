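# faersignal

Case/non-case disproportionality analysis for spontaneous adverse event
report databases, in the style of FAERS pharmacovigilance studies.

Spontaneous reporting systems have no denominator, so drug safety signals
are mined by *disproportionality*: is an event reported more often with a
drug than the rest of the database suggests it should be? `faersignal`
implements the full pipeline around that idea for FAERS-like report tables:

- **report store** — read the four-table format (demographics, drugs,
  reactions, indications), clean it (missing-data removal, study-window
  restriction, version and field-match deduplication) with an exactly
  reconciling provenance log;
- **case/exposure definition** — a composite event as a MedDRA-style
  Higher Level Term minus excluded Preferred Terms; exposure as any
  mention (suspected, interacting or concomitant) of a drug class resolved
  through a synonym dictionary;
- **disproportionality statistics** — the reporting odds ratio
  ROR = (a/b)/(c/d) with the Woolf interval
  exp(ln ROR ± z·√(1/a+1/b+1/c+1/d)), and the information component
  IC = log2((a+½)/(E+½)), E = n_drug·n_event/n_total, with a normal or
  Norén-style interval; a dual-criterion signal flag (ROR lower bound > 1
  with a ≥ 3, or IC lower bound > 0);
- **adjusted ROR** — logistic regression (own IRLS with step-halving,
  Wald intervals) of case status on exposure versus a reference drug
  class, controlling sex, age group and reporting year;
- **strata & sensitivity** — declarative subset specifications (gender,
  region removal, extra PT exclusions, comorbidity proxy, year windows)
  re-running the whole computation per stratum;
- **synthetic data** — a report generator with known ground-truth odds
  ratios, confounding, duplicates and missingness, so every stage is
  testable without access to regulatory data.

The motivating analysis is the reported association between
angiotensin-converting enzyme inhibitors (ACEIs) and primary malignant
lung cancer, but every definition (event, classes, strata, criteria) is
configurable.

## Worked example

Reconstructing a published class-level analysis from its printed marginal
counts (622 exposed cases; 197,320 ACEI reports; 20,403 lung-cancer
reports; 7,861,515 cleaned reports):

```r
library(faersignal)

tab <- build_table(622, n_drug = 197320, n_event = 20403, n_total = 7861515)
signal_result(tab)
#> <signal_result> a=622  ROR 1.22 (1.13-1.32)  IC 0.28 (0.17-0.39)  signal: TRUE [ROR+IC]
```

The odds of a lung-cancer report are 1.22 times higher among ACEI reports
than in the rest of the database; both the ROR interval (above 1) and the
IC interval (above 0) fire, so the pair is flagged as a signal.

The same machinery on simulated data with a known injected odds ratio of
1.5, including gender strata with gender-restricted comparators:

```r
hier <- load_hierarchy()
dict <- load_dictionary()
ev   <- lung_cancer_event(hier)

sim <- generate_reports(synth_config(n_reports = 100000,
                                     true_or = c(ACEI = 1.5), seed = 1))
lab <- classify(sim$collection, ev, "ACEI", hier, dict)
signal_result(build_table(lab))
#> <signal_result> a=61  ROR 1.46 (1.13-1.89)  IC 0.51 (0.15-0.88)  signal: TRUE [ROR+IC]

run_panel(sim$collection, ev, "ACEI",
          list(stratum_spec("all"),
               stratum_spec("female", list(list(field = "sex", op = "==", value = "female"))),
               stratum_spec("male",   list(list(field = "sex", op = "==", value = "male")))),
          hier, dict)[, c("drug", "stratum", "a", "ror", "ror_low", "ror_high", "signal")]
#>   drug stratum  a  ror ror_low ror_high signal
#> 1 ACEI     all 61 1.46   1.127     1.89   TRUE
#> 2 ACEI  female 25 1.28   0.854     1.91  FALSE
#> 3 ACEI    male 31 1.65   1.144     2.37   TRUE
```

The point estimate 1.46 sits close to the injected truth (1.5) and its
95% interval covers it; at 25–31 exposed cases per sex stratum, stratum
intervals are wide and individual strata may or may not reach the signal
threshold — exactly the small-count behaviour stratified SRS analyses must
contend with.

A full run (clean → classify → panel → descriptives → adjusted fit) with
TSV outputs and a reproducible config snapshot:

```r
res <- run_analysis(run_config(
  demo_path = "in/demo.tsv", drug_path = "in/drug.tsv",
  reac_path = "in/reac.tsv", indi_path = "in/indi.tsv",
  drug_queries = c("ACEI", "lisinopril", "ramipril"),
  adjusted = TRUE, out_dir = "out"))
```

A thin command-line wrapper with `analyze`, `simulate` and `describe`
subcommands ships in `inst/scripts/faersignal`.

See the vignette (`vignettes/disproportionality-methods.Rmd`) for the
statistical model, the cleaning and stratification rules, and the design
of the synthetic-data generator.

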