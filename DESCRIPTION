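Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A case/non-case disproportionality analysis pipeline for
    FAERS-like spontaneous adverse event report databases. Reads, cleans and
    deduplicates report tables; classifies reports as cases of a composite
    MedDRA-style event (one Higher Level Term minus excluded Preferred Terms)
    and as exposed to a drug class; computes the reporting odds ratio (ROR)
    and Bayesian information component (IC) with 95 percent intervals and a
    dual-criterion signal flag; estimates the covariate-adjusted ROR by
    logistic regression against a reference drug class; re-runs the analysis
    over declarative subset and sensitivity strata; and simulates report
    collections with known ground-truth odds ratios so every stage is
    testable without access to regulatory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
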