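# Shared fixtures: vocabularies, tiny hand-built collections, and shortcuts.

hier <- load_hierarchy()
dict <- load_dictionary()
lung_ev <- lung_cancer_event(hier)

pt <- function(name) pt_code(hier, name)

example_paths <- function() {
  lapply(c(demo = "demo.tsv", drug = "drug.tsv", reac = "reac.tsv",
           indi = "indi.tsv"),
         function(f) fs_extdata("example", f))
}

# A hand-built collection covering all four 2x2 cells:
#   C1 exposed case, C2 exposed non-case, C3 unexposed case,
#   C4 unexposed non-case, plus C5 exposed with an excluded-PT-only event.
four_cell_collection <- function() {
  demo <- data.frame(
    report_id = paste0("C", 1:5), version = 1L,
    sex = c("female", "male", "female", "male", "unknown"),
    age_group = c("45-64", "65-74", ">75", "18-44", "unknown"),
    country = c("US", "US", "DE", "GB", "unknown"),
    receipt_year = c(2010L, 2011L, 2012L, 2013L, 2014L),
    receipt_quarter = c(1L, 2L, 3L, 4L, 1L),
    outcomes = c("hospitalization", "", "death", "", "")
  )
  drugs <- data.frame(
    report_id = c("C1", "C2", "C3", "C4", "C5"),
    verbatim_name = c("LISINOPRIL 10MG", "RAMIPRIL", "HYDROCHLOROTHIAZIDE",
                      "LIPITOR", "ENALAPRIL MALEATE 5 MG"),
    role = c("suspect", "concomitant", "suspect", "suspect", "suspect")
  )
  reactions <- data.frame(
    report_id = c("C1", "C2", "C3", "C4", "C5"),
    pt_code = c(pt("Lung adenocarcinoma"), pt("Cough"),
                pt("Small cell lung cancer"), pt("Headache"),
                pt("Metastases to lung"))
  )
  indications <- data.frame(report_id = paste0("C", 1:5),
                            pt_code = pt("Hypertension"))
  report_collection(demo, drugs, reactions, indications)
}

# Small synthetic collection for recount-style oracles.
small_sim <- function(n = 10000, seed = 42, ...) {
  generate_reports(synth_config(n_reports = n, seed = seed, ...),
                   hierarchy = hier, dictionary = dict)
}
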