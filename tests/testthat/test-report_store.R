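test_that("packaged example tables are read and joined correctly", {
  p <- example_paths()
  coll <- read_tables(p$demo, p$drug, p$reac, p$indi)
  expect_s3_class(coll, "report_collection")
  expect_equal(n_reports(coll), 3)
  expect_setequal(coll$demo$report_id, c("R0001", "R0002", "R0003"))
  # joins: drug and reaction rows attach to their own report only
  expect_equal(sort(coll$drugs$report_id[coll$drugs$verbatim_name == "NORVASC"]),
               "R0001")
  expect_equal(coll$reactions$pt_code[coll$reactions$report_id == "R0003"],
               pt("Metastases to lung"))
  expect_equal(coll$demo$region, c("America", "Europe", "Europe"))
})

test_that("child rows referencing an absent report_id are dropped and logged", {
  p <- example_paths()
  td <- withr::local_tempdir()
  drug <- read.delim(p$drug, colClasses = "character")
  drug <- rbind(drug, data.frame(report_id = "GHOST",
                                 verbatim_name = "LISINOPRIL", role = "suspect"))
  write.table(drug, file.path(td, "drug.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  coll <- read_tables(p$demo, file.path(td, "drug.tsv"), p$reac, p$indi)
  expect_false("GHOST" %in% coll$drugs$report_id)
  prov <- coll$provenance
  expect_equal(prov$n[prov$rule == "orphan_drug_rows"], 1L)
})

test_that("missing files and missing mandatory columns raise clear errors", {
  p <- example_paths()
  expect_error(read_tables("no/such/file.tsv", p$drug, p$reac, p$indi),
               "not found")
  td <- withr::local_tempdir()
  demo <- read.delim(p$demo, colClasses = "character")
  demo$sex <- NULL
  write.table(demo, file.path(td, "demo.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_tables(file.path(td, "demo.tsv"), p$drug, p$reac, p$indi),
               "sex")
})

test_that("schema remapping and comma delimiters are honoured", {
  p <- example_paths()
  td <- withr::local_tempdir()
  demo <- read.delim(p$demo, colClasses = "character")
  names(demo)[names(demo) == "sex"] <- "patient_sex"
  write.table(demo, file.path(td, "demo.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  for (f in c("drug", "reac", "indi")) {
    tab <- read.delim(p[[f]], colClasses = "character")
    write.table(tab, file.path(td, paste0(f, ".csv")), sep = ",",
                quote = FALSE, row.names = FALSE)
  }
  coll <- read_tables(file.path(td, "demo.csv"), file.path(td, "drug.csv"),
                      file.path(td, "reac.csv"), file.path(td, "indi.csv"),
                      schema_config = list(delimiter = ",",
                                           demo = list(sex = "patient_sex")))
  expect_equal(coll$demo$sex, c("male", "female", "unknown"))
})

test_that("raw ages are binned with left-closed boundaries, ties to the older group", {
  expect_equal(bin_age(c(0, 17, 18, 44, 45, 64, 65, 74, 75, 90, NA)),
               c("<18", "<18", "18-44", "18-44", "45-64", "45-64",
                 "65-74", "65-74", ">75", ">75", "unknown"))
})

test_that("region assignment is a total deterministic function", {
  expect_equal(assign_region("US"), "America")
  expect_equal(assign_region("DE"), "Europe")
  expect_equal(assign_region(c("JP", "AU", "ZA")),
               c("Asia", "Oceania", "Africa"))
  expect_equal(assign_region(""), "unknown")
  expect_equal(assign_region("ZZ"), "unknown")
  expect_equal(assign_region("unknown"), "unknown")
})

test_that("cleaning removes reports with no reactions or no drugs as missing data", {
  coll <- four_cell_collection()
  coll$reactions <- coll$reactions[coll$reactions$report_id != "C2", , drop = FALSE]
  out <- clean(coll)
  expect_false("C2" %in% out$demo$report_id)
  prov <- out$provenance
  expect_equal(prov$n[prov$rule == "removed_missing_data"], 1L)
  # unknown demographics are NOT a removal criterion
  expect_true("C5" %in% out$demo$report_id)
})

test_that("versioning keeps only the highest version of a report", {
  coll <- four_cell_collection()
  v2 <- coll$demo[coll$demo$report_id == "C1", , drop = FALSE]
  v2$version <- 2L
  v2$sex <- "male"  # updated field on the newer version
  coll$demo <- rbind(coll$demo, v2)
  out <- clean(coll, fieldmatch_dedup = FALSE)
  kept <- out$demo[out$demo$report_id == "C1", ]
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$version, 2L)
  expect_equal(kept$sex, "male")
})

test_that("window filtering uses year-quarter order", {
  coll <- four_cell_collection()  # years 2010..2014
  out <- clean(coll, window_start = "2011Q3", window_end = "2013Q4")
  expect_setequal(out$demo$report_id, c("C3", "C4"))
  expect_error(clean(coll, window_start = "2015Q1", window_end = "2014Q1"),
               "window_start")
})

test_that("field-match dedup removes injected exact copies; provenance reconciles", {
  sim <- small_sim(n = 4000, seed = 11, dup_rate = 0.05)
  coll <- sim$collection
  out <- clean(coll, dictionary = dict)
  prov <- out$provenance
  g <- function(rule) prov$n[prov$rule == rule]
  expect_equal(g("clean_output") + g("removed_missing_data") +
                 g("removed_outside_window") + g("removed_duplicate_version") +
                 g("removed_duplicate_fieldmatch"),
               g("clean_input"))
  # oracle: expected survivors = number of distinct field keys in the input
  key <- with(coll$demo, paste(sex, age_group, country, receipt_year,
                               receipt_quarter))
  gset <- vapply(split(resolve_generic(coll$drugs$verbatim_name, dict),
                       coll$drugs$report_id),
                 function(v) paste(sort(unique(v)), collapse = "|"), "")
  rset <- vapply(split(coll$reactions$pt_code, coll$reactions$report_id),
                 function(v) paste(sort(unique(v)), collapse = "|"), "")
  full_key <- paste(key, gset[coll$demo$report_id], rset[coll$demo$report_id])
  expect_equal(n_reports(out), length(unique(full_key)))
  # every injected duplicate was removed (its original is field-identical)
  n_injected <- sum(sim$truth$is_duplicate)
  expect_gte(g("removed_duplicate_fieldmatch"), n_injected)
})

test_that("dedup never removes the last representative of a duplicate group", {
  sim <- small_sim(n = 2000, seed = 3, dup_rate = 0.1)
  out <- clean(sim$collection, dictionary = dict)
  originals <- sim$truth$dup_of[sim$truth$is_duplicate]
  survivors <- out$demo$report_id
  # for every duplicated original, some representative survived
  expect_true(all(originals %in% survivors |
                    vapply(originals, function(o)
                      any(sim$truth$report_id[sim$truth$dup_of %in% o] %in% survivors),
                      logical(1))))
})

test_that("clean is idempotent", {
  sim <- small_sim(n = 3000, seed = 5, dup_rate = 0.08)
  once <- clean(sim$collection, "2004Q1", "2020Q1", dictionary = dict)
  twice <- clean(once, "2004Q1", "2020Q1", dictionary = dict)
  expect_equal(twice$demo, once$demo)
  expect_equal(twice$drugs, once$drugs)
  expect_equal(twice$reactions, once$reactions)
  prov <- twice$provenance
  removed <- prov$n[grepl("^removed_", prov$rule)]
  expect_equal(sum(tail(removed, 4)), 0L)
})

test_that("cleaning everything warns rather than errors", {
  coll <- four_cell_collection()
  coll$reactions <- coll$reactions[0, , drop = FALSE]
  expect_warning(out <- clean(coll), "every report")
  expect_equal(n_reports(out), 0L)
})
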