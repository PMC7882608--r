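test_that("clause filters retain exactly the matching reports", {
  coll <- four_cell_collection()
  fem <- apply_stratum(coll, stratum_spec("female", list(
    list(field = "sex", op = "==", value = "female"))))
  expect_setequal(fem$demo$report_id, c("C1", "C3"))
  # child tables are subset along with demo
  expect_setequal(unique(fem$drugs$report_id), c("C1", "C3"))
})

test_that("removing Europe keeps unknown-region reports", {
  coll <- four_cell_collection()  # regions: America, America, Europe, Europe, unknown
  out <- apply_stratum(coll, stratum_spec("no_europe", list(
    list(field = "region", op = "!=", value = "Europe"))))
  expect_setequal(out$demo$report_id, c("C1", "C2", "C5"))
  # set-builder oracle
  expect_setequal(out$demo$report_id,
                  coll$demo$report_id[coll$demo$region != "Europe"])
})

test_that("year clauses match the generator's per-year bookkeeping", {
  sim <- small_sim(n = 6000, seed = 31)
  out <- apply_stratum(sim$collection, stratum_spec("early", list(
    list(field = "receipt_year", op = "<=", value = 2011))))
  expect_equal(n_reports(out), sum(sim$truth$receipt_year <= 2011))
  expect_setequal(out$demo$report_id,
                  sim$truth$report_id[sim$truth$receipt_year <= 2011])
})

test_that("unknown fields and ops in clauses are configuration errors", {
  expect_error(stratum_spec("x", list(list(field = "height", op = "==", value = 1))),
               "unknown stratum field")
  expect_error(stratum_spec("x", list(list(field = "sex", op = "~", value = 1))),
               "unknown stratum op")
})

test_that("the diabetes stratum uses indication PTs and antidiabetic co-medication", {
  sim <- small_sim(n = 8000, seed = 17)
  out <- apply_stratum(sim$collection, stratum_spec("dm", list(
    list(field = "diabetes", op = "==", value = TRUE))), hier, dict)
  # oracle: reports with a diabetes indication PT or an antidiabetic drug
  dia_pts <- hier$terms$pt_code[hier$terms$hlt_name ==
                                  "Diabetes mellitus (incl subtypes)"]
  by_indi <- unique(sim$collection$indications$report_id[
    sim$collection$indications$pt_code %in% dia_pts])
  gen <- resolve_generic(sim$collection$drugs$verbatim_name, dict)
  by_drug <- unique(sim$collection$drugs$report_id[
    !is.na(gen) & gen %in% query_generics("antidiabetic", dict)])
  expect_setequal(out$demo$report_id, union(by_indi, by_drug))
  # every detected report is truly diabetic in the generator's truth
  expect_true(all(out$demo$report_id %in%
                    sim$truth$report_id[sim$truth$diabetes]))
})

test_that("extra PT exclusions reclassify carriers as non-cases (or drop them)", {
  coll <- four_cell_collection()
  nsclc <- pt("Non-small cell lung cancer")
  coll$reactions$pt_code[coll$reactions$report_id == "C1"] <- nsclc
  # reclassify mode: C1 stays in the collection but is no longer a case
  panel <- run_panel(coll, lung_ev, "ACEI",
                     list(stratum_spec("all"),
                          stratum_spec("excl_nsclc", extra_pt_exclusions = nsclc)),
                     hier, dict)
  expect_equal(panel$a[panel$stratum == "all"], 1)
  expect_equal(panel$a[panel$stratum == "excl_nsclc"], 0)
  expect_equal(panel$a[panel$stratum == "excl_nsclc"] +
                 panel$b[panel$stratum == "excl_nsclc"],
               panel$a[panel$stratum == "all"] + panel$b[panel$stratum == "all"])
  # drop mode: C1 leaves the collection entirely
  dropped <- apply_stratum(coll, stratum_spec("x", extra_pt_exclusions = nsclc,
                                              drop_extra_pt_reports = TRUE))
  expect_false("C1" %in% dropped$demo$report_id)
})

test_that("panel on the all stratum equals a direct disproportionality call", {
  sim <- small_sim(n = 5000, seed = 23, true_or = c(ACEI = 1.5))
  coll <- sim$collection
  panel <- run_panel(coll, lung_ev, "ACEI", list(stratum_spec("all")),
                     hier, dict)
  lab <- classify(coll, lung_ev, "ACEI", hier, dict)
  res <- signal_result(build_table(lab))
  expect_equal(nrow(panel), 1L)
  expect_equal(panel$ror, res$ror)
  expect_equal(panel$ic, res$ic)
  expect_equal(c(panel$a, panel$b, panel$c, panel$d),
               unname(c(res$a, res$b, res$c, res$d)))
})

test_that("sex strata partition the unstratified cells exactly", {
  sim <- small_sim(n = 10000, seed = 29, true_or = c(ACEI = 1.5))
  strata <- list(stratum_spec("all"),
                 stratum_spec("female", list(list(field = "sex", op = "==", value = "female"))),
                 stratum_spec("male", list(list(field = "sex", op = "==", value = "male"))),
                 stratum_spec("unknown", list(list(field = "sex", op = "==", value = "unknown"))))
  panel <- run_panel(sim$collection, lung_ev, "ACEI", strata, hier, dict)
  for (cell in c("a", "b", "c", "d"))
    expect_equal(sum(panel[[cell]][panel$stratum != "all"]),
                 panel[[cell]][panel$stratum == "all"])
})

test_that("adding a filter never increases any cell count", {
  sim <- small_sim(n = 8000, seed = 37)
  base <- list(list(field = "sex", op = "==", value = "female"))
  more <- c(base, list(list(field = "receipt_year", op = "<=", value = 2011)))
  panel <- run_panel(sim$collection, lung_ev, "ACEI",
                     list(stratum_spec("one", base), stratum_spec("two", more)),
                     hier, dict)
  for (cell in c("a", "b", "c", "d"))
    expect_lte(panel[[cell]][panel$stratum == "two"],
               panel[[cell]][panel$stratum == "one"])
})

test_that("panel output is deterministic and ordered class-first, drugs alphabetical", {
  sim <- small_sim(n = 4000, seed = 41, true_or = c(ACEI = 1.5))
  strata <- list(stratum_spec("all"),
                 stratum_spec("female", list(list(field = "sex", op = "==", value = "female"))))
  p1 <- run_panel(sim$collection, lung_ev, c("ACEI", "ramipril", "lisinopril"),
                  strata, hier, dict)
  p2 <- run_panel(sim$collection, lung_ev, c("ACEI", "ramipril", "lisinopril"),
                  strata, hier, dict)
  expect_identical(p1, p2)
  expect_equal(p1$drug, rep(c("ACEI", "lisinopril", "ramipril"), each = 2))
  expect_equal(p1$stratum, rep(c("all", "female"), 3))
})

test_that("a stratum with zero exposed reports yields an undefined-marker row", {
  coll <- four_cell_collection()
  panel <- run_panel(coll, lung_ev, "moexipril", list(stratum_spec("all")),
                     hier, dict)
  expect_equal(nrow(panel), 1L)
  expect_true(is.na(panel$ror))
  expect_false(panel$signal)
  expect_equal(panel$criteria_detail, "undefined")
})

test_that("sex-specific injected ORs reproduce the female-not-male signal pattern", {
  hits_f <- 0L; hits_m <- 0L; ordered <- 0L; n_rep <- 5L
  strata <- list(
    stratum_spec("female", list(list(field = "sex", op = "==", value = "female"))),
    stratum_spec("male", list(list(field = "sex", op = "==", value = "male"))))
  for (s in seq_len(n_rep)) {
    sim <- generate_reports(synth_config(
      n_reports = 500000, seed = 100 + s,
      true_or_by_sex = list(ACEI = c(male = 1.0, female = 1.36, unknown = 1.0))),
      hierarchy = hier, dictionary = dict)
    panel <- run_panel(sim$collection, lung_ev, "ACEI", strata, hier, dict)
    f <- panel[panel$stratum == "female", ]
    m <- panel[panel$stratum == "male", ]
    ordered <- ordered + (f$ror > m$ror)
    hits_f <- hits_f + f$signal
    hits_m <- hits_m + m$signal
  }
  expect_gte(ordered, n_rep - 1L)
  expect_gte(hits_f, n_rep - 1L)
  expect_lte(hits_m, 1L)
})
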