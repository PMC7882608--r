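#' Define an analysis stratum
#'
#' A stratum is a pure declarative filter over reports — a conjunction of
#' (field, op, value) clauses — optionally combined with extra PT exclusions
#' merged into the event definition downstream (used e.g. to reclassify
#' non-small cell lung cancer reports as non-cases in a sensitivity run).
#'
#' Supported fields: `sex`, `age_group`, `country`, `region`,
#' `receipt_year`, `receipt_quarter`, and the derived predicate `diabetes`
#' (report has a diabetes indication PT or an antidiabetic co-medication).
#' Supported ops: `==`, `!=`, `<`, `<=`, `>`, `>=`, `in`, `not_in`.
#'
#' @param name unique stratum name.
#' @param clauses list of `list(field, op, value)` clauses, AND-composed;
#'   empty list = the whole collection.
#' @param extra_pt_exclusions PT codes appended to the event definition's
#'   exclusion set in this stratum.
#' @param drop_extra_pt_reports if TRUE, reports carrying any
#'   `extra_pt_exclusions` PT are removed from the stratum entirely instead
#'   of being reclassified as non-cases.
#' @return A `stratum_spec`.
#' @export
stratum_spec <- function(name, clauses = list(),
                         extra_pt_exclusions = character(),
                         drop_extra_pt_reports = FALSE) {
  for (cl in clauses) {
    if (!all(c("field", "op", "value") %in% names(cl)))
      stop("each clause needs field, op and value")
    if (!(cl$field %in% c("sex", "age_group", "country", "region",
                          "receipt_year", "receipt_quarter", "diabetes")))
      stop("unknown stratum field: ", cl$field)
    if (!(cl$op %in% c("==", "!=", "<", "<=", ">", ">=", "in", "not_in")))
      stop("unknown stratum op: ", cl$op)
  }
  structure(list(name = name, clauses = clauses,
                 extra_pt_exclusions = as.character(extra_pt_exclusions),
                 drop_extra_pt_reports = drop_extra_pt_reports),
            class = "stratum_spec")
}

# Diabetes proxy: indication PT in the packaged diabetes PT set, or any drug
# mention resolving to the antidiabetic class. SRS databases carry no
# diagnosis table, so indication + co-medication is the standard workaround.
has_diabetes <- function(collection, hierarchy, dictionary) {
  dia_pts <- pts_under_hlt(hierarchy,
                           hlt_code(hierarchy, "Diabetes mellitus (incl subtypes)"))
  by_indi <- collection$demo$report_id %in%
    collection$indications$report_id[collection$indications$pt_code %in% dia_pts]
  by_drug <- unname(is_exposed(collection, "antidiabetic", dictionary))
  by_indi | by_drug
}

eval_clause <- function(values, op, value) {
  switch(op,
         "==" = values == value,
         "!=" = values != value,
         "<"  = values < value,
         "<=" = values <= value,
         ">"  = values > value,
         ">=" = values >= value,
         "in" = values %in% value,
         "not_in" = !(values %in% value),
         stop("unknown op: ", op))
}

#' Filter a collection to one stratum
#'
#' Retains reports satisfying every clause of the stratum. Negative clauses are
#' interpreted narrowly: `(region != Europe)` removes Europe reports only,
#' keeping unknown-region reports (unknowns are tracked as their own level,
#' never silently removed). With `drop_extra_pt_reports = TRUE`, reports
#' carrying an extra-excluded PT are also removed here.
#'
#' @param collection a `report_collection`.
#' @param spec a `stratum_spec`.
#' @param hierarchy,dictionary required only when a clause uses the derived
#'   `diabetes` field or reports are dropped by PT.
#' @return The filtered `report_collection`.
#' @export
apply_stratum <- function(collection, spec, hierarchy = NULL,
                          dictionary = NULL) {
  keep <- rep(TRUE, nrow(collection$demo))
  for (cl in spec$clauses) {
    values <- if (cl$field == "diabetes") {
      if (is.null(hierarchy) || is.null(dictionary))
        stop("diabetes clauses need hierarchy and dictionary")
      has_diabetes(collection, hierarchy, dictionary)
    } else collection$demo[[cl$field]]
    keep <- keep & eval_clause(values, cl$op, cl$value)
  }
  if (spec$drop_extra_pt_reports && length(spec$extra_pt_exclusions)) {
    carriers <- unique(collection$reactions$report_id[
      collection$reactions$pt_code %in% spec$extra_pt_exclusions])
    keep <- keep & !(collection$demo$report_id %in% carriers)
  }
  subset_reports(collection, which(keep))
}

# Event definition effective inside a stratum.
stratum_event <- function(event_def, spec) {
  if (!length(spec$extra_pt_exclusions) || spec$drop_extra_pt_reports)
    return(event_def)
  event_definition(event_def$hlt,
                   union(event_def$excluded_pts, spec$extra_pt_exclusions),
                   label = event_def$label)
}

#' Built-in subset and sensitivity strata
#'
#' The panel used for robustness checks: all reports; female and male
#' subsets (each with a gender-restricted comparator); Europe removed
#' (unknown-region reports retained); non-small cell lung cancer reports
#' reclassified as non-cases; diabetes-restricted; and an early reporting
#' window.
#'
#' @param hierarchy a `term_hierarchy` (for the NSCLC PT code).
#' @param early_years year range of the early-window stratum.
#' @return list of `stratum_spec`s.
#' @export
default_strata <- function(hierarchy = load_hierarchy(),
                           early_years = c(2004, 2011)) {
  nsclc <- pt_code(hierarchy, "Non-small cell lung cancer")
  list(
    stratum_spec("all"),
    stratum_spec("female", list(list(field = "sex", op = "==", value = "female"))),
    stratum_spec("male", list(list(field = "sex", op = "==", value = "male"))),
    stratum_spec("no_europe",
                 list(list(field = "region", op = "!=", value = "Europe"))),
    stratum_spec("excl_nsclc", extra_pt_exclusions = nsclc),
    stratum_spec("diabetes",
                 list(list(field = "diabetes", op = "==", value = TRUE))),
    stratum_spec("early_window",
                 list(list(field = "receipt_year", op = ">=", value = early_years[1]),
                      list(field = "receipt_year", op = "<=", value = early_years[2])))
  )
}

#' Run the disproportionality panel over drugs and strata
#'
#' For each drug query (the class-level aggregate first, then single
#' generics alphabetically) and each stratum (in list order) the collection
#' is filtered, classified and summarised into one `signal_result` row.
#' Strata with zero exposed or zero event reports yield a row of
#' undefined-markers rather than being dropped. Output row order is
#' deterministic.
#'
#' @param collection a cleaned `report_collection`.
#' @param event_def an `event_definition`.
#' @param drug_queries character vector of drug classes/generics; the first
#'   element is conventionally the class-level query. Single generics are
#'   sorted alphabetically after it.
#' @param strata list of `stratum_spec`s (default [default_strata()]).
#' @param hierarchy,dictionary vocabularies.
#' @param alpha,ic_ci_method,criteria passed through to [signal_result()].
#' @return data frame, one row per (drug x stratum).
#' @export
run_panel <- function(collection, event_def, drug_queries,
                      strata = default_strata(hierarchy),
                      hierarchy = load_hierarchy(),
                      dictionary = load_dictionary(),
                      alpha = 0.05, ic_ci_method = "normal",
                      criteria = signal_criteria()) {
  nm <- vapply(strata, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("stratum names must be unique")
  drug_queries <- c(drug_queries[1], sort(drug_queries[-1]))
  rows <- list()
  for (dq in drug_queries) {
    for (sp in strata) {
      sub <- apply_stratum(collection, sp, hierarchy, dictionary)
      ev <- stratum_event(event_def, sp)
      lab <- classify(sub, ev, dq, hierarchy, dictionary)
      cc <- attr(lab, "cell_counts")
      row <- if ((cc[["a"]] + cc[["b"]]) == 0 || (cc[["a"]] + cc[["c"]]) == 0 ||
                 sum(cc) == 0) {
        data.frame(drug = dq, stratum = sp$name, label = ev$label,
                   a = cc[["a"]], b = cc[["b"]], c = cc[["c"]], d = cc[["d"]],
                   expected = NA_real_, ror = NA_real_, ror_low = NA_real_,
                   ror_high = NA_real_, ic = NA_real_, ic_low = NA_real_,
                   ic_high = NA_real_, signal = FALSE,
                   criteria_detail = "undefined", corrected = FALSE,
                   stringsAsFactors = FALSE)
      } else {
        res <- signal_result(build_table(lab), alpha = alpha,
                             ic_ci_method = ic_ci_method, criteria = criteria)
        signal_result_row(res, drug = dq, stratum = sp$name, label = ev$label)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
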