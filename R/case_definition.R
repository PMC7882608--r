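#' Case status of reports for a composite event
#'
#' A report is a case when at least one of its reaction PTs lies under the
#' event's HLT and is not in the exclusion set. A report whose only
#' qualifying PTs are excluded is a non-case. PT codes absent from the
#' hierarchy never qualify (they are logged once per unknown code).
#'
#' @param collection a `report_collection`.
#' @param event_def an `event_definition`.
#' @param hierarchy a `term_hierarchy`.
#' @return named logical vector, one element per report (names = report_id).
#' @export
is_case <- function(collection, event_def, hierarchy) {
  qualifying <- setdiff(pts_under_hlt(hierarchy, event_def$hlt),
                        event_def$excluded_pts)
  unknown <- setdiff(unique(collection$reactions$pt_code),
                     hierarchy$terms$pt_code)
  if (length(unknown))
    message("PT code(s) not in hierarchy treated as non-qualifying: ",
            paste(unknown, collapse = ", "))
  hit <- collection$reactions$report_id[collection$reactions$pt_code %in% qualifying]
  out <- collection$demo$report_id %in% hit
  names(out) <- collection$demo$report_id
  out
}

#' Exposure status of reports for a drug class or generic
#'
#' A report is exposed when any of its drug mentions resolves (after name
#' normalization) to a generic in the query set and was reported in one of
#' the accepted roles. By default all three roles count — suspected,
#' interacting and concomitant drugs alike.
#'
#' @param collection a `report_collection`.
#' @param query drug class label (e.g. `"ACEI"`) or generic name.
#' @param dictionary a `drug_dictionary`.
#' @param roles roles counting as exposure (default all three).
#' @return named logical vector, one element per report.
#' @export
is_exposed <- function(collection, query, dictionary,
                       roles = c("suspect", "interacting", "concomitant")) {
  gens <- query_generics(query, dictionary)
  g <- if ("generic_name" %in% names(collection$drugs) &&
           !anyNA(collection$drugs$generic_name))
    collection$drugs$generic_name
  else resolve_generic(collection$drugs$verbatim_name, dictionary)
  hit <- collection$drugs$report_id[!is.na(g) & g %in% gens &
                                      collection$drugs$role %in% roles]
  out <- collection$demo$report_id %in% hit
  names(out) <- collection$demo$report_id
  out
}

#' Label every report with case and exposure flags
#'
#' The case/non-case classification step: each report receives a
#' (case, exposed) flag pair, and the four 2x2 cell counts are attached.
#' Counting is report-level: a report counts once however many qualifying
#' PTs or query-class drug mentions it carries.
#'
#' @inheritParams is_case
#' @inheritParams is_exposed
#' @param exposure_query drug class label or generic name.
#' @return The collection with logical columns `is_case`, `is_exposed` added
#'   to `$demo` and a `cell_counts` attribute `c(a, b, c, d)` (exposed
#'   cases, exposed non-cases, unexposed cases, unexposed non-cases).
#' @export
classify <- function(collection, event_def, exposure_query, hierarchy,
                     dictionary,
                     roles = c("suspect", "interacting", "concomitant")) {
  cs <- is_case(collection, event_def, hierarchy)
  ex <- is_exposed(collection, exposure_query, dictionary, roles)
  collection$demo$is_case <- unname(cs)
  collection$demo$is_exposed <- unname(ex)
  attr(collection, "cell_counts") <- c(
    a = sum(ex & cs), b = sum(ex & !cs),
    c = sum(!ex & cs), d = sum(!ex & !cs)
  )
  collection
}
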