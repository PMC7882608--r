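#' Construct a report collection
#'
#' The in-memory representation of a FAERS-like spontaneous report database:
#' one demographics row per report plus child tables of drug mentions,
#' reaction PTs and indication PTs keyed by `report_id`. A provenance log
#' accumulates counts in/out for every cleaning rule so that
#' `|out| + sum(removed) == |in|` is always assertable.
#'
#' @param demo data frame: `report_id`, `version`, `sex`, `age_group`,
#'   `country`, `region`, `receipt_year`, `receipt_quarter`, `outcomes`
#'   (semicolon-separated subset of hospitalization / disability /
#'   life-threatening / death, possibly empty).
#' @param drugs data frame: `report_id`, `verbatim_name`, `role`
#'   (suspect / interacting / concomitant), optionally `generic_name`.
#' @param reactions,indications data frames: `report_id`, `pt_code`.
#' @param provenance data frame: `rule`, `n` (cleaning log).
#' @return A `report_collection`.
#' @export
report_collection <- function(demo, drugs, reactions, indications,
                              provenance = NULL) {
  demo$report_id <- as.character(demo$report_id)
  demo$version <- as.integer(demo$version %||% 1L)
  demo$receipt_year <- as.integer(demo$receipt_year)
  demo$receipt_quarter <- as.integer(demo$receipt_quarter)
  if (is.null(demo$outcomes)) demo$outcomes <- ""
  if (is.null(demo$region)) demo$region <- assign_region(demo$country)
  for (col in c("sex", "age_group", "country", "outcomes"))
    demo[[col]] <- as.character(demo[[col]])
  bad_sex <- !(demo$sex %in% SEX_LEVELS)
  if (any(bad_sex)) stop("invalid sex value(s): ",
                         paste(unique(demo$sex[bad_sex]), collapse = ", "))
  bad_age <- !(demo$age_group %in% AGE_LEVELS)
  if (any(bad_age)) stop("invalid age_group value(s): ",
                         paste(unique(demo$age_group[bad_age]), collapse = ", "))
  bad_role <- !(drugs$role %in% c("suspect", "interacting", "concomitant"))
  if (any(bad_role)) stop("invalid drug role(s): ",
                          paste(unique(drugs$role[bad_role]), collapse = ", "))
  if (is.null(provenance))
    provenance <- data.frame(rule = "input", n = nrow(demo))
  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 indications = indications, provenance = provenance),
            class = "report_collection")
}

#' @export
print.report_collection <- function(x, ...) {
  cat("<report_collection> ", nrow(x$demo), " reports, ",
      nrow(x$drugs), " drug mentions, ", nrow(x$reactions),
      " reaction PTs\n", sep = "")
  invisible(x)
}

#' Number of reports in a collection
#' @param x a `report_collection`.
#' @export
n_reports <- function(x) nrow(x$demo)

add_provenance <- function(collection, rule, n) {
  collection$provenance <- rbind(collection$provenance,
                                 data.frame(rule = rule, n = as.integer(n)))
  collection
}

# Subset a collection to a set of demo row indices, dropping child rows of
# removed reports. Keeps provenance untouched (callers log their own rule).
subset_reports <- function(collection, keep_idx) {
  demo <- collection$demo[keep_idx, , drop = FALSE]
  ids <- demo$report_id
  out <- collection
  out$demo <- demo
  out$drugs <- collection$drugs[collection$drugs$report_id %in% ids, , drop = FALSE]
  out$reactions <- collection$reactions[collection$reactions$report_id %in% ids, , drop = FALSE]
  out$indications <- collection$indications[collection$indications$report_id %in% ids, , drop = FALSE]
  rownames(out$demo) <- NULL
  out
}

#' Map a country code to a reporting region
#'
#' Deterministic lookup in the packaged ISO-3166 alpha-2 country-to-region
#' table (America / Europe / Asia / Oceania / Africa); unmapped, empty or
#' `"unknown"` codes map to `"unknown"`. Total function: never errors.
#'
#' @param country_code character vector of country codes.
#' @param region_map optional data frame `country`, `region` overriding the
#'   packaged table.
#' @return character vector of regions.
#' @export
assign_region <- function(country_code,
                          region_map = NULL) {
  if (is.null(region_map)) region_map <- .region_map_cache()
  r <- region_map$region[match(toupper(as.character(country_code)),
                               region_map$country)]
  r[is.na(r)] <- "unknown"
  r
}

.region_env <- new.env(parent = emptyenv())
.region_map_cache <- function() {
  if (is.null(.region_env$map))
    .region_env$map <- read_tsv_strict(fs_extdata("country_region.tsv"))
  .region_env$map
}

#' Bin a raw age in years into reporting age groups
#'
#' Boundaries are left-closed at 18, 45, 65 and 75: ages of exactly 45, 65
#' or 75 fall in the older group (so 75 is reported as `">75"`). The
#' boundary vector is configurable because published tables rarely state
#' their convention.
#'
#' @param age numeric vector of ages in years; `NA` maps to `"unknown"`.
#' @param breaks ascending boundary vector (default `c(18, 45, 65, 75)`).
#' @return character vector of age-group labels.
#' @export
bin_age <- function(age, breaks = c(18, 45, 65, 75)) {
  labs <- AGE_LEVELS[seq_len(length(breaks) + 1)]
  idx <- findInterval(age, breaks, left.open = FALSE) + 1L
  out <- labs[idx]
  out[is.na(age)] <- "unknown"
  out
}

default_schema <- function() {
  list(
    delimiter = "\t",
    demo = list(report_id = "report_id", version = "version", sex = "sex",
                age = "age", age_group = "age_group", country = "country",
                receipt_year = "receipt_year",
                receipt_quarter = "receipt_quarter", outcomes = "outcomes"),
    drug = list(report_id = "report_id", verbatim_name = "verbatim_name",
                role = "role"),
    reac = list(report_id = "report_id", pt_code = "pt_code"),
    indi = list(report_id = "report_id", pt_code = "pt_code")
  )
}

# Merge user schema over defaults (shallow, per table).
merge_schema <- function(schema_config) {
  s <- default_schema()
  if (is.null(schema_config)) return(s)
  for (tb in intersect(names(schema_config), names(s))) {
    if (tb == "delimiter") next
    for (f in names(schema_config[[tb]])) s[[tb]][[f]] <- schema_config[[tb]][[f]]
  }
  if (!is.null(schema_config$delimiter)) s$delimiter <- schema_config$delimiter
  s
}

require_cols <- function(tab, cols, table_name) {
  miss <- setdiff(unlist(cols), names(tab))
  if (length(miss))
    stop("table '", table_name, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
}

#' Read FAERS-like report tables into a collection
#'
#' Joins a demographics table with drug, reaction and indication child
#' tables sharing the `report_id` key. Child rows referencing a report_id
#' absent from the demographics table are dropped and counted in the
#' provenance log as orphans. If the demographics table carries a raw `age`
#' column instead of `age_group`, ages are binned with [bin_age()].
#'
#' @param demo_path,drug_path,reac_path,indi_path paths to delimited text
#'   tables with header rows.
#' @param schema_config optional nested list (or YAML file read with
#'   [yaml::read_yaml()]) remapping column names per table and setting the
#'   `delimiter` (default tab).
#' @return A `report_collection`; one report per distinct
#'   (`report_id`, `version`) pair.
#' @export
read_tables <- function(demo_path, drug_path, reac_path, indi_path,
                        schema_config = NULL) {
  s <- merge_schema(schema_config)
  for (p in c(demo_path, drug_path, reac_path, indi_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  raw_demo <- read_tsv_strict(demo_path, s$delimiter)
  raw_drug <- read_tsv_strict(drug_path, s$delimiter)
  raw_reac <- read_tsv_strict(reac_path, s$delimiter)
  raw_indi <- read_tsv_strict(indi_path, s$delimiter)

  dm <- s$demo
  has_age_group <- dm$age_group %in% names(raw_demo)
  need <- c(dm$report_id, dm$sex, dm$country, dm$receipt_year,
            dm$receipt_quarter, if (!has_age_group) dm$age)
  require_cols(raw_demo, need, "demo")
  require_cols(raw_drug, s$drug, "drug")
  require_cols(raw_reac, s$reac, "reac")
  require_cols(raw_indi, s$indi, "indi")

  demo <- data.frame(
    report_id = raw_demo[[dm$report_id]],
    version = if (dm$version %in% names(raw_demo))
      suppressWarnings(as.integer(raw_demo[[dm$version]])) else 1L,
    sex = raw_demo[[dm$sex]],
    age_group = if (has_age_group) raw_demo[[dm$age_group]]
      else bin_age(suppressWarnings(as.numeric(raw_demo[[dm$age]]))),
    country = raw_demo[[dm$country]],
    receipt_year = suppressWarnings(as.integer(raw_demo[[dm$receipt_year]])),
    receipt_quarter = suppressWarnings(as.integer(raw_demo[[dm$receipt_quarter]])),
    outcomes = if (dm$outcomes %in% names(raw_demo)) raw_demo[[dm$outcomes]] else ""
  )
  demo$sex[!(demo$sex %in% SEX_LEVELS)] <- "unknown"
  demo$age_group[!(demo$age_group %in% AGE_LEVELS)] <- "unknown"
  demo$version[is.na(demo$version)] <- 1L

  # unparseable demographics rows: bad id / year / quarter
  bad <- !nzchar(demo$report_id) | is.na(demo$receipt_year) |
    is.na(demo$receipt_quarter) | !(demo$receipt_quarter %in% 1:4)
  n_bad <- sum(bad)
  demo <- demo[!bad, , drop = FALSE]
  # duplicated (report_id, version) rows collapse to their first occurrence
  key <- paste(demo$report_id, demo$version, sep = "\r")
  n_dup_rows <- sum(duplicated(key))
  demo <- demo[!duplicated(key), , drop = FALSE]

  ids <- unique(demo$report_id)
  drugs <- data.frame(report_id = raw_drug[[s$drug$report_id]],
                      verbatim_name = raw_drug[[s$drug$verbatim_name]],
                      role = raw_drug[[s$drug$role]])
  drugs$role[!(drugs$role %in% c("suspect", "interacting", "concomitant"))] <- "concomitant"
  reac <- data.frame(report_id = raw_reac[[s$reac$report_id]],
                     pt_code = raw_reac[[s$reac$pt_code]])
  indi <- data.frame(report_id = raw_indi[[s$indi$report_id]],
                     pt_code = raw_indi[[s$indi$pt_code]])

  orphan <- c(drug = sum(!(drugs$report_id %in% ids)),
              reac = sum(!(reac$report_id %in% ids)),
              indi = sum(!(indi$report_id %in% ids)))
  drugs <- drugs[drugs$report_id %in% ids, , drop = FALSE]
  reac <- reac[reac$report_id %in% ids, , drop = FALSE]
  indi <- indi[indi$report_id %in% ids, , drop = FALSE]
  rownames(demo) <- rownames(drugs) <- rownames(reac) <- rownames(indi) <- NULL

  prov <- data.frame(
    rule = c("input", "skipped_unparseable_demo_rows",
             "collapsed_duplicate_demo_rows", "orphan_drug_rows",
             "orphan_reaction_rows", "orphan_indication_rows"),
    n = as.integer(c(nrow(demo), n_bad, n_dup_rows, orphan))
  )
  report_collection(demo, drugs, reac, indi, provenance = prov)
}

#' Clean a report collection
#'
#' Applies, in order: removal of reports with no drug mention or no reaction
#' PT ("missing data"), restriction to the study window (receipt year and
#' quarter), versioning deduplication (highest `version` per `report_id`
#' wins), and optional conservative field-match deduplication. Demographic
#' missingness (unknown sex/age/country) is deliberately *not* a removal
#' criterion: unknown strata are retained and reported.
#'
#' Field-match duplicates are reports agreeing exactly on sex, age group,
#' country, receipt year/quarter, the sorted set of (generic) drug names and
#' the sorted set of reaction PTs; the first by file order is kept. This
#' approximates regulator-side duplicate detection, whose exact algorithm is
#' not public, and can be switched off.
#'
#' @param collection a `report_collection`.
#' @param window_start,window_end study window bounds as `"YYYYQn"` strings
#'   or `c(year, quarter)`; `NULL` disables window filtering.
#' @param fieldmatch_dedup apply the field-match duplicate rule (default TRUE).
#' @param dictionary optional `drug_dictionary`; when supplied, field-match
#'   keys use resolved generic names, otherwise normalized verbatim names.
#' @return A cleaned `report_collection` with an extended provenance log.
#' @export
clean <- function(collection, window_start = NULL, window_end = NULL,
                  fieldmatch_dedup = TRUE, dictionary = NULL) {
  x <- collection
  n_in <- nrow(x$demo)

  # missing data: no drug mention or no reaction PT
  has_drug <- x$demo$report_id %in% unique(x$drugs$report_id)
  has_reac <- x$demo$report_id %in% unique(x$reactions$report_id)
  keep <- has_drug & has_reac
  n_missing <- sum(!keep)
  x <- subset_reports(x, which(keep))

  # study window
  n_window <- 0L
  if (!is.null(window_start) || !is.null(window_end)) {
    idx <- yq_index(x$demo$receipt_year, x$demo$receipt_quarter)
    lo <- if (is.null(window_start)) -Inf else do.call(yq_index, as.list(parse_yq(window_start)))
    hi <- if (is.null(window_end)) Inf else do.call(yq_index, as.list(parse_yq(window_end)))
    if (lo > hi) stop("window_start must not be after window_end")
    keep <- idx >= lo & idx <= hi
    n_window <- sum(!keep)
    x <- subset_reports(x, which(keep))
  }

  # versioning: keep the highest version per report_id
  o <- order(x$demo$report_id, -x$demo$version)
  dup_ver <- duplicated(x$demo$report_id[o])
  drop_rows <- sort(o[dup_ver])
  n_version <- length(drop_rows)
  if (n_version) x <- subset_reports(x, setdiff(seq_len(nrow(x$demo)), drop_rows))

  # field-match duplicates (first by file order kept)
  n_fieldmatch <- 0L
  if (fieldmatch_dedup && nrow(x$demo)) {
    dnames <- if (!is.null(dictionary)) {
      g <- resolve_generic(x$drugs$verbatim_name, dictionary)
      ifelse(is.na(g), normalize_drug_name(x$drugs$verbatim_name), g)
    } else normalize_drug_name(x$drugs$verbatim_name)
    drug_key <- vapply(split(dnames, x$drugs$report_id),
                       function(v) paste(sort(unique(v)), collapse = "|"),
                       character(1))
    reac_key <- vapply(split(x$reactions$pt_code, x$reactions$report_id),
                       function(v) paste(sort(unique(v)), collapse = "|"),
                       character(1))
    key <- paste(x$demo$sex, x$demo$age_group, x$demo$country,
                 x$demo$receipt_year, x$demo$receipt_quarter,
                 drug_key[x$demo$report_id], reac_key[x$demo$report_id],
                 sep = "\r")
    dup <- duplicated(key)
    n_fieldmatch <- sum(dup)
    if (n_fieldmatch) x <- subset_reports(x, which(!dup))
  }

  n_out <- nrow(x$demo)
  if (n_out == 0L) warning("cleaning removed every report")
  stopifnot(n_out + n_missing + n_window + n_version + n_fieldmatch == n_in)
  x <- add_provenance(x, "clean_input", n_in)
  x <- add_provenance(x, "removed_missing_data", n_missing)
  x <- add_provenance(x, "removed_outside_window", n_window)
  x <- add_provenance(x, "removed_duplicate_version", n_version)
  x <- add_provenance(x, "removed_duplicate_fieldmatch", n_fieldmatch)
  add_provenance(x, "clean_output", n_out)
}
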