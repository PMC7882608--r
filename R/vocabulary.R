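#' Load a PT-to-HLT term hierarchy
#'
#' Reads a miniature MedDRA-style vocabulary: each Preferred Term (PT) maps
#' to exactly one Higher Level Term (HLT). The packaged vocabulary covers
#' the lower respiratory tract neoplasm HLT (including the benign /
#' secondary PTs that must be excluded from a primary-malignancy case
#' definition) plus decoy HLTs used as reaction and indication background.
#'
#' @param path TSV with columns `pt_code`, `pt_name`, `hlt_code`, `hlt_name`.
#'   Defaults to the packaged miniature vocabulary.
#' @return A `term_hierarchy` object: data frame of terms plus name lookup.
#' @export
load_hierarchy <- function(path = fs_extdata("meddra_mini.tsv")) {
  tab <- read_tsv_strict(path)
  need <- c("pt_code", "pt_name", "hlt_code", "hlt_name")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("hierarchy file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$pt_code))
    stop("each PT must map to exactly one HLT")
  structure(list(terms = tab), class = "term_hierarchy")
}

#' @export
print.term_hierarchy <- function(x, ...) {
  cat("<term_hierarchy> ", nrow(x$terms), " PTs under ",
      length(unique(x$terms$hlt_code)), " HLTs\n", sep = "")
  invisible(x)
}

# PT codes under one HLT.
pts_under_hlt <- function(hierarchy, hlt_code) {
  hierarchy$terms$pt_code[hierarchy$terms$hlt_code == hlt_code]
}

#' Look up a PT code by its display name
#'
#' @param hierarchy a `term_hierarchy`.
#' @param name PT display name(s), matched case-insensitively.
#' @return PT code(s).
#' @export
pt_code <- function(hierarchy, name) {
  i <- match(tolower(name), tolower(hierarchy$terms$pt_name))
  if (anyNA(i)) stop("PT name(s) not in hierarchy: ",
                     paste(name[is.na(i)], collapse = ", "))
  hierarchy$terms$pt_code[i]
}

#' Look up an HLT code by its display name
#' @inheritParams pt_code
#' @export
hlt_code <- function(hierarchy, name) {
  i <- match(tolower(name), tolower(hierarchy$terms$hlt_name))
  if (anyNA(i)) stop("HLT name(s) not in hierarchy: ",
                     paste(name[is.na(i)], collapse = ", "))
  hierarchy$terms$hlt_code[i]
}

#' Define a composite adverse event
#'
#' An event is one HLT minus an explicit set of excluded PTs; a report is a
#' case when it carries at least one non-excluded PT under the HLT. This is
#' the standard mechanism for restricting a broad MedDRA grouping (here,
#' lower respiratory tract neoplasms) to a clinically homogeneous subset
#' (primary malignant lung cancer).
#'
#' @param hlt HLT code.
#' @param excluded_pts PT codes excluded from the case definition; must all
#'   fall under `hlt`.
#' @param label human-readable event label.
#' @param hierarchy a `term_hierarchy` used to validate the definition.
#' @return An `event_definition` object.
#' @export
event_definition <- function(hlt, excluded_pts = character(), label = hlt,
                             hierarchy = NULL) {
  excluded_pts <- unique(as.character(excluded_pts))
  if (!is.null(hierarchy)) {
    under <- pts_under_hlt(hierarchy, hlt)
    if (!length(under)) stop("HLT not in hierarchy: ", hlt)
    bad <- setdiff(excluded_pts, under)
    if (length(bad)) stop("excluded PTs not under HLT ", hlt, ": ",
                          paste(bad, collapse = ", "))
  }
  structure(list(hlt = hlt, excluded_pts = excluded_pts, label = label),
            class = "event_definition")
}

#' The primary malignant lung cancer event definition
#'
#' Lower respiratory tract neoplasm HLT minus the six PTs that are not
#' primary malignant lung cancer (pulmonary carcinoid, leukaemic
#' infiltration, endobronchial lipoma, the two benign neoplasm terms, and
#' lung metastases).
#'
#' @param hierarchy a `term_hierarchy` (defaults to the packaged one).
#' @return An `event_definition`.
#' @export
lung_cancer_event <- function(hierarchy = load_hierarchy()) {
  excl <- c("Carcinoid tumour pulmonary", "Leukaemic infiltration pulmonary",
            "Endobronchial lipoma", "Benign respiratory tract neoplasm",
            "Benign lung neoplasm", "Metastases to lung")
  event_definition(
    hlt = hlt_code(hierarchy, "Lower respiratory tract neoplasms"),
    excluded_pts = pt_code(hierarchy, excl),
    label = "primary malignant lung cancer",
    hierarchy = hierarchy
  )
}

#' Load a drug dictionary
#'
#' Maps normalized verbatim drug strings to generic names, and generics to
#' drug classes. The packaged dictionary covers the ten FDA-approved ACE
#' inhibitors, irbesartan (ARB comparator), thiazide diuretics (reference
#' class for adjusted estimates), an antidiabetic class (used as a diabetes
#' co-medication proxy) and common decoy drugs.
#'
#' @param path TSV with columns `synonym`, `generic`, `class`.
#' @return A `drug_dictionary` object.
#' @export
load_dictionary <- function(path = fs_extdata("drug_dictionary.tsv")) {
  tab <- read_tsv_strict(path)
  need <- c("synonym", "generic", "class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("dictionary file missing column(s): ",
                         paste(miss, collapse = ", "))
  tab$synonym <- toupper(tab$synonym)
  gen2cls <- tab$class[!duplicated(tab$generic)]
  names(gen2cls) <- tab$generic[!duplicated(tab$generic)]
  structure(list(synonyms = tab, generic_to_class = gen2cls),
            class = "drug_dictionary")
}

#' @export
print.drug_dictionary <- function(x, ...) {
  cat("<drug_dictionary> ", nrow(x$synonyms), " synonyms, ",
      length(x$generic_to_class), " generics, classes: ",
      paste(sort(unique(x$generic_to_class)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Tokens stripped from verbatim drug strings before lookup: doses, units,
# salts and formulation/route words. Deliberately no fuzzy matching.
.DOSE_TOKENS <- c("MG", "MCG", "G", "ML", "MGS", "HCL", "HCT",
                  "TABLET", "TABLETS", "TAB", "TABS", "CAPSULE", "CAPSULES",
                  "CAP", "CAPS", "ORAL", "INJECTION", "SOLUTION", "XR", "ER",
                  "SR", "CR", "DAILY", "QD", "BID", "UNKNOWN")

#' Normalize a verbatim drug name
#'
#' Uppercases, strips punctuation, removes dose/unit/formulation tokens and
#' bare numbers, and collapses whitespace, yielding the key used for exact
#' dictionary lookup.
#'
#' @param x character vector of verbatim names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(x)
  x <- gsub("[^A-Z0-9 ]+", " ", x)
  x <- gsub("[0-9]+(\\.[0-9]+)?", " ", x)
  toks <- strsplit(trimws(gsub(" +", " ", x)), " ", fixed = TRUE)
  vapply(toks, function(t) paste(t[!(t %in% .DOSE_TOKENS)], collapse = " "),
         character(1))
}

#' Resolve verbatim drug names to generics
#'
#' @param x verbatim names.
#' @param dictionary a `drug_dictionary`.
#' @return generic names; `NA` where unresolved.
#' @export
resolve_generic <- function(x, dictionary) {
  key <- normalize_drug_name(x)
  dictionary$synonyms$generic[match(key, dictionary$synonyms$synonym)]
}

#' Generics belonging to a drug class or a single generic
#'
#' @param query a class label (e.g. `"ACEI"`) or a generic name.
#' @param dictionary a `drug_dictionary`.
#' @return character vector of generic names in the query set.
#' @export
query_generics <- function(query, dictionary) {
  cls <- dictionary$generic_to_class
  if (query %in% cls) return(names(cls)[cls == query])
  if (query %in% names(cls)) return(query)
  stop("unresolvable drug query (not a known class or generic): ", query)
}
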