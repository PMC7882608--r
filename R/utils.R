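#' @keywords internal
"_PACKAGE"

#' Display rounding: half away from zero
#'
#' Published pharmacovigilance tables round half away from zero, unlike base
#' [round()]'s round-half-to-even. Used for all displayed estimates (2 dp)
#' and percentages (1 dp).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Truncation alternative for percentage display (some published tables
# appear to truncate rather than round).
trunc_digits <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a data file shipped with the package
#'
#' Thin wrapper around [system.file()] that errors when the file is absent.
#'
#' @param ... path components under `inst/extdata`.
#' @return Absolute path to the file.
#' @export
fs_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "faersignal")
  if (!nzchar(p)) stop("packaged data file not found: ", file.path(...))
  p
}

# Parse "2004Q1" / c(2004, 1) / list(2004, 1) into c(year, quarter).
parse_yq <- function(x) {
  if (is.character(x)) {
    m <- regmatches(x, regexec("^([0-9]{4})[Qq]([1-4])$", x))[[1]]
    if (length(m) != 3) stop("cannot parse year-quarter: ", x)
    return(c(as.integer(m[2]), as.integer(m[3])))
  }
  x <- as.integer(unlist(x))
  stopifnot(length(x) == 2, x[2] %in% 1:4)
  x
}

# Total order on (year, quarter).
yq_index <- function(year, quarter) year * 4L + (quarter - 1L)

read_tsv_strict <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = delim, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = if (delim == ",") "\"" else "",
                    na.strings = NULL, fileEncoding = "UTF-8")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

SEX_LEVELS <- c("male", "female", "unknown")
AGE_LEVELS <- c("<18", "18-44", "45-64", "65-74", ">75", "unknown")
REGION_LEVELS <- c("America", "Europe", "Asia", "Oceania", "Africa", "unknown")
OUTCOME_LEVELS <- c("hospitalization", "disability", "life-threatening", "death")
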