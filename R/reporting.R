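#' Descriptive characteristics table of exposed reports
#'
#' Summarises, among reports exposed to the query drug class, cases versus
#' non-cases by sex, age group, reporting region, reporting country (top
#' countries, then "Other countries", unknown last) and serious outcome.
#' Percentages are of the column total (cases or non-cases), rounded
#' half-away-from-zero to 1 decimal by default; `percent = "truncate"`
#' truncates instead, since published tables do not always state their
#' rounding rule. Serious-outcome rows are not mutually exclusive and need
#' not sum to 100.
#'
#' @param collection a collection classified with [classify()].
#' @param top_countries number of individually listed countries.
#' @param percent `"round"` (default) or `"truncate"`.
#' @return data frame: `block`, `level`, `cases`, `cases_pct`, `noncases`,
#'   `noncases_pct`.
#' @export
describe <- function(collection, top_countries = 4, percent = c("round", "truncate")) {
  percent <- match.arg(percent)
  d <- collection$demo
  if (is.null(d$is_case) || is.null(d$is_exposed))
    stop("collection has not been classified; run classify()")
  d <- d[d$is_exposed, , drop = FALSE]
  pct <- function(x, tot) {
    p <- if (tot > 0) 100 * x / tot else 0
    if (percent == "round") round_half_away(p, 1) else trunc_digits(p, 1)
  }
  n_case <- sum(d$is_case)
  n_non <- sum(!d$is_case)
  one_block <- function(block, values, levels) {
    rows <- lapply(levels, function(lv) {
      ca <- sum(values == lv & d$is_case)
      no <- sum(values == lv & !d$is_case)
      data.frame(block = block, level = lv, cases = ca,
                 cases_pct = pct(ca, n_case), noncases = no,
                 noncases_pct = pct(no, n_non), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  known <- setdiff(unique(d$country), "unknown")
  cnt <- sort(table(factor(d$country, levels = known)), decreasing = TRUE)
  top <- names(cnt)[seq_len(min(top_countries, length(cnt)))]
  country_lab <- ifelse(d$country %in% top, d$country,
                        ifelse(d$country == "unknown", "unknown",
                               "Other countries"))
  out_levels <- function(lvl) vapply(
    strsplit(d$outcomes, ";", fixed = TRUE),
    function(o) lvl %in% o, logical(1))
  outcome_rows <- lapply(OUTCOME_LEVELS, function(lvl) {
    f <- out_levels(lvl)
    data.frame(block = "serious_outcome", level = lvl,
               cases = sum(f & d$is_case), cases_pct = pct(sum(f & d$is_case), n_case),
               noncases = sum(f & !d$is_case),
               noncases_pct = pct(sum(f & !d$is_case), n_non),
               stringsAsFactors = FALSE)
  })
  out <- rbind(
    one_block("sex", d$sex, SEX_LEVELS),
    one_block("age_group", d$age_group, AGE_LEVELS),
    one_block("country", country_lab,
              c(top, if (any(country_lab == "Other countries")) "Other countries",
                if (any(country_lab == "unknown")) "unknown")),
    one_block("region", d$region, REGION_LEVELS),
    do.call(rbind, outcome_rows)
  )
  rownames(out) <- NULL
  out
}

#' Build a run configuration
#'
#' Collects every input needed to reproduce an analysis run. Fully
#' serializable to YAML; [run_analysis()] writes the snapshot next to its
#' outputs so a run can be replayed from it.
#'
#' @param demo_path,drug_path,reac_path,indi_path input tables.
#' @param vocabulary_path,dictionary_path vocabulary files (defaults:
#'   packaged).
#' @param event list: `hlt_name`, `excluded_pt_names`, `label` (defaults:
#'   the primary malignant lung cancer definition).
#' @param drug_queries drug class + generics analysed (first = class-level).
#' @param window_start,window_end study window (`"YYYYQn"`).
#' @param strata `"default"`, `"none"`, or a list of `stratum_spec`s.
#' @param adjusted logical: fit the covariate-adjusted ROR.
#' @param regression a `regression_spec` for the adjusted fit.
#' @param criteria a [signal_criteria()] list.
#' @param ic_ci_method `"normal"` or `"noren"`.
#' @param out_dir output directory.
#' @param schema_config optional column remapping for [read_tables()].
#' @param seed integer seed for any stochastic step.
#' @return A `run_config`.
#' @export
run_config <- function(demo_path, drug_path, reac_path, indi_path,
                       vocabulary_path = NULL, dictionary_path = NULL,
                       event = NULL, drug_queries = c("ACEI"),
                       window_start = "2004Q1", window_end = "2020Q1",
                       strata = "default", adjusted = FALSE,
                       regression = regression_spec(),
                       criteria = signal_criteria(),
                       ic_ci_method = "normal",
                       out_dir = "faersignal_out", schema_config = NULL,
                       seed = 1L) {
  structure(list(demo_path = demo_path, drug_path = drug_path,
                 reac_path = reac_path, indi_path = indi_path,
                 vocabulary_path = vocabulary_path,
                 dictionary_path = dictionary_path, event = event,
                 drug_queries = drug_queries, window_start = window_start,
                 window_end = window_end, strata = strata,
                 adjusted = adjusted, regression = regression,
                 criteria = criteria, ic_ci_method = ic_ci_method,
                 out_dir = out_dir, schema_config = schema_config,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with fields matching [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(args$drug_queries)) args$drug_queries <- unlist(args$drug_queries)
  if (!is.null(args$regression)) args$regression <- do.call(regression_spec, args$regression)
  if (!is.null(args$criteria)) args$criteria <- do.call(signal_criteria, args$criteria)
  if (is.list(args$strata)) args$strata <- lapply(args$strata, function(s) do.call(stratum_spec, s))
  do.call(run_config, args)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$regression <- unclass(snap$regression)
  if (is.list(snap$strata))
    snap$strata <- lapply(snap$strata, unclass)
  snap
}

log_line <- function(con, stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Read -> clean -> classify -> disproportionality panel -> descriptive
#' table -> optional adjusted-ROR fit. Writes `signals.tsv`,
#' `descriptives.tsv`, `provenance.tsv`, optionally `fit_summary.tsv`, a
#' `config_snapshot.yaml` and a `run.log` into the output directory. On any
#' fatal error, partial outputs are removed before the error propagates.
#' Re-running on the same inputs and configuration reproduces byte-identical
#' outputs.
#'
#' @param config a `run_config` or path to a YAML config.
#' @return invisibly, a list with `panel`, `descriptives`, `fit` (or NULL),
#'   `collection` and the output paths.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  logcon <- file(file.path(out_dir, "run.log"), open = "wt")
  written <- file.path(out_dir, "run.log")
  ok <- FALSE
  on.exit({
    close(logcon)
    if (!ok) unlink(written)
  })

  hierarchy <- load_hierarchy(config$vocabulary_path %||% fs_extdata("meddra_mini.tsv"))
  dictionary <- load_dictionary(config$dictionary_path %||% fs_extdata("drug_dictionary.tsv"))
  event_def <- if (is.null(config$event)) lung_cancer_event(hierarchy) else
    event_definition(hlt_code(hierarchy, config$event$hlt_name),
                     pt_code(hierarchy, config$event$excluded_pt_names %||% character()),
                     label = config$event$label %||% config$event$hlt_name,
                     hierarchy = hierarchy)

  coll <- read_tables(config$demo_path, config$drug_path, config$reac_path,
                      config$indi_path, config$schema_config)
  log_line(logcon, "read", n_reports(coll), " reports read")
  coll <- clean(coll, config$window_start, config$window_end,
                dictionary = dictionary)
  log_line(logcon, "clean", n_reports(coll), " reports after cleaning")

  strata <- if (identical(config$strata, "default")) default_strata(hierarchy)
    else if (identical(config$strata, "none")) list(stratum_spec("all"))
    else config$strata
  panel <- run_panel(coll, event_def, config$drug_queries, strata,
                     hierarchy, dictionary,
                     ic_ci_method = config$ic_ci_method,
                     criteria = config$criteria)
  log_line(logcon, "panel", nrow(panel), " signal rows")

  labeled <- classify(coll, event_def, config$drug_queries[1], hierarchy,
                      dictionary)
  desc <- describe(labeled)

  fit <- NULL
  if (isTRUE(config$adjusted)) {
    fit <- adjusted_ror(labeled, config$regression, dictionary)
    log_line(logcon, "adjusted",
             sprintf("aROR %.4f (%.4f-%.4f), n=%d, converged=%s",
                     fit$aror, fit$aror_ci[1], fit$aror_ci[2], fit$n_used,
                     fit$converged))
  }

  paths <- list(signals = file.path(out_dir, "signals.tsv"),
                descriptives = file.path(out_dir, "descriptives.tsv"),
                provenance = file.path(out_dir, "provenance.tsv"),
                config = file.path(out_dir, "config_snapshot.yaml"))
  write_tsv(panel, paths$signals)
  write_tsv(desc, paths$descriptives)
  write_tsv(coll$provenance, paths$provenance)
  yaml::write_yaml(config_snapshot(config), paths$config)
  written <- c(written, unlist(paths))
  if (!is.null(fit)) {
    paths$fit <- file.path(out_dir, "fit_summary.tsv")
    write_tsv(fit_summary(fit), paths$fit)
    written <- c(written, paths$fit)
  }
  log_line(logcon, "done", "outputs in ", out_dir)
  ok <- TRUE
  invisible(list(panel = panel, descriptives = desc, fit = fit,
                 collection = coll, paths = paths))
}
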