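#' Configuration of the synthetic report generator
#'
#' Describes a FAERS-like population with known ground truth: per-class
#' exposure prevalences, a baseline odds of the target event among
#' unexposed reports, true exposure-event odds ratios (optionally
#' sex-specific), covariate distributions, optional confounding,
#' near-duplicate injection and per-field missingness. The same seed always
#' yields an identical collection.
#'
#' Default covariate margins loosely follow large spontaneous-report
#' databases (46/46/8 male/female/unknown; age mode 45-64; US-dominated
#' reporting). The default baseline event odds (0.02) is set so that
#' collections of 1e5-5e5 reports carry exposed-case counts in the hundreds
#' — the count regime of published class-level analyses — rather than the
#' raw per-report event rate of a database 10-100x larger; at that value a
#' sex stratum of a 5e5-report collection holds roughly 135 exposed cases,
#' enough to detect an odds ratio of 1.36 with over 90\% probability.
#'
#' @param n_reports number of base reports (before duplicate injection).
#' @param p_exposure named per-class exposure probabilities.
#' @param baseline_event_odds odds of the target event among unexposed.
#' @param true_or named per-class odds multipliers on the event.
#' @param true_or_by_sex optional list: class -> named vector of per-sex
#'   odds multipliers overriding `true_or` for that class.
#' @param covariate_dists named list of probability vectors for `sex`,
#'   `age_group`, `country` (levels = names) and `receipt_year`
#'   (integer years = names).
#' @param confounding optional list of terms
#'   `list(field, level, classes, log_or_exposure, log_or_event)`: reports
#'   with `field == level` get `log_or_exposure` added to the exposure logit
#'   of each class in `classes` and `log_or_event` added to the event logit.
#' @param dup_rate fraction of reports duplicated (exact field copies under
#'   fresh report ids, injected last).
#' @param missing_rates named per-field probabilities of overwriting `sex`,
#'   `age_group` or `country` with `"unknown"` (applied before duplication).
#' @param excluded_pt_rate probability that an event report is coded with an
#'   excluded (non-qualifying) PT of the target HLT instead of a qualifying
#'   one, so its latent event never becomes a case.
#' @param background_excluded_rate probability that a non-event report
#'   carries an excluded target-HLT PT as background noise.
#' @param decoy_pt_rate controls the number of decoy reaction PTs per report
#'   (every report gets at least one).
#' @param p_diabetes prevalence of the latent diabetes comorbidity.
#' @param seed integer seed; single pseudo-random stream per run.
#' @return A validated `synth_config`.
#' @export
synth_config <- function(n_reports = 10000,
                         p_exposure = c(ACEI = 0.025, thiazide = 0.02,
                                        irbesartan = 0.005),
                         baseline_event_odds = 0.02,
                         true_or = c(ACEI = 1.0),
                         true_or_by_sex = NULL,
                         covariate_dists = NULL,
                         confounding = NULL,
                         dup_rate = 0,
                         missing_rates = c(sex = 0, age_group = 0, country = 0),
                         excluded_pt_rate = 0.1,
                         background_excluded_rate = 0.002,
                         decoy_pt_rate = 0.3,
                         p_diabetes = 0.08,
                         seed = 1L) {
  if (n_reports <= 0) stop("n_reports must be positive")
  probs <- c(p_exposure, dup_rate, missing_rates, excluded_pt_rate,
             background_excluded_rate, decoy_pt_rate, p_diabetes)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (baseline_event_odds <= 0) stop("baseline_event_odds must be positive")
  dists <- list(
    sex = c(male = 0.46, female = 0.46, unknown = 0.08),
    age_group = c("<18" = 0.01, "18-44" = 0.06, "45-64" = 0.28,
                  "65-74" = 0.19, ">75" = 0.18, unknown = 0.28),
    country = c(US = 0.60, CA = 0.03, GB = 0.10, DE = 0.05, FR = 0.04,
                JP = 0.02, AU = 0.01, BR = 0.01, ZA = 0.005, unknown = 0.135),
    receipt_year = stats::setNames(rep(1 / 16, 16), 2004:2019)
  )
  for (f in names(covariate_dists %||% list())) dists[[f]] <- covariate_dists[[f]]
  if (!is.null(true_or_by_sex)) {
    for (k in names(true_or_by_sex)) {
      bad <- setdiff(names(true_or_by_sex[[k]]), names(dists$sex))
      if (length(bad))
        stop("per-stratum OR for absent sex level(s): ",
             paste(bad, collapse = ", "))
      if (!(k %in% names(p_exposure)))
        stop("per-stratum OR for class without exposure prevalence: ", k)
    }
  }
  bad_or <- setdiff(names(true_or), names(p_exposure))
  if (length(bad_or))
    stop("true_or given for class without exposure prevalence: ",
         paste(bad_or, collapse = ", "))
  structure(list(n_reports = as.integer(n_reports), p_exposure = p_exposure,
                 baseline_event_odds = baseline_event_odds, true_or = true_or,
                 true_or_by_sex = true_or_by_sex, covariate_dists = dists,
                 confounding = confounding, dup_rate = dup_rate,
                 missing_rates = missing_rates,
                 excluded_pt_rate = excluded_pt_rate,
                 background_excluded_rate = background_excluded_rate,
                 decoy_pt_rate = decoy_pt_rate, p_diabetes = p_diabetes,
                 seed = as.integer(seed)),
            class = "synth_config")
}

sample_levels <- function(n, dist) {
  names(dist)[sample.int(length(dist), n, replace = TRUE, prob = dist)]
}

#' Generate a synthetic report collection with ground truth
#'
#' Per report: covariates are drawn from their categorical distributions;
#' exposure to each drug class from a logistic model whose intercept matches
#' the class prevalence and which includes any configured confounder terms;
#' the target event from a logistic model with log-odds
#' `log(baseline_event_odds) + sum(log true OR over exposed classes) +
#' confounder terms`, with per-sex ORs where configured. Event reports
#' receive one target-HLT PT (an excluded PT with probability
#' `excluded_pt_rate`, so the latent event does not always surface as a
#' case); all reports receive decoy PTs, one drug mention per exposed class
#' and one decoy drug. Missingness is applied to covariates, then exact
#' duplicate copies are injected under fresh report ids.
#'
#' @param config a `synth_config`.
#' @param hierarchy,dictionary vocabularies used to emit realistic PT codes
#'   and verbatim drug names (defaults: packaged).
#' @return list: `collection` (a `report_collection`) and `truth` (data
#'   frame: report_id, per-class exposure flags, `event`, `case`,
#'   `diabetes`, `sex`, `receipt_year`, `is_duplicate`, `dup_of`).
#' @export
generate_reports <- function(config, hierarchy = load_hierarchy(),
                             dictionary = load_dictionary()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_reports
  d <- config$covariate_dists

  sex <- sample_levels(n, d$sex)
  age_group <- sample_levels(n, d$age_group)
  country <- sample_levels(n, d$country)
  receipt_year <- as.integer(sample_levels(n, d$receipt_year))
  receipt_quarter <- sample.int(4L, n, replace = TRUE)
  diabetes <- stats::rbinom(n, 1, config$p_diabetes) == 1

  conf_terms <- function() {
    # per-report confounder contributions, split by target (exposure/event)
    out <- list()
    for (tm in config$confounding %||% list()) {
      ind <- as.numeric(get(tm$field)[seq_len(n)] == tm$level)
      out[[length(out) + 1L]] <- list(classes = tm$classes %||% names(config$p_exposure),
                                      expo = ind * (tm$log_or_exposure %||% 0),
                                      event = ind * (tm$log_or_event %||% 0))
    }
    out
  }
  conf <- conf_terms()

  classes <- names(config$p_exposure)
  exposed <- matrix(FALSE, n, length(classes), dimnames = list(NULL, classes))
  for (k in classes) {
    eta <- rep(stats::qlogis(config$p_exposure[[k]]), n)
    for (tm in conf) if (k %in% tm$classes) eta <- eta + tm$expo
    exposed[, k] <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
  }

  eta_event <- rep(log(config$baseline_event_odds), n)
  for (k in classes) {
    lor <- log(if (k %in% names(config$true_or)) config$true_or[[k]] else 1)
    if (k %in% names(config$true_or_by_sex %||% list())) {
      by_sex <- config$true_or_by_sex[[k]]
      lor <- log(unname(by_sex[sex]))
      lor[is.na(lor)] <- 0
    }
    eta_event <- eta_event + exposed[, k] * lor
  }
  for (tm in conf) eta_event <- eta_event + tm$event
  event <- stats::rbinom(n, 1, stats::plogis(eta_event)) == 1

  # reaction PTs
  target_hlt <- hlt_code(hierarchy, "Lower respiratory tract neoplasms")
  excl_names <- c("Carcinoid tumour pulmonary", "Leukaemic infiltration pulmonary",
                  "Endobronchial lipoma", "Benign respiratory tract neoplasm",
                  "Benign lung neoplasm", "Metastases to lung")
  excluded_pts <- pt_code(hierarchy, excl_names)
  qualifying_pts <- setdiff(pts_under_hlt(hierarchy, target_hlt), excluded_pts)
  decoy_pts <- setdiff(hierarchy$terms$pt_code,
                       pts_under_hlt(hierarchy, target_hlt))

  report_id <- sprintf("S%07d", seq_len(n))
  coded_excluded <- event & (stats::runif(n) < config$excluded_pt_rate)
  case <- event & !coded_excluded
  bg_excl <- !event & (stats::runif(n) < config$background_excluded_rate)

  target_pt <- rep(NA_character_, n)
  target_pt[case] <- sample(qualifying_pts, sum(case), replace = TRUE)
  target_pt[coded_excluded | bg_excl] <-
    sample(excluded_pts, sum(coded_excluded | bg_excl), replace = TRUE)
  n_decoys <- 1L + stats::rbinom(n, 2, config$decoy_pt_rate)
  reac_id <- c(rep(report_id, n_decoys), report_id[!is.na(target_pt)])
  reac_pt <- c(sample(decoy_pts, sum(n_decoys), replace = TRUE),
               target_pt[!is.na(target_pt)])
  reactions <- data.frame(report_id = reac_id, pt_code = reac_pt)

  # drug mentions: one synonym per exposed class + one decoy drug per report
  syn <- dictionary$synonyms
  # a "class" in p_exposure may be a class label or a single generic
  pool <- function(cls) which(syn$generic %in% query_generics(cls, dictionary))
  drug_rows <- list()
  for (k in classes) {
    idx <- which(exposed[, k])
    if (!length(idx)) next
    pk <- pool(k)
    pick <- pk[sample.int(length(pk), length(idx), replace = TRUE)]
    drug_rows[[k]] <- data.frame(
      report_id = report_id[idx],
      verbatim_name = syn$synonym[pick],
      generic_name = syn$generic[pick],
      role = sample(c("suspect", "concomitant", "interacting"), length(idx),
                    replace = TRUE, prob = c(0.7, 0.25, 0.05)))
  }
  dia_drug <- diabetes & (stats::runif(n) < 0.5)
  if (any(dia_drug)) {
    pk <- pool("antidiabetic")
    pick <- pk[sample.int(length(pk), sum(dia_drug), replace = TRUE)]
    drug_rows[["antidiabetic"]] <- data.frame(
      report_id = report_id[dia_drug], verbatim_name = syn$synonym[pick],
      generic_name = syn$generic[pick], role = "concomitant")
  }
  pk <- pool("other")
  pick <- pk[sample.int(length(pk), n, replace = TRUE)]
  drug_rows[["decoy"]] <- data.frame(
    report_id = report_id, verbatim_name = syn$synonym[pick],
    generic_name = syn$generic[pick],
    role = sample(c("suspect", "concomitant"), n, replace = TRUE,
                  prob = c(0.5, 0.5)))
  drugs <- do.call(rbind, drug_rows)
  rownames(drugs) <- NULL

  # indications: diabetes PT for diabetics, hypertension for antihypertensive
  # users, unknown-indication otherwise
  dia_pt <- pt_code(hierarchy, "Type 2 diabetes mellitus")
  htn_pt <- pt_code(hierarchy, "Hypertension")
  unk_pt <- pt_code(hierarchy, "Product used for unknown indication")
  dia_ind <- diabetes & (stats::runif(n) < 0.7)
  anti_htn <- Reduce(`|`, lapply(intersect(classes, c("ACEI", "thiazide", "irbesartan")),
                                 function(k) exposed[, k]), rep(FALSE, n))
  htn_ind <- anti_htn & (stats::runif(n) < 0.5)
  indications <- data.frame(
    report_id = c(report_id[dia_ind], report_id[htn_ind],
                  report_id[!dia_ind & !htn_ind]),
    pt_code = c(rep(dia_pt, sum(dia_ind)), rep(htn_pt, sum(htn_ind)),
                rep(unk_pt, sum(!dia_ind & !htn_ind))))

  # outcome flags are independent Bernoullis; drawing the joint combination
  # from its 16-cell product distribution avoids per-report string work
  outcome_probs <- c(hospitalization = 0.30, disability = 0.03,
                     `life-threatening` = 0.05, death = 0.08)
  combo <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))
  combo_lab <- apply(combo, 1, function(r) paste(OUTCOME_LEVELS[r], collapse = ";"))
  combo_p <- apply(combo, 1, function(r)
    prod(ifelse(r, outcome_probs, 1 - outcome_probs)))
  outcomes <- combo_lab[sample.int(length(combo_lab), n, replace = TRUE,
                                   prob = combo_p)]

  # missingness, applied before duplication so copies share it
  for (f in names(config$missing_rates)) {
    r <- config$missing_rates[[f]]
    if (r > 0) {
      hit <- stats::runif(n) < r
      v <- get(f)
      v[hit] <- "unknown"
      assign(f, v)
    }
  }

  demo <- data.frame(report_id = report_id, version = 1L, sex = sex,
                     age_group = age_group, country = country,
                     receipt_year = receipt_year,
                     receipt_quarter = receipt_quarter, outcomes = outcomes)

  truth <- data.frame(report_id = report_id, stringsAsFactors = FALSE)
  for (k in classes) truth[[paste0("exposed_", k)]] <- exposed[, k]
  truth$event <- event
  truth$case <- case
  truth$diabetes <- diabetes
  truth$sex <- sex
  truth$receipt_year <- receipt_year
  truth$is_duplicate <- FALSE
  truth$dup_of <- NA_character_

  # duplicate injection: exact field copies under fresh report ids
  n_dup <- floor(config$dup_rate * n)
  if (n_dup > 0) {
    src <- sample.int(n, n_dup, replace = FALSE)
    dup_id <- sprintf("D%07d", seq_len(n_dup))
    dd <- demo[src, , drop = FALSE]
    dd$report_id <- dup_id
    demo <- rbind(demo, dd)
    copy_child <- function(tab) {
      m <- match(tab$report_id, report_id[src])
      rows <- tab[!is.na(m), , drop = FALSE]
      rows$report_id <- dup_id[m[!is.na(m)]]
      rbind(tab, rows)
    }
    drugs <- copy_child(drugs)
    reactions <- copy_child(reactions)
    indications <- copy_child(indications)
    tdup <- truth[src, , drop = FALSE]
    tdup$report_id <- dup_id
    tdup$is_duplicate <- TRUE
    tdup$dup_of <- report_id[src]
    truth <- rbind(truth, tdup)
  }
  rownames(demo) <- rownames(truth) <- NULL
  rownames(drugs) <- rownames(reactions) <- rownames(indications) <- NULL

  collection <- report_collection(demo, drugs, reactions, indications)
  list(collection = collection, truth = truth)
}

#' Write a collection as the four-table delimited format
#'
#' Emits `demo.tsv`, `drug.tsv`, `reac.tsv`, `indi.tsv` in the schema read
#' by [read_tables()]; a write/read round trip reproduces the collection.
#'
#' @param collection a `report_collection`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the four file paths.
#' @export
write_tables <- function(collection, out_dir) {
  if (n_reports(collection) == 0) stop("refusing to write an empty collection")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("demo.tsv", "drug.tsv", "reac.tsv", "indi.tsv"))
  write_tsv(collection$demo[, c("report_id", "version", "sex", "age_group",
                                "country", "receipt_year", "receipt_quarter",
                                "outcomes")], paths[1])
  write_tsv(collection$drugs[, c("report_id", "verbatim_name", "role")], paths[2])
  write_tsv(collection$reactions[, c("report_id", "pt_code")], paths[3])
  write_tsv(collection$indications[, c("report_id", "pt_code")], paths[4])
  invisible(paths)
}

#' Write generator ground truth as TSV
#' @param truth the `truth` data frame from [generate_reports()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  write_tsv(truth, path)
  invisible(path)
}
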