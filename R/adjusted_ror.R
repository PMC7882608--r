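#' Specification of the covariate-adjusted ROR model
#'
#' The adjusted reporting odds ratio is estimated by logistic regression of
#' case status on exposure within the subpopulation of reports mentioning
#' either the exposure class or a named reference class, controlling for
#' report covariates. Reports mentioning both classes are excluded by
#' default (`overlap = "exclude"`); set `overlap = "as_exposed"` to count
#' them with the exposure class.
#'
#' @param exposure exposure drug class (e.g. `"ACEI"`).
#' @param reference reference drug class (e.g. `"thiazide"`); must differ
#'   from `exposure`.
#' @param covariates subset of `c("sex", "age_group", "receipt_year")`;
#'   must be non-empty for an estimate labelled "adjusted".
#' @param year_coding `"categorical"` (default: one indicator per calendar
#'   year, earliest year baseline) or `"linear"` (single slope on
#'   year - earliest year).
#' @param overlap `"exclude"` or `"as_exposed"`.
#' @return A `regression_spec`.
#' @export
regression_spec <- function(exposure = "ACEI", reference = "thiazide",
                            covariates = c("sex", "age_group", "receipt_year"),
                            year_coding = c("categorical", "linear"),
                            overlap = c("exclude", "as_exposed")) {
  year_coding <- match.arg(year_coding)
  overlap <- match.arg(overlap)
  if (identical(exposure, reference))
    stop("exposure and reference class must differ")
  bad <- setdiff(covariates, c("sex", "age_group", "receipt_year"))
  if (length(bad)) stop("unsupported covariate(s): ", paste(bad, collapse = ", "))
  structure(list(exposure = exposure, reference = reference,
                 covariates = covariates, year_coding = year_coding,
                 overlap = overlap),
            class = "regression_spec")
}

# Hand-rolled treatment-contrast dummy coding: one column per non-baseline
# level actually present. Baselines: male sex, 45-64 age, earliest year.
dummy_code <- function(values, levels_present, baseline, prefix) {
  lev <- setdiff(levels_present, baseline)
  if (!length(lev)) return(NULL)
  m <- matrix(0, nrow = length(values), ncol = length(lev),
              dimnames = list(NULL, paste0(prefix, lev)))
  for (j in seq_along(lev)) m[, j] <- as.numeric(values == lev[j])
  m
}

#' Build the design matrix for the adjusted-ROR fit
#'
#' Restricts a case-classified collection to reports exposed to the exposure
#' or reference class (the reference class is the baseline), applies the
#' overlap rule, drops reports with unknown sex or unknown age group
#' (missing-covariate exclusion), and dummy-codes the covariates with
#' documented baselines (male; 45-64; earliest receipt year).
#'
#' @param collection a `report_collection` classified with [classify()] for
#'   case status (its `is_case` column is the outcome).
#' @param spec a `regression_spec`.
#' @param dictionary a `drug_dictionary`.
#' @return list: `X` (numeric design matrix with intercept), `y` (0/1
#'   outcome), `n_used`, `excluded` (named counts), `report_id`.
#' @export
build_design <- function(collection, spec, dictionary) {
  if (is.null(collection$demo$is_case))
    stop("collection has no case classification; run classify() first")
  exp_flag <- is_exposed(collection, spec$exposure, dictionary)
  ref_flag <- is_exposed(collection, spec$reference, dictionary)

  both <- exp_flag & ref_flag
  keep <- (exp_flag | ref_flag)
  n_overlap <- 0L
  if (spec$overlap == "exclude") {
    n_overlap <- sum(both)
    keep <- keep & !both
  }
  d <- collection$demo[keep, , drop = FALSE]
  exposed <- exp_flag[keep]

  use_sex <- "sex" %in% spec$covariates
  use_age <- "age_group" %in% spec$covariates
  miss <- (use_sex & d$sex == "unknown") | (use_age & d$age_group == "unknown")
  n_missing <- sum(miss)
  d <- d[!miss, , drop = FALSE]
  exposed <- exposed[!miss]
  if (nrow(d) == 0L) stop("no reports remain after exclusions")
  if (length(unique(exposed)) < 2L)
    stop("exposure is constant in the design population; ",
         "cannot estimate an adjusted ROR")

  X <- cbind(`(Intercept)` = 1, exposure = as.numeric(unname(exposed)))
  if (use_sex)
    X <- cbind(X, dummy_code(d$sex, intersect(SEX_LEVELS, unique(d$sex)),
                             "male", "sex_"))
  if (use_age)
    X <- cbind(X, dummy_code(d$age_group,
                             intersect(AGE_LEVELS, unique(d$age_group)),
                             "45-64", "age_"))
  if ("receipt_year" %in% spec$covariates) {
    y0 <- min(d$receipt_year)
    if (spec$year_coding == "linear") {
      X <- cbind(X, year = d$receipt_year - y0)
    } else {
      X <- cbind(X, dummy_code(as.character(d$receipt_year),
                               as.character(sort(unique(d$receipt_year))),
                               as.character(y0), "year_"))
    }
  }
  list(X = X, y = as.numeric(d$is_case), n_used = nrow(d),
       excluded = c(overlap = n_overlap, missing_covariates = n_missing),
       report_id = d$report_id)
}

logistic_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  # log(1 + exp(eta)) computed without overflow for large |eta|
  lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  sum(y * eta - lse)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `logit P(y=1) = X beta` with Wald intervals.
#' Convergence when the largest absolute score falls below `tol` or the
#' relative log-likelihood change does. The per-iteration log-likelihood
#' trace is retained (it must be non-decreasing with the step-halving
#' safeguard used here). Coefficients larger than 15 in absolute value set a
#' quasi-separation warning flag.
#'
#' @param X numeric design matrix including an intercept column.
#' @param y 0/1 outcome vector.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance.
#' @param alpha two-sided error rate for the Wald intervals.
#' @return A `fit_result`: `beta`, `se`, `or` / `or_ci` per term, `aror` and
#'   `aror_ci` for the `exposure` term, `loglik_trace`, `n_used`,
#'   `converged`, `iterations`, `separation`.
#' @export
fit_logistic <- function(X, y, max_iter = 100, tol = 1e-8, alpha = 0.05) {
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank-deficient after dropping empty levels")
  p <- ncol(X)
  beta <- numeric(p)
  ll <- logistic_loglik(X, y, beta)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), .Machine$double.eps)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    step <- solve(info, score)
    # step-halving keeps the log-likelihood monotone
    new_beta <- beta + step
    new_ll <- logistic_loglik(X, y, new_beta)
    h <- 0
    while (new_ll < ll && h < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- logistic_loglik(X, y, new_beta)
      h <- h + 1
    }
    beta <- new_beta
    rel <- abs(new_ll - ll) / (abs(ll) + 1e-12)
    ll <- new_ll
    trace <- c(trace, ll)
    if (max(abs(score)) < tol || rel < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), .Machine$double.eps)
  cov <- solve(crossprod(X * w, X))
  se <- sqrt(diag(cov))
  names(beta) <- names(se) <- colnames(X)
  z <- stats::qnorm(1 - alpha / 2)
  or <- exp(beta)
  or_low <- exp(beta - z * se)
  or_high <- exp(beta + z * se)
  separation <- any(abs(beta) > 15)
  if (separation) warning("possible quasi-separation: |beta| > 15")
  aror <- if ("exposure" %in% names(beta)) unname(or["exposure"]) else NA_real_
  aror_ci <- if ("exposure" %in% names(beta))
    c(unname(or_low["exposure"]), unname(or_high["exposure"]))
  else c(NA_real_, NA_real_)
  structure(list(beta = beta, se = se, or = or, or_low = or_low,
                 or_high = or_high, aror = aror, aror_ci = aror_ci,
                 loglik = ll, loglik_trace = trace, n_used = length(y),
                 converged = converged, iterations = iter,
                 separation = separation),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> n=", x$n_used, ", ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  if (!is.na(x$aror))
    cat(sprintf("  aROR %.4f (95%% CI %.4f-%.4f)\n",
                x$aror, x$aror_ci[1], x$aror_ci[2]))
  invisible(x)
}

#' Covariate-adjusted reporting odds ratio
#'
#' Convenience wrapper: [build_design()] then [fit_logistic()].
#'
#' @inheritParams build_design
#' @param ... passed to [fit_logistic()].
#' @return A `fit_result` (see [fit_logistic()]); `aror` is the adjusted ROR.
#' @export
adjusted_ror <- function(collection, spec, dictionary, ...) {
  des <- build_design(collection, spec, dictionary)
  fit <- fit_logistic(des$X, des$y, ...)
  fit$excluded <- des$excluded
  fit
}

#' Export a fitted model as a tidy per-term table
#'
#' @param fit a `fit_result`.
#' @return data frame: term, beta, se, OR, ci_low, ci_high.
#' @export
fit_summary <- function(fit) {
  data.frame(term = names(fit$beta), beta = unname(fit$beta),
             se = unname(fit$se), or = unname(fit$or),
             ci_low = unname(fit$or_low), ci_high = unname(fit$or_high),
             stringsAsFactors = FALSE)
}
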