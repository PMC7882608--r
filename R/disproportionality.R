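#' Build the 2x2 contingency table of a drug-event pair
#'
#' Cells follow the case/non-case convention: `a` exposed cases, `b` exposed
#' non-cases, `c` unexposed cases, `d` unexposed non-cases; the comparator is
#' all other reports in the cleaned database. Constructible either from a
#' classified collection (see [classify()]) or directly from marginal counts
#' `(a, n_drug, n_event, n_total)` as printed in published analyses.
#'
#' @param x a classified `report_collection`, or the count `a` when building
#'   from marginals.
#' @param n_drug,n_event,n_total marginal counts (reports mentioning the
#'   drug; reports with the event; database size) when `x` is a count.
#' @return A `contingency_table` with fields `a`, `b`, `c`, `d`, `n_drug`,
#'   `n_event`, `n_total`.
#' @export
build_table <- function(x, n_drug = NULL, n_event = NULL, n_total = NULL) {
  if (inherits(x, "report_collection")) {
    cc <- attr(x, "cell_counts")
    if (is.null(cc)) stop("collection has not been classified; run classify()")
    a <- cc[["a"]]; b <- cc[["b"]]; c <- cc[["c"]]; d <- cc[["d"]]
  } else {
    a <- as.numeric(x)
    if (is.null(n_drug) || is.null(n_event) || is.null(n_total))
      stop("building from counts requires a, n_drug, n_event and n_total")
    b <- n_drug - a
    c <- n_event - a
    d <- n_total - n_drug - c
  }
  if (any(c(a, b, c, d) < 0))
    stop("negative implied cell count: a=", a, " b=", b, " c=", c, " d=", d)
  if (a + b + c + d == 0) stop("empty database: all cells zero")
  structure(list(a = a, b = b, c = c, d = d,
                 n_drug = a + b, n_event = a + c, n_total = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>  a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d,
      "  (n_drug=", x$n_drug, ", n_event=", x$n_event,
      ", n_total=", x$n_total, ")\n", sep = "")
  invisible(x)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' ROR = (a/b)/(c/d): the odds of the event among reports exposed to the
#' drug divided by the odds among all other reports. The CI is computed on
#' the log scale, `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When
#' any cell is zero the Haldane-Anscombe correction (add 0.5 to every cell)
#' is applied and the result flagged `corrected`; with the correction
#' disabled a zero cell yields an undefined-result marker (`NA` estimate).
#'
#' @param table a `contingency_table`.
#' @param alpha two-sided error rate (default 0.05 for a 95\% CI).
#' @param correction apply Haldane-Anscombe when a cell is zero.
#' @return list with `ror`, `ci` (length-2 vector), `corrected`, `defined`.
#' @export
compute_ror <- function(table, alpha = 0.05, correction = TRUE) {
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction)
      return(list(ror = NA_real_, ci = c(NA_real_, NA_real_),
                  corrected = FALSE, defined = FALSE))
    cells <- cells + 0.5
    corrected <- TRUE
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  z <- stats::qnorm(1 - alpha / 2)
  ror <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, ci = exp(log(ror) + c(-1, 1) * z * se),
       corrected = corrected, defined = TRUE)
}

#' Information component with shrinkage
#'
#' IC = log2((a + 1/2) / (E + 1/2)) where E = n_drug * n_event / n_total is
#' the count expected under independence of drug and event reporting; the
#' half-count shrinkage stabilises small counts (BCPNN-style). The default
#' interval is the normal approximation IC +/- z / (ln 2 * sqrt(a));
#' `ci_method = "noren"` instead returns the IC025/IC975 credibility-bound
#' approximation of the BCPNN posterior.
#'
#' @param table a `contingency_table`.
#' @param alpha two-sided error rate (default 0.05); used by the normal
#'   interval only.
#' @param ci_method `"normal"` (default) or `"noren"`.
#' @return list with `ic` (bits), `ci`, `expected`, `defined_ci` (FALSE when
#'   `a = 0`, where only the point estimate is returned).
#' @export
compute_ic <- function(table, alpha = 0.05, ci_method = c("normal", "noren")) {
  ci_method <- match.arg(ci_method)
  if (table$n_total == 0) stop("empty database: n_total is zero")
  if (table$n_drug == 0 || table$n_event == 0)
    stop("IC undefined: zero drug or event margin")
  a <- table$a
  E <- table$n_drug * table$n_event / table$n_total
  ic <- log2((a + 0.5) / (E + 0.5))
  if (a == 0)
    return(list(ic = ic, ci = c(NA_real_, NA_real_), expected = E,
                defined_ci = FALSE))
  ci <- if (ci_method == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    ic + c(-1, 1) * z / (log(2) * sqrt(a))
  } else {
    # Noren et al. posterior credibility-bound approximation
    c(ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5),
      ic + 2.4 * (a + 0.5)^(-0.5) + 0.5 * (a + 0.5)^(-1.5))
  }
  list(ic = ic, ci = ci, expected = E, defined_ci = TRUE)
}

#' Full disproportionality result for one drug-event pair
#'
#' Combines [compute_ror()], [compute_ic()] and [detect_signal()] into one
#' `signal_result` row.
#'
#' @param table a `contingency_table`.
#' @param alpha two-sided error rate.
#' @param ic_ci_method passed to [compute_ic()].
#' @param criteria passed to [detect_signal()].
#' @param correction passed to [compute_ror()].
#' @return A `signal_result` list: cells, `expected`, `ror`, `ror_ci`, `ic`,
#'   `ic_ci`, `signal`, `criteria_detail`, `corrected`.
#' @export
signal_result <- function(table, alpha = 0.05, ic_ci_method = "normal",
                          criteria = signal_criteria(), correction = TRUE) {
  r <- compute_ror(table, alpha, correction)
  i <- compute_ic(table, alpha, ic_ci_method)
  res <- structure(list(
    a = table$a, b = table$b, c = table$c, d = table$d,
    expected = i$expected,
    ror = r$ror, ror_ci = r$ci,
    ic = i$ic, ic_ci = i$ci,
    corrected = r$corrected
  ), class = "signal_result")
  det <- detect_signal(res, criteria)
  res$signal <- det$signal
  res$criteria_detail <- det$criteria_detail
  res
}

#' @export
print.signal_result <- function(x, ...) {
  f <- function(v) sprintf("%.2f", round_half_away(v, 2))
  cat("<signal_result> a=", x$a,
      "  ROR ", f(x$ror), " (", f(x$ror_ci[1]), "-", f(x$ror_ci[2]), ")",
      "  IC ", f(x$ic), " (", f(x$ic_ci[1]), "-", f(x$ic_ci[2]), ")",
      "  signal: ", x$signal, " [", x$criteria_detail, "]\n", sep = "")
  invisible(x)
}

#' Signal criteria configuration
#'
#' Defaults follow common pharmacovigilance practice: the ROR criterion
#' fires when the lower 95\% bound exceeds 1 with at least 3 exposed cases;
#' the IC criterion fires when the lower IC bound exceeds 0. A signal is
#' declared when at least one criterion fires.
#'
#' @param ror_ci_low_gt ROR lower-bound threshold (default 1).
#' @param min_a minimum exposed-case count for the ROR criterion (default 3).
#' @param ic_ci_low_gt IC lower-bound threshold (default 0).
#' @return list of thresholds.
#' @export
signal_criteria <- function(ror_ci_low_gt = 1, min_a = 3, ic_ci_low_gt = 0) {
  list(ror_ci_low_gt = ror_ci_low_gt, min_a = min_a,
       ic_ci_low_gt = ic_ci_low_gt)
}

#' Dual-criterion signal call
#'
#' @param result a `signal_result` (or any list with `a`, `ror_ci`, `ic_ci`).
#' @param criteria see [signal_criteria()]. Undefined CIs (`NA`) fail their
#'   criterion.
#' @return list: `signal` (logical) and `criteria_detail` (`"ROR"`, `"IC"`,
#'   `"ROR+IC"` or `"none"`).
#' @export
detect_signal <- function(result, criteria = signal_criteria()) {
  ror_ok <- isTRUE(result$ror_ci[1] > criteria$ror_ci_low_gt) &&
    isTRUE(result$a >= criteria$min_a)
  ic_ok <- isTRUE(result$ic_ci[1] > criteria$ic_ci_low_gt)
  detail <- c("none", "ROR", "IC", "ROR+IC")[1 + ror_ok + 2 * ic_ok]
  list(signal = ror_ok || ic_ok, criteria_detail = detail)
}

# One signal_result flattened to a single data frame row for TSV export.
signal_result_row <- function(res, drug = NA_character_,
                              stratum = NA_character_, label = NA_character_) {
  data.frame(
    drug = drug, stratum = stratum, label = label,
    a = res$a, b = res$b, c = res$c, d = res$d,
    expected = res$expected,
    ror = res$ror, ror_low = res$ror_ci[1], ror_high = res$ror_ci[2],
    ic = res$ic, ic_low = res$ic_ci[1], ic_high = res$ic_ci[2],
    signal = res$signal, criteria_detail = res$criteria_detail,
    corrected = res$corrected,
    stringsAsFactors = FALSE
  )
}
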