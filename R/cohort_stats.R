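#' Percent change between two positive quantities
#'
#' `100 * (followup - baseline) / baseline`. Negative values indicate loss;
#' this sign convention is used throughout the package for volumes and PBVC.
#' Scale invariant: rescaling both arguments by a common factor leaves the
#' result unchanged.
#'
#' @param baseline Positive baseline value(s).
#' @param followup Follow-up value(s); vectorised with `baseline`.
#' @return Percent change(s).
#' @examples
#' percent_change(798024.63, 780135.80)  # gray-matter volume loss, percent
#' @export
percent_change <- function(baseline, followup) {
  if (!is.numeric(baseline) || !is.numeric(followup))
    stop("inputs must be numeric", call. = FALSE)
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("'baseline' must be positive and finite", call. = FALSE)
  100 * (followup - baseline) / baseline
}

#' Paired Student's t-test for two-timepoint measurements
#'
#' Classic paired t on the follow-up minus baseline differences with a
#' two-sided p-value. When every difference is identical (zero variance)
#' the t statistic is undefined; the result carries an explicit
#' `degenerate` flag instead of NaN arithmetic.
#'
#' @param baseline,followup Equal-length numeric vectors, n >= 2.
#' @return An object of class `paired_t_result`: `n`, `mean_diff`
#'   (follow-up minus baseline), `t_statistic`, `p_value`, `direction`
#'   (`"increase"`, `"decrease"` or `"none"`), `degenerate`.
#' @export
paired_t_test <- function(baseline, followup) {
  if (length(baseline) != length(followup))
    stop("'baseline' and 'followup' must have equal length", call. = FALSE)
  n <- length(baseline)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- followup - baseline
  md <- mean(d)
  direction <- if (md > 0) "increase" else if (md < 0) "decrease" else "none"
  if (stats::sd(d) == 0) {
    return(structure(list(n = n, mean_diff = md, t_statistic = NA_real_,
                          p_value = NA_real_, direction = direction,
                          degenerate = TRUE),
                     class = "paired_t_result"))
  }
  ht <- stats::t.test(followup, baseline, paired = TRUE)
  structure(list(n = n, mean_diff = md,
                 t_statistic = unname(ht$statistic),
                 p_value = ht$p.value, direction = direction,
                 degenerate = FALSE),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("Paired t-test (n = %d): mean diff = %.4g; degenerate (zero-variance differences)\n",
                x$n, x$mean_diff))
  } else {
    cat(sprintf("Paired t-test (n = %d): mean diff = %.4g (%s), t = %.3f, p = %.4g\n",
                x$n, x$mean_diff, x$direction, x$t_statistic, x$p_value))
  }
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`. A constant input
#' vector has no defined ranking correlation and returns a degenerate
#' result.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A list: `rho`, `p_value`, `n`, `degenerate`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = n,
       degenerate = FALSE)
}

#' Linear regression of percent brain volume change on covariates
#'
#' Ordinary least squares with intercept, reproducing the uni/multivariate
#' analysis plan of longitudinal atrophy studies: in univariate mode each
#' requested covariate is fitted separately against PBVC; in multivariate
#' mode the covariates are fitted jointly. Race (or any factor covariate) is
#' coded as treatment contrasts with the largest category as reference.
#' PBVC follows the negative-equals-loss convention.
#'
#' @param records A data.frame with a `pbvc` column and the requested
#'   covariate columns (e.g. from [simulate_cohort]).
#' @param terms Character vector of covariate column names.
#' @param multivariate If `TRUE`, fit all terms jointly; otherwise one fit
#'   per term.
#' @param conf_level Confidence level for coefficient intervals.
#' @return A list of objects of class `pbvc_regression` (one per fit), each
#'   with `terms` (data.frame: `name`, `coefficient`, `ci_low`, `ci_high`,
#'   `p_value`), `r_squared` and `n`. In multivariate mode the list has one
#'   element.
#' @export
regress_pbvc <- function(records, terms, multivariate = FALSE,
                         conf_level = 0.95) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame", call. = FALSE)
  if (!"pbvc" %in% names(records))
    stop("'records' must contain a 'pbvc' column", call. = FALSE)
  missing_terms <- setdiff(terms, names(records))
  if (length(missing_terms))
    stop("missing covariate column(s): ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  if (anyNA(records[c("pbvc", terms)]))
    stop("missing values among 'pbvc' and requested covariates", call. = FALSE)
  dat <- records
  for (tm in terms) {
    if (is.character(dat[[tm]]) || is.factor(dat[[tm]])) {
      f <- factor(dat[[tm]])
      dat[[tm]] <- stats::relevel(f, ref = names(which.max(table(f))))
    }
  }
  fit_one <- function(rhs) {
    if (nrow(dat) <= length(rhs) + 1L)
      stop("too few subjects for the requested model", call. = FALSE)
    fml <- stats::reformulate(rhs, response = "pbvc")
    mm <- stats::model.matrix(fml, dat)
    if (qr(mm)$rank < ncol(mm))
      stop("rank-deficient design: collinear covariates", call. = FALSE)
    fit <- stats::lm(fml, data = dat)
    ci <- stats::confint(fit, level = conf_level)
    sm <- summary(fit)
    keep <- rownames(sm$coefficients) != "(Intercept)"
    structure(list(
      terms = data.frame(
        name = rownames(sm$coefficients)[keep],
        coefficient = sm$coefficients[keep, 1],
        ci_low = ci[keep, 1],
        ci_high = ci[keep, 2],
        p_value = sm$coefficients[keep, 4],
        row.names = NULL, stringsAsFactors = FALSE),
      r_squared = sm$r.squared,
      n = nrow(dat),
      formula = deparse(fml)),
      class = "pbvc_regression")
  }
  if (multivariate) {
    list(fit_one(terms))
  } else {
    out <- lapply(terms, fit_one)
    names(out) <- terms
    out
  }
}

#' @export
print.pbvc_regression <- function(x, digits = 4, ...) {
  cat(sprintf("OLS: %s  (n = %d, R^2 = %.3f)\n", x$formula, x$n, x$r_squared))
  tb <- x$terms
  tb[-1] <- lapply(tb[-1], signif, digits)
  print(tb, row.names = FALSE)
  invisible(x)
}
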