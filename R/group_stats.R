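group_comparison <- function(outcome, effect_type, estimate, ci_lower,
                             ci_upper, p_value, method,
                             contrast = "low vs high C-peptide",
                             adjusted_for = character(0),
                             note = NA_character_) {
  structure(
    data.frame(outcome = outcome, contrast = contrast,
               effect_type = effect_type, estimate = estimate,
               ci_lower = ci_lower, ci_upper = ci_upper,
               p_value = p_value,
               adjusted_for = paste(adjusted_for, collapse = "+"),
               method = method, note = note),
    class = c("group_comparison", "data.frame"))
}

#' Paired t test on matched-pair differences
#'
#' Classic paired t statistic on the within-pair differences, with
#' df = n - 1, a two-sided p-value from the t distribution, and the mean
#' difference with its 95% CI.
#'
#' @param differences numeric vector of within-pair differences
#'   (low-group value minus its matched high-group value).
#' @param outcome outcome label for the report.
#' @return a `group_comparison` row.
#' @export
paired_t <- function(differences, outcome = "outcome") {
  d <- differences[!is.na(differences)]
  if (length(d) < 2) stop("degenerate input: need >= 2 pair differences")
  if (stats::sd(d) == 0)
    stop("degenerate input: zero variance of pair differences")
  tt <- stats::t.test(d)
  group_comparison(outcome, "mean difference",
                   unname(tt$estimate), tt$conf.int[1], tt$conf.int[2],
                   tt$p.value, "paired t test")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction (a Yates-corrected
#' variant is available as a sensitivity switch), df = 1, two-sided.
#' The reported effect is the difference in proportions
#' `a/(a+b) - c/(c+d)` with a Wald 95% CI.
#'
#' @param a,b,c,d cell counts: rows are groups, columns
#'   event / no event.
#' @param correct apply Yates continuity correction.
#' @param outcome outcome label.
#' @return a `group_comparison` row with attributes `chi_sq` and
#'   `proportions`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE,
                           outcome = "proportion") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("input error: counts must be non-negative integers")
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate input: zero margin in 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  p1 <- a / (a + b)
  p2 <- c / (c + d)
  se <- sqrt(p1 * (1 - p1) / (a + b) + p2 * (1 - p2) / (c + d))
  cmp <- group_comparison(outcome, "proportion difference",
                          p1 - p2, p1 - p2 - 1.96 * se, p1 - p2 + 1.96 * se,
                          ht$p.value,
                          if (correct) "chi-square (Yates)" else "chi-square")
  attr(cmp, "chi_sq") <- unname(ht$statistic)
  attr(cmp, "proportions") <- c(p1, p2)
  cmp
}

#' Exact (Garwood) Poisson confidence interval for a rate
#'
#' For `k` events over exposure `T`, the rate is `k / T` with exact 95%
#' CI from chi-square quantiles:
#' `[qchisq(.025, 2k) / 2, qchisq(.975, 2k + 2) / 2] / T`, the lower
#' bound being 0 when `k = 0`.
#'
#' @param events non-negative integer event count.
#' @param exposure positive exposure (person-time in the unit the rate is
#'   wanted in).
#' @param conf confidence level.
#' @return list with `rate`, `ci_lower`, `ci_upper`, `events`,
#'   `exposure`.
#' @export
poisson_rate_ci <- function(events, exposure, conf = 0.95) {
  if (events < 0 || events != round(events))
    stop("input error: events must be a non-negative integer")
  if (exposure <= 0) stop("input error: exposure must be > 0")
  alpha <- 1 - conf
  lower <- if (events == 0) 0 else stats::qchisq(alpha / 2, 2 * events) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * events + 2) / 2
  list(rate = events / exposure, ci_lower = lower / exposure,
       ci_upper = upper / exposure, events = as.integer(events),
       exposure = exposure)
}

#' Compare two Poisson rates (rate ratio and z test)
#'
#' The rate ratio is compared on the log scale:
#' `z = log(r1 / r2) / sqrt(1/k1 + 1/k2)` on the event counts, with a
#' two-sided normal p-value and a log-scale Wald 95% CI.  If either
#' count is zero the ratio is reported with an unbounded-CI flag rather
#' than a silent infinity.
#'
#' @param events1,exposure1 events and exposure in group 1 (low
#'   C-peptide by convention).
#' @param events2,exposure2 events and exposure in group 2.
#' @param outcome outcome label.
#' @return a `group_comparison` row (effect type `rate ratio`).
#' @export
rate_compare <- function(events1, exposure1, events2, exposure2,
                         outcome = "rate") {
  if (exposure1 <= 0 || exposure2 <= 0)
    stop("input error: exposures must be > 0")
  r1 <- events1 / exposure1
  r2 <- events2 / exposure2
  if (events1 == 0 || events2 == 0) {
    return(group_comparison(outcome, "rate ratio",
                            if (r2 > 0) r1 / r2 else NA_real_,
                            NA_real_, NA_real_, NA_real_,
                            "rate ratio z test",
                            note = "unbounded CI: zero events in a group"))
  }
  se <- sqrt(1 / events1 + 1 / events2)
  z <- log(r1 / r2) / se
  p <- 2 * stats::pnorm(-abs(z))
  cmp <- group_comparison(outcome, "rate ratio", r1 / r2,
                          exp(log(r1 / r2) - 1.96 * se),
                          exp(log(r1 / r2) + 1.96 * se),
                          p, "rate ratio z test")
  attr(cmp, "z") <- z
  cmp
}

#' Adjusted group-contrast regression models
#'
#' Fits the group contrast with optional covariate adjustment by
#' maximum likelihood (IRLS via [stats::glm()]): logistic regression for
#' binary outcomes (odds ratio), Poisson log-link regression with an
#' exposure offset for counts (rate ratio), and linear regression /
#' ANCOVA for continuous outcomes (adjusted mean difference).  Reports
#' the Wald 95% CI and p-value for the group coefficient.
#' Non-convergence or separation is reported explicitly in the `note`
#' field, never silently.
#'
#' @param data data frame holding outcome, group and covariates.
#' @param outcome name of the outcome column.
#' @param group name of the group column; coerced to a factor whose
#'   *second* level is the exposed (low C-peptide) group unless it is
#'   already a factor.
#' @param covariates character vector of adjustment covariate names
#'   (may be empty).
#' @param family `"binomial"`, `"poisson"` or `"gaussian"`.
#' @param offset optional name of an exposure column (Poisson only); the
#'   model offset is its log.
#' @param maxit IRLS iteration cap.
#' @return a `group_comparison` row; the fitted model is attached as
#'   attribute `fit`.
#' @export
adjusted_models <- function(data, outcome, group, covariates = character(0),
                            family = c("binomial", "poisson", "gaussian"),
                            offset = NULL, maxit = 100) {
  family <- match.arg(family)
  if (!is.factor(data[[group]])) data[[group]] <- factor(data[[group]])
  rhs <- paste(c(group, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  off <- if (!is.null(offset)) log(data[[offset]]) else NULL
  fit_warnings <- character(0)
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = family, offset = off,
               control = stats::glm.control(maxit = maxit)),
    warning = function(w) {
      fit_warnings <<- c(fit_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  term <- grep(paste0("^", group), rownames(co), value = TRUE)[1]
  est <- co[term, 1]
  se <- co[term, 2]
  p <- co[term, 4]
  note <- NA_character_
  if (length(fit_warnings))
    note <- paste("fit warning:", paste(unique(fit_warnings), collapse = "; "))
  if (!fit$converged) note <- "non-convergence: IRLS did not converge"
  if (family == "binomial" && se > 50)
    note <- "separation suspected: unstable standard error"
  log_scale <- family %in% c("binomial", "poisson")
  effect_type <- switch(family, binomial = "odds ratio",
                        poisson = "rate ratio",
                        gaussian = "adjusted mean difference")
  transf <- if (log_scale) exp else identity
  cmp <- group_comparison(outcome, effect_type, transf(est),
                          transf(est - 1.96 * se), transf(est + 1.96 * se),
                          p,
                          paste0(family, " regression"),
                          contrast = paste("levels of", group),
                          adjusted_for = covariates, note = note)
  attr(cmp, "fit") <- fit
  cmp
}
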