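#' Harrell's C-index with an asymptotic confidence interval
#'
#' `C = (concordant + 0.5 * tied-score) / comparable` over the usual
#' censoring-comparable pairs (the earlier time must be an event; at tied
#' times an event is comparable with a censored subject). The variance is the
#' U-statistic projection estimate; the CI is Wald on that scale.
#'
#' @param risk Per-subject risk score (higher = riskier).
#' @param time Follow-up time.
#' @param event 0/1 event indicator.
#' @param conf_level Confidence level.
#' @return List: `C`, `ci` (length 2), `var`, `pairs` (comparable pairs).
#' @export
harrell_c <- function(risk, time, event, conf_level = 0.95) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  res <- concordance_cpp(as.numeric(time), as.integer(event), as.numeric(risk))
  if (res$pairs <= 0) stop("no comparable pairs")
  q <- qnorm(1 - (1 - conf_level) / 2)
  half <- q * sqrt(max(res$var, 0))
  list(C = res$C, ci = c(max(0, res$C - half), min(1, res$C + half)),
       var = res$var, pairs = res$pairs)
}

#' Compare two correlated C-indices
#'
#' Tests the difference between the C-indices of two risk scores evaluated on
#' the *same* subjects, using a U-statistic projection estimate of the
#' variance of the difference that accounts for the correlation between the
#' two concordance estimates, with a two-sided normal p-value.
#'
#' @param risk_ref,risk_new Risk scores of the reference and new model for
#'   the same subjects, in the same order.
#' @inheritParams harrell_c
#' @return Object of class `cc_compare`: `C_ref`, `C_new` (each with `ci`),
#'   `delta` (= C_new - C_ref), `var_delta`, `p`.
#' @export
compare_c <- function(risk_ref, risk_new, time, event, conf_level = 0.95) {
  n <- length(time)
  if (length(risk_ref) != n || length(risk_new) != n)
    stop("both risk vectors must cover the same subjects as the outcome")
  res <- compare_c_cpp(as.numeric(time), as.integer(event),
                       as.numeric(risk_ref), as.numeric(risk_new))
  if (is.na(res$C1)) stop("no comparable pairs")
  q <- qnorm(1 - (1 - conf_level) / 2)
  delta <- res$C2 - res$C1
  p <- if (res$var_diff > 0) 2 * pnorm(-abs(delta) / sqrt(res$var_diff))
       else as.numeric(delta == 0)
  structure(list(
    C_ref = res$C1,
    ci_ref = c(max(0, res$C1 - q * sqrt(res$var1)),
               min(1, res$C1 + q * sqrt(res$var1))),
    C_new = res$C2,
    ci_new = c(max(0, res$C2 - q * sqrt(res$var2)),
               min(1, res$C2 + q * sqrt(res$var2))),
    delta = delta, var_delta = res$var_diff, p = p, n = n),
    class = "cc_compare")
}

#' @export
print.cc_compare <- function(x, digits = 4, ...) {
  cat(sprintf("C (reference): %.4f (%.4f, %.4f)\n", x$C_ref, x$ci_ref[1],
              x$ci_ref[2]))
  cat(sprintf("C (new):       %.4f (%.4f, %.4f)\n", x$C_new, x$ci_new[1],
              x$ci_new[2]))
  cat(sprintf("delta C = %.4f, two-sided p = %.4g (n = %d)\n",
              x$delta, x$p, x$n))
  invisible(x)
}

#' Incremental C-index of a single biomarker
#'
#' Difference in Harrell's C between the base model extended by one feature
#' and the base model alone, per sex, both fitted as sex-specific weighted
#' Cox models on the same sample.
#'
#' @param data `case_cohort` (or full-cohort) data frame.
#' @param feature Feature column to add (must not be a base covariate).
#' @param base Base covariates.
#' @param sex `"M"`, `"F"`, or `"both"` (pooled sex-specific predictions).
#' @param horizon Risk horizon for the predictions.
#' @param alpha Sampling fraction (default: the `alpha` attribute).
#' @return List with `delta_c`, `C_base`, `C_ext`, `p` (correlated-C test).
#' @export
incremental_c <- function(data, feature, base = score2_variables(),
                          sex = c("both", "M", "F"), horizon = 10,
                          alpha = attr(data, "alpha")) {
  sex <- match.arg(sex)
  if (feature %in% base) stop("'feature' is already a base covariate")
  d <- if (sex == "both") data else data[data$sex == sex, , drop = FALSE]
  spec0 <- model_spec(base = base)
  spec1 <- model_spec(layers = "proteins",
                      proteins = list(male = feature, female = feature),
                      base = base)
  m0 <- fit_sex_specific(spec0, d, alpha = alpha)
  m1 <- fit_sex_specific(spec1, d, alpha = alpha)
  r0 <- pooled_risk(m0, d, horizon)
  r1 <- pooled_risk(m1, d, horizon)
  cmp <- compare_c(r0, r1, d$time_years, d$event)
  list(delta_c = cmp$delta, C_base = cmp$C_ref, C_ext = cmp$C_new, p = cmp$p)
}
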