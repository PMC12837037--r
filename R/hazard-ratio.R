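#' Hazard ratio per standard deviation for a single biomarker
#'
#' Enters one biomarker, standardised by the stratum's (weighted) standard
#' deviation, into a weighted Cox model adjusted for the clinical base
#' covariates, within one sex stratum. The confidence interval is a Wald
#' interval on the robust (sandwich) standard error.
#'
#' @param data A `case_cohort` data frame (or full cohort) with the feature,
#'   the adjustment covariates, `sex`, `time_years`, `event` and (for a
#'   case-cohort sample) `in_subcohort`.
#' @param feature Biomarker column name.
#' @param sex `"M"` or `"F"`.
#' @param adjustment Adjustment covariates (default [score2_variables()]).
#' @param alpha Sampling fraction (default: the `alpha` attribute).
#' @param weighted_sd Standardise by the Barlow-weighted SD (default) or the
#'   unweighted stratum SD.
#' @param conf_level Confidence level.
#' @return One-row data frame: `feature`, `sex`, `hr_per_sd`, `ci_low`,
#'   `ci_high`, `p`, `n`, `n_events`.
#' @export
hazard_ratio_per_sd <- function(data, feature, sex,
                                adjustment = score2_variables(),
                                alpha = attr(data, "alpha"),
                                weighted_sd = TRUE, conf_level = 0.95) {
  stopifnot(feature %in% names(data))
  d <- data[data$sex == sex, , drop = FALSE]
  if (!nrow(d) || sum(d$event) < 10)
    stop("stratum must be non-empty with at least 10 events")
  cc <- "in_subcohort" %in% names(d) && !is.null(alpha) && alpha < 1
  w <- if (cc) barlow_weights(d$in_subcohort, d$event, alpha)$pre_weight
       else rep(1, nrow(d))
  ms <- if (weighted_sd) weighted_mean_sd(d[[feature]], w)
        else c(mean = mean(d[[feature]]), sd = sd(d[[feature]]))
  if (!is.finite(ms[["sd"]]) || ms[["sd"]] <= 0)
    stop(sprintf("feature '%s' has zero variance in stratum %s", feature, sex))
  X <- as.matrix(d[c(adjustment, feature)])
  X[, feature] <- (X[, feature] - ms[["mean"]]) / ms[["sd"]]
  fit <- fit_cox(X, d$time_years, d$event,
                 in_subcohort = if (cc) d$in_subcohort else NULL,
                 alpha = if (cc) alpha else NULL)
  b <- fit$coefficients[feature]
  se <- fit$robust_se[feature]
  q <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(feature = feature, sex = sex,
             hr_per_sd = exp(b),
             ci_low = exp(b - q * se), ci_high = exp(b + q * se),
             p = 2 * pnorm(-abs(b / se)),
             n = nrow(d), n_events = sum(d$event),
             row.names = NULL, stringsAsFactors = FALSE)
}
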