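#' Specification of a sex-specific multi-omics risk model
#'
#' The base model always contains the eight clinical covariates (sex handled
#' by stratification); omics layers are added on top in the given order.
#' Protein lists may differ by sex (signatures are selected per sex);
#' metabolites are a fixed pre-selected panel and the polygenic score is a
#' single column.
#'
#' @param layers Ordered subset of `c("proteins", "metabolites", "prs")`.
#' @param proteins Named list `male`/`female` of protein columns.
#' @param metabolites Character vector (or named list `male`/`female`) of
#'   metabolite columns.
#' @param prs Name of the polygenic-score column.
#' @param base Clinical base covariates.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(layers = character(0),
                       proteins = list(male = character(0),
                                       female = character(0)),
                       metabolites = character(0), prs = "prs",
                       base = score2_variables()) {
  layers <- unique(layers)
  bad <- setdiff(layers, c("proteins", "metabolites", "prs"))
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  if (!is.list(metabolites))
    metabolites <- list(male = metabolites, female = metabolites)
  structure(list(base = base, layers = layers, proteins = proteins,
                 metabolites = metabolites, prs = prs),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Risk-model specification\n")
  cat("  base covariates:", paste(x$base, collapse = ", "), "\n")
  cat("  layers:", if (length(x$layers)) paste(x$layers, collapse = " + ")
      else "(none)", "\n")
  if ("proteins" %in% x$layers)
    cat(sprintf("  proteins: %d male / %d female\n",
                length(x$proteins$male), length(x$proteins$female)))
  invisible(x)
}

spec_columns <- function(spec, sex = c("male", "female")) {
  sex <- match.arg(sex)
  cols <- spec$base
  for (l in spec$layers)
    cols <- c(cols, switch(l,
                           proteins = spec$proteins[[sex]],
                           metabolites = spec$metabolites[[sex]],
                           prs = spec$prs))
  unique(cols)
}

#' Fit a sex-specific risk model
#'
#' Independent Barlow-weighted Cox fits per sex on the covariates the
#' specification assigns to that sex.
#'
#' @param spec A [model_spec()].
#' @param data `case_cohort` (or full-cohort) data frame.
#' @param alpha Sampling fraction (default: the `alpha` attribute).
#' @return Object of class `sex_cox` with elements `male`, `female`
#'   ([fit_cox()] objects) and `spec`.
#' @export
fit_sex_specific <- function(spec, data, alpha = attr(data, "alpha")) {
  stopifnot(inherits(spec, "model_spec"))
  cc <- "in_subcohort" %in% names(data) && !is.null(alpha) && alpha < 1
  fits <- lapply(c(male = "M", female = "F"), function(s) {
    d <- data[data$sex == s, , drop = FALSE]
    if (!sum(d$event)) stop("no events in stratum ", s)
    cols <- spec_columns(spec, if (s == "M") "male" else "female")
    fit_cox(as.matrix(d[cols]), d$time_years, d$event,
            in_subcohort = if (cc) d$in_subcohort else NULL,
            alpha = if (cc) alpha else NULL)
  })
  structure(list(male = fits$male, female = fits$female, spec = spec),
            class = "sex_cox")
}

#' @export
print.sex_cox <- function(x, ...) {
  cat("Sex-specific risk model\n")
  print(x$spec)
  cat(sprintf("  male: n = %d, events = %d | female: n = %d, events = %d\n",
              x$male$n, x$male$n_events, x$female$n, x$female$n_events))
  invisible(x)
}

#' Pooled absolute risks from a sex-specific model
#'
#' Scores every subject with their own sex's fit and concatenates the
#' predictions, so that male, female and total-population metrics all derive
#' from the same sex-specific models.
#'
#' @param model A `sex_cox` fit.
#' @param data Cohort data frame with a `sex` column (`"M"`/`"F"`).
#' @param horizon Risk horizon in years.
#' @return Vector of 10-year absolute risks aligned with `data` rows.
#' @export
pooled_risk <- function(model, data, horizon = 10) {
  stopifnot(inherits(model, "sex_cox"))
  if (anyNA(data$sex) || !all(data$sex %in% c("M", "F")))
    stop("every subject must have known sex 'M' or 'F'")
  out <- numeric(nrow(data))
  for (s in c("M", "F")) {
    idx <- data$sex == s
    if (!any(idx)) next
    fit <- if (s == "M") model$male else model$female
    cols <- spec_columns(model$spec, if (s == "M") "male" else "female")
    out[idx] <- predict_absolute_risk(fit, as.matrix(data[idx, cols]),
                                      horizon)
  }
  out
}
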