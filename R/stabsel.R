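#' Bootstrap-LASSO stability selection of biomarker signatures
#'
#' For one sex stratum, draws `B` bootstrap resamples of the analysis sample
#' (by default stratified jointly on case status and sub-cohort membership so
#' that the case-cohort composition — and hence the Barlow sampling fraction
#' — is preserved), refits the cross-validated LASSO-Cox model in every
#' resample with the clinical base covariates force-included, records the
#' active penalised covariates at each resample's `lambda_min`, and retains
#' the features selected in at least `threshold * B` resamples.
#'
#' @param data `case_cohort` (or full-cohort) data frame.
#' @param sex `"M"` or `"F"`; the stratum analysed.
#' @param features Penalised candidate features (default: protein columns).
#' @param adjustment Force-included covariates (default [score2_variables()]).
#' @param B Number of bootstrap resamples (default 1000).
#' @param threshold Retention threshold on the selection frequency
#'   (default 0.95).
#' @param n_folds Folds for the inner cross-validation (default 10).
#' @param seed Integer seed driving the whole resampling loop.
#' @param stratified Stratify the bootstrap on case status x sub-cohort
#'   membership (default TRUE; unstratified whole-sample resampling is
#'   available for sensitivity analyses).
#' @param alpha Sampling fraction (default: the `alpha` attribute; 1 when
#'   absent).
#' @param max_redraw Cap on redraws of degenerate (event-free) resamples.
#' @param dfmax Path truncation: a resample's path stops once more than this
#'   many penalised covariates are active (default 25, roughly three times
#'   the largest plausible signature; bounds the cost of the dense path tail
#'   without affecting retention at a 95% threshold; `NULL` disables
#'   truncation).
#' @param kkt_tol Optimality tolerance for the per-resample fits; the
#'   retained set is insensitive to solver precision far below this level.
#' @return Object of class `stability_selection`: `frequency` (named,
#'   multiples of `1/B`), `retained`, `B`, `threshold`, `sex`, `seed`,
#'   `lambda_min` (per resample), `n_redraws`.
#' @export
stability_selection <- function(data, sex,
                                features = omics_columns(data, "proteins"),
                                adjustment = score2_variables(),
                                B = 1000L, threshold = 0.95, n_folds = 10L,
                                seed = 1L, stratified = TRUE,
                                alpha = attr(data, "alpha"),
                                max_redraw = 100L, dfmax = 25L,
                                kkt_tol = 1e-4) {
  if (B < 1) stop("'B' must be at least 1")
  stopifnot_prob(threshold, "threshold")
  d <- data[data$sex == sex, , drop = FALSE]
  if (!nrow(d)) stop("empty sex stratum")
  if (sum(d$event) < 30)
    warning(sprintf("only %d events in stratum %s: selection will be unstable",
                    sum(d$event), sex))
  cc <- "in_subcohort" %in% names(d) && !is.null(alpha) && alpha < 1
  n <- nrow(d)
  cols <- c(adjustment, features)
  X <- as.matrix(d[cols])
  pf <- c(rep(0, length(adjustment)), rep(1, length(features)))

  strata <- if (stratified && cc)
    interaction(d$event, d$in_subcohort, drop = TRUE)
  else if (stratified) factor(d$event)
  else factor(rep(1, n))
  groups <- split(seq_len(n), strata)

  counts <- setNames(numeric(length(features)), features)
  lmin <- numeric(B)
  n_redraws <- 0L
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    repeat {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]), use.names = FALSE)
      if (sum(d$event[idx]) > 0) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraw)
        stop("exceeded the cap on redraws of event-free resamples")
    }
    # alpha rescaled by the realised sub-cohort share of the resample
    # (equal to the original alpha under stratified resampling)
    a_b <- if (cc)
      alpha * sum(d$in_subcohort[idx]) / sum(d$in_subcohort) else NULL
    cv <- cv_lambda_min(X[idx, , drop = FALSE], d$time_years[idx],
                        d$event[idx],
                        in_subcohort = if (cc) d$in_subcohort[idx] else NULL,
                        alpha = a_b, penalty_factor = pf, n_folds = n_folds,
                        seed = sample.int(.Machine$integer.max, 1),
                        dfmax = dfmax, kkt_tol = kkt_tol)
    counts[cv$active_min] <- counts[cv$active_min] + 1
    lmin[b] <- cv$lambda_min
  }
  freq <- counts / B
  structure(list(frequency = freq,
                 retained = names(freq)[freq >= threshold],
                 B = as.integer(B), threshold = threshold, sex = sex,
                 seed = as.integer(seed), lambda_min = lmin,
                 n_redraws = n_redraws, adjustment = adjustment,
                 stratified = stratified),
            class = "stability_selection")
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf("Bootstrap-LASSO stability selection (sex %s, B = %d, threshold %.2f)\n",
              x$sex, x$B, x$threshold))
  cat(sprintf("  retained %d feature(s): %s\n", length(x$retained),
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(none)"))
  top <- sort(x$frequency, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top)) {
    cat("  top selection frequencies:\n")
    print(round(head(top, 10), 3))
  }
  invisible(x)
}

#' @export
plot.stability_selection <- function(x, ...) {
  f <- sort(x$frequency, decreasing = TRUE)
  f <- f[f > 0]
  plot(seq_along(f), f, type = "h", ylim = c(0, 1),
       xlab = "feature rank", ylab = "selection frequency",
       main = sprintf("Stability selection (sex %s)", x$sex), ...)
  abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Refit the retained signature in an unpenalised weighted Cox model
#'
#' Fits the clinical base covariates plus the retained features of a
#' [stability_selection()] result, per sex, by unpenalised weighted Cox
#' regression. An empty retained set returns the base-covariates-only model.
#'
#' @param selection A `stability_selection` object.
#' @param data The analysis sample the selection was run on.
#' @param alpha Sampling fraction (default: the `alpha` attribute).
#' @return A [fit_cox()] object (`cc_cox`).
#' @export
refit_selected <- function(selection, data, alpha = attr(data, "alpha")) {
  stopifnot(inherits(selection, "stability_selection"))
  d <- data[data$sex == selection$sex, , drop = FALSE]
  cols <- c(selection$adjustment, selection$retained)
  cc <- "in_subcohort" %in% names(d) && !is.null(alpha) && alpha < 1
  fit_cox(as.matrix(d[cols]), d$time_years, d$event,
          in_subcohort = if (cc) d$in_subcohort else NULL,
          alpha = if (cc) alpha else NULL)
}
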