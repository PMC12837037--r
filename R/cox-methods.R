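#' @export
print.cc_cox <- function(x, digits = 4, ...) {
  cat("Weighted Cox proportional-hazards model (Breslow ties)\n")
  if (!is.null(x$alpha) && x$alpha < 1)
    cat(sprintf("  case-cohort design, Barlow weights (alpha = %.4f)\n",
                x$alpha))
  cat(sprintf("  n = %d subjects, %d events; loglik = %.4f; %d iterations%s\n",
              x$n, x$n_events, x$loglik[["final"]], x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(round(cbind(coef = x$coefficients, `HR` = exp(x$coefficients),
                    `robust se` = x$robust_se), digits))
  invisible(x)
}

#' @export
summary.cc_cox <- function(object, conf_level = 0.95, ...) {
  z <- object$coefficients / object$robust_se
  q <- qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    coef = object$coefficients,
    hr = exp(object$coefficients),
    se = object$se,
    robust_se = object$robust_se,
    hr_low = exp(object$coefficients - q * object$robust_se),
    hr_high = exp(object$coefficients + q * object$robust_se),
    z = z,
    p = 2 * pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik, n = object$n,
                 n_events = object$n_events, converged = object$converged,
                 alpha = object$alpha),
            class = "summary.cc_cox")
}

#' @export
print.summary.cc_cox <- function(x, digits = 4, ...) {
  cat(sprintf("Weighted Cox model: n = %d, events = %d, alpha = %.4f\n",
              x$n, x$n_events, x$alpha))
  print(round(x$coefficients, digits))
  cat(sprintf("log partial likelihood: null %.4f, final %.4f\n",
              x$loglik[["null"]], x$loglik[["final"]]))
  invisible(x)
}

#' @export
coef.cc_cox <- function(object, ...) object$coefficients

#' @export
vcov.cc_cox <- function(object, robust = TRUE, ...)
  if (robust) object$var else object$naive_var

#' @export
logLik.cc_cox <- function(object, ...) {
  structure(object$loglik[["final"]], df = length(object$coefficients),
            class = "logLik")
}

#' Predictions from a weighted Cox fit
#'
#' @param object A `cc_cox` fit.
#' @param newx Covariate matrix with the fitting columns (or `newdata` for
#'   formula fits).
#' @param type `"lp"` (linear predictor, centred at the fitting-sample
#'   weighted mean), `"risk"` (absolute risk by `horizon`) or `"survival"`.
#' @param horizon Horizon in years for `type = "risk"`/`"survival"`.
#' @param newdata Data frame, for fits created through the formula interface.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.cc_cox <- function(object, newx = NULL, type = c("lp", "risk", "survival"),
                           horizon = 10, newdata = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newx)) {
    if (is.null(newdata) || is.null(object$terms))
      stop("supply 'newx' (or 'newdata' for formula fits)")
    tt <- delete.response(object$terms)
    X <- model.matrix(tt, model.frame(tt, newdata, na.action = na.pass))
    newx <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  }
  newx <- as.matrix(newx)
  lp <- drop(newx %*% object$coefficients) - sum(object$means * object$coefficients)
  if (type == "lp") return(lp)
  risk <- predict_absolute_risk(object, newx, horizon)
  if (type == "risk") risk else 1 - risk
}

#' Absolute risk by a horizon from a weighted Cox fit
#'
#' Computes `1 - exp(-H0(horizon) * exp(lp))` with the Breslow baseline
#' cumulative hazard `H0` and the linear predictor centred at the
#' fitting-sample weighted covariate mean.
#'
#' @param model A `cc_cox` fit.
#' @param newx Covariate matrix.
#' @param horizon Horizon in years; must not exceed the fitting sample's
#'   maximum observed time.
#' @return Vector of probabilities in `[0, 1]`.
#' @export
predict_absolute_risk <- function(model, newx, horizon = 10) {
  stopifnot(inherits(model, "cc_cox"))
  if (horizon > model$max_time)
    stop(sprintf("horizon %.3g exceeds the maximum observed time %.3g",
                 horizon, model$max_time))
  newx <- as.matrix(newx)
  lp <- drop(newx %*% model$coefficients) - sum(model$means * model$coefficients)
  h0 <- baseline_hazard_at(model, horizon)
  1 - exp(-h0 * exp(lp))
}

# right-continuous step-function lookup of the centred baseline hazard
baseline_hazard_at <- function(model, t) {
  bh <- model$basehaz
  if (!nrow(bh)) return(0)
  idx <- findInterval(t, bh$time)
  ifelse(idx == 0, 0, bh$hazard[pmax(idx, 1)])
}

#' @export
residuals.cc_cox <- function(object, type = "score", ...) {
  match.arg(type, "score")
  object$score_residuals
}
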