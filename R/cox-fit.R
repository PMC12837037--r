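#' Weighted Cox proportional-hazards fit (Breslow ties)
#'
#' Maximises the weighted Breslow partial likelihood by Newton-Raphson with
#' step-halving, on counting-process data `(start, stop]` so that Barlow
#' case-cohort weighting (subjects entering the risk set only at their own
#' event) is expressed directly. Model-based and robust (sandwich) standard
#' errors are both computed; the sandwich aggregates score residuals by
#' subject, as required for valid inference under case-cohort weighting.
#' The Breslow baseline cumulative hazard is stored with the linear predictor
#' centred at the weighted covariate mean of the fitting sample, so the fit
#' can emit absolute risks.
#'
#' `fit_cox()` is generic: the default method takes a covariate matrix, the
#' formula method a `survival::Surv` response and a data frame. Supplying
#' `in_subcohort` and `alpha` requests Barlow expansion of a case-cohort
#' sample; otherwise weights default to 1 and the fit is an ordinary Cox
#' model.
#'
#' @param x Covariate matrix (subjects in rows), or a formula.
#' @param time Follow-up time (years).
#' @param event 0/1 event indicator.
#' @param in_subcohort Optional 0/1 sub-cohort membership (Barlow design).
#' @param alpha Sub-cohort sampling fraction, required with `in_subcohort`.
#' @param ties Tie handling; only `"breslow"` is implemented.
#' @param control List of solver settings, see [cox_control()].
#' @param ... Passed between methods.
#' @return Object of class `cc_cox` with components `coefficients`, `se`,
#'   `robust_se`, `var` (robust), `naive_var`, `loglik` (null and final),
#'   `iterations`, `converged`, `monotone` (separation flag), `means`
#'   (weighted covariate centre), `basehaz` (step function of the centred
#'   cumulative baseline hazard), `n`, `n_events`, `max_time`.
#' @examples
#' d <- generate_cohort(sim_config(n_full_cohort = 400, n_proteins = 0,
#'                                 n_metabolites = 0, include_prs = FALSE,
#'                                 seed = 3))$data
#' f <- fit_cox(as.matrix(d[c("age", "sbp")]), d$time_years, d$event)
#' exp(coef(f))  # hazard ratios
#' @export
fit_cox <- function(x, ...) UseMethod("fit_cox")

#' @rdname fit_cox
#' @param formula A formula with a `survival::Surv(time, event)` response.
#' @param data Data frame holding the formula variables.
#' @export
fit_cox.formula <- function(formula, data, in_subcohort = NULL, alpha = NULL,
                            ties = "breslow", control = cox_control(), ...) {
  mf <- model.frame(formula, data, na.action = na.pass)
  y <- model.response(mf)
  if (!survival::is.Surv(y)) stop("the response must be a survival::Surv object")
  X <- model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- fit_cox.default(X, time = y[, "time"], event = y[, "status"],
                         in_subcohort = in_subcohort, alpha = alpha,
                         ties = ties, control = control, ...)
  fit$call <- match.call()
  fit$terms <- terms(mf)
  fit
}

#' @rdname fit_cox
#' @export
fit_cox.default <- function(x, time, event, in_subcohort = NULL, alpha = NULL,
                            ties = "breslow", control = cox_control(), ...) {
  ties <- match.arg(ties, "breslow")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (anyNA(x) || anyNA(time) || anyNA(event))
    stop("missing values in covariates or outcome; impute first")
  if (sum(event) < 1) stop("at least one event is required")
  p <- ncol(x)
  if (qr(x)$rank < p)
    stop("covariate matrix is rank deficient (exactly collinear predictors)")

  ex <- cc_expand(x, time, event, in_subcohort, alpha)
  # weighted covariate centre of the fitting sample (subject-level weights)
  subw <- if (is.null(in_subcohort)) rep(1, nrow(x)) else
    barlow_weights(in_subcohort, event, alpha)$pre_weight
  subw[subw == 0] <- 1  # outside-sub-cohort cases count at their event weight
  means <- colSums(x * subw) / sum(subw)
  sds <- apply(x, 2, sd)

  beta <- rep(0, p)
  ev0 <- cox_eval_cpp(ex$x, ex$start, ex$stop, ex$status, ex$w, beta, TRUE)
  ll0 <- ev0$loglik
  ll_old <- ll0
  ev <- ev0
  converged <- FALSE
  monotone <- FALSE
  iter <- 0
  for (iter in seq_len(control$max_iter)) {
    info <- ev$info
    delta <- tryCatch(solve(info, ev$grad), error = function(e) {
      solve(info + diag(control$ridge, p), ev$grad)
    })
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ev_new <- cox_eval_cpp(ex$x, ex$start, ex$stop, ex$status, ex$w,
                             beta_new, TRUE)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- beta_new
    ev <- ev_new
    if (max(abs(ev$grad)) <= control$score_tol ||
        abs(ev$loglik - ll_old) <= control$rel_tol * (abs(ev$loglik) + 1e-10)) {
      converged <- TRUE
      ll_old <- ev$loglik
      break
    }
    ll_old <- ev$loglik
  }
  # separation guard: a diverging estimate (on the per-SD scale) signals a
  # monotone partial likelihood; cap and flag rather than fail silently
  big <- which(abs(beta) * pmax(sds, 1e-12) > control$beta_cap)
  if (length(big)) {
    warning("monotone likelihood (separation): coefficient estimate capped for ",
            paste(colnames(x)[big], collapse = ", "))
    beta[big] <- sign(beta[big]) * control$beta_cap / pmax(sds[big], 1e-12)
    ev <- cox_eval_cpp(ex$x, ex$start, ex$stop, ex$status, ex$w, beta, TRUE)
    monotone <- TRUE
  }
  if (!converged && !monotone)
    warning("Newton-Raphson did not converge in ", control$max_iter,
            " iterations")

  naive_var <- tryCatch(solve(ev$info), error = function(e)
    solve(ev$info + diag(control$ridge, p)))
  U <- cox_score_resid_cpp(ex$x, ex$start, ex$stop, ex$status, ex$w, beta)
  Us <- rowsum(U, ex$id)
  robust_var <- naive_var %*% crossprod(Us) %*% naive_var
  dimnames(naive_var) <- dimnames(robust_var) <- list(colnames(x), colnames(x))

  # baseline cumulative hazard centred at the weighted covariate mean
  h0 <- cumsum(ev$h0_increment) * exp(sum(means * beta))
  basehaz <- data.frame(time = ev$event_times, hazard = h0)

  structure(list(coefficients = setNames(as.numeric(beta), colnames(x)),
                 se = sqrt(diag(naive_var)),
                 robust_se = sqrt(diag(robust_var)),
                 var = robust_var, naive_var = naive_var,
                 loglik = c(null = ll0, final = ev$loglik),
                 score = ev$grad,
                 iterations = iter, converged = converged,
                 monotone = monotone, means = means, basehaz = basehaz,
                 score_residuals = Us,
                 n = nrow(x), n_events = sum(event == 1),
                 max_time = max(time), alpha = alpha %||% 1,
                 ties = ties, call = match.call()),
            class = "cc_cox")
}

#' Solver settings for [fit_cox()]
#'
#' @param max_iter Newton iteration cap.
#' @param score_tol Convergence on the maximal absolute score component.
#' @param rel_tol Convergence on the relative log-likelihood change.
#' @param beta_cap Per-SD coefficient magnitude treated as separation.
#' @param ridge Ridge added to a singular information matrix.
#' @return List of settings.
#' @export
cox_control <- function(max_iter = 30L, score_tol = 1e-8, rel_tol = 1e-10,
                        beta_cap = 15, ridge = 1e-8) {
  list(max_iter = max_iter, score_tol = score_tol, rel_tol = rel_tol,
       beta_cap = beta_cap, ridge = ridge)
}
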