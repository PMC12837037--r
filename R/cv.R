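#' Ten-fold cross-validated penalty selection for the LASSO-Cox path
#'
#' Selects the penalty minimising the cross-validated partial-likelihood
#' deviance. Folds are stratified on event status. The default criterion is
#' the Verweij-van Houwelingen form, `-2 * (l_all(beta_k) - l_train(beta_k))`
#' per left-out fold `k`, which remains well defined for small folds; the
#' basic fold-wise form (partial likelihood restricted to the held-out
#' subjects) is available via `form = "basic"`.
#'
#' @inheritParams lasso_cox_path
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the stratified fold assignment.
#' @param form Cross-validated deviance form.
#' @param fold_kkt_tol Optimality tolerance for the fold fits (the held-out
#'   deviance is insensitive to solver precision well below this level); the
#'   returned full-sample path always carries the strict `kkt_tol`
#'   certificate.
#' @return Object of class `cc_lasso_cv`: `lambda`, `cvm` (mean CV deviance),
#'   `cvsd` (fold SE), `lambda_min`, `index_min`, `beta_min` (native-scale
#'   coefficients of the full-sample path at `lambda_min`), `active_min`
#'   (names of active penalised covariates at `lambda_min`), `folds`, `path`.
#' @export
cv_lambda_min <- function(x, time, event, in_subcohort = NULL, alpha = NULL,
                          penalty_factor = NULL, n_folds = 10L, seed = 1L,
                          lambda = NULL, nlambda = 100L,
                          lambda_min_ratio = 0.001,
                          form = c("vvh", "basic"), dfmax = NULL,
                          kkt_tol = 1e-7, fold_kkt_tol = 1e-3) {
  form <- match.arg(form)
  if (n_folds < 2) stop("'n_folds' must be at least 2")
  x <- as.matrix(x)
  n <- nrow(x)
  path <- lasso_cox_path(x, time, event, in_subcohort, alpha, penalty_factor,
                         lambda = lambda, nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio,
                         dfmax = dfmax, kkt_tol = kkt_tol)
  grid <- path$lambda

  set.seed(as.integer(seed))
  folds <- integer(n)
  for (g in list(which(event == 1), which(event == 0))) {
    if (length(g))
      folds[g] <- sample(rep_len(seq_len(n_folds), length(g)))
  }
  ev_per_fold <- vapply(seq_len(n_folds), function(k)
    sum(event[folds == k]), numeric(1))
  if (any(ev_per_fold == 0))
    stop("a fold has zero events after stratified assignment; ",
         "reduce 'n_folds'")

  ex_all <- cc_expand(x, time, event, in_subcohort, alpha)
  devmat <- matrix(NA_real_, length(grid), n_folds)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    pk <- lasso_cox_path(x[tr, , drop = FALSE], time[tr], event[tr],
                         in_subcohort = if (!is.null(in_subcohort))
                           in_subcohort[tr] else NULL,
                         alpha = alpha, penalty_factor = penalty_factor,
                         lambda = grid, dfmax = dfmax,
                         kkt_tol = fold_kkt_tol, scan_stride = 3L)
    ex_tr <- cc_expand(x[tr, , drop = FALSE], time[tr], event[tr],
                       if (!is.null(in_subcohort)) in_subcohort[tr] else NULL,
                       alpha)
    ex_te <- if (form == "basic")
      cc_expand(x[!tr, , drop = FALSE], time[!tr], event[!tr],
                if (!is.null(in_subcohort)) in_subcohort[!tr] else NULL,
                alpha) else NULL
    mm <- seq_along(pk$lambda)
    if (form == "vvh") {
      ll_all <- cox_loglik_multi_cpp(ex_all$x %*% pk$beta, ex_all$start,
                                     ex_all$stop, ex_all$status, ex_all$w)
      ll_tr <- cox_loglik_multi_cpp(ex_tr$x %*% pk$beta, ex_tr$start,
                                    ex_tr$stop, ex_tr$status, ex_tr$w)
      devmat[mm, k] <- -2 * (ll_all - ll_tr)
    } else {
      devmat[mm, k] <- -2 * cox_loglik_multi_cpp(ex_te$x %*% pk$beta,
                                                 ex_te$start, ex_te$stop,
                                                 ex_te$status, ex_te$w)
    }
  }
  ok <- rowSums(is.na(devmat)) == 0
  cvm <- rowMeans(devmat)
  cvsd <- apply(devmat, 1, sd) / sqrt(n_folds)
  idx <- which(ok)[which.min(cvm[ok])]
  beta_min <- path$beta[, min(idx, ncol(path$beta))]
  active <- names(beta_min)[path$penalty_factor > 0 & beta_min != 0]
  structure(list(lambda = grid, cvm = cvm, cvsd = cvsd,
                 lambda_min = grid[idx], index_min = idx,
                 beta_min = beta_min, active_min = active,
                 folds = folds, seed = seed, form = form, path = path),
            class = "cc_lasso_cv")
}

#' @export
print.cc_lasso_cv <- function(x, ...) {
  cat(sprintf("Cross-validated LASSO-Cox (%s deviance, %d folds)\n",
              x$form, max(x$folds)))
  cat(sprintf("  lambda_min = %.5g (grid point %d of %d), %d active covariates\n",
              x$lambda_min, x$index_min, length(x$lambda),
              length(x$active_min)))
  invisible(x)
}

#' @export
plot.cc_lasso_cv <- function(x, ...) {
  plot(log(x$lambda), x$cvm, type = "l",
       xlab = expression(log(lambda)), ylab = "CV partial-likelihood deviance",
       main = "Cross-validation curve", ...)
  segments(log(x$lambda), x$cvm - x$cvsd, log(x$lambda), x$cvm + x$cvsd,
           col = "grey70")
  abline(v = log(x$lambda_min), lty = 2)
  invisible(x)
}
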