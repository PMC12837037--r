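test_that("the path satisfies its definitional endpoints", {
  d <- gen_surv(300, c(0.8, -0.6, rep(0, 8)), seed = 20)
  pf <- c(0, 0, rep(1, 8))
  path <- lasso_cox_path(d$x, d$time, d$event, penalty_factor = pf)
  # at lambda_max all penalised coefficients are exactly zero and the forced
  # covariates equal their unpenalised two-covariate fit
  expect_equal(path$df[1], 0)
  expect_true(all(path$beta[3:10, 1] == 0))
  f2 <- fit_cox(d$x[, 1:2], d$time, d$event)
  expect_lt(max(abs(path$beta[1:2, 1] - coef(f2))), 1e-6)
  # KKT certificate holds everywhere on the returned path
  expect_lt(max(path$kkt), 1e-6)
  # empty / non-decreasing grids are rejected
  expect_error(lasso_cox_path(d$x, d$time, d$event, lambda = numeric(0)),
               "empty")
  expect_error(lasso_cox_path(d$x, d$time, d$event, lambda = c(1, 2)),
               "decreasing")
  expect_error(lasso_cox_path(d$x, d$time, rep(0, 300)), "no events")
})

test_that("the penalised fit approaches the unpenalised fit as lambda -> 0", {
  d <- gen_surv(600, c(0.6, -0.4, 0.3, 0, 0), seed = 21)
  path <- lasso_cox_path(d$x, d$time, d$event,
                         nlambda = 120, lambda_min_ratio = 1e-6)
  f <- fit_cox(d$x, d$time, d$event)
  expect_lt(max(abs(path$beta[, ncol(path$beta)] - coef(f))), 1e-4)
})

test_that("the solver agrees with glmnet along the path", {
  skip_if_not_installed("glmnet")
  d <- gen_surv(400, c(0.8, -0.6, rep(0, 18)), seed = 22)
  path <- lasso_cox_path(d$x, d$time, d$event)
  g <- glmnet::glmnet(d$x, survival::Surv(d$time, d$event), family = "cox",
                      standardize = TRUE, thresh = 1e-12,
                      lambda = path$lambda / length(d$time))
  for (m in c(20, 40, 70)) {
    bg <- as.matrix(glmnet::coef.glmnet(
      g, s = path$lambda[m] / length(d$time), exact = TRUE, x = d$x,
      y = survival::Surv(d$time, d$event)))
    expect_lt(max(abs(path$beta[, m] - bg)), 1e-5)
  }
})

test_that("strong planted predictors enter the path before any null", {
  d <- gen_surv(1000, c(0.8, 0.7, -0.7, rep(0, 50)), rate = 0.1, seed = 23)
  path <- lasso_cox_path(d$x, d$time, d$event)
  mid <- which(path$df >= 3)[1]
  active <- rownames(path$beta)[path$beta[, mid] != 0]
  expect_setequal(active, c("v1", "v2", "v3"))
})

test_that("cross-validated penalty selection is deterministic and stratified", {
  d <- gen_surv(300, c(0.6, -0.5, rep(0, 10)), rate = 0.1, seed = 24)
  cv1 <- cv_lambda_min(d$x, d$time, d$event, seed = 7)
  cv2 <- cv_lambda_min(d$x, d$time, d$event, seed = 7)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(min(cv1$cvm[is.finite(cv1$cvm)]), cv1$cvm[cv1$index_min])
  # more folds than events in a stratum is impossible
  few <- gen_surv(60, c(0.5), rate = 0.01, seed = 25)
  expect_error(cv_lambda_min(few$x, few$time, few$event,
                             n_folds = sum(few$event) + 1), "zero events")
})

test_that("cross-validation keeps strong signals and prunes pure noise", {
  # strong planted effects survive at lambda_min
  keep <- 0
  for (s in 1:5) {
    d <- gen_surv(800, c(1, -1, rep(0, 30)), rate = 0.08, seed = 30 + s)
    cv <- cv_lambda_min(d$x, d$time, d$event, seed = s)
    keep <- keep + all(c("v1", "v2") %in% cv$active_min)
  }
  expect_gte(keep, 5)
  # pure noise puts lambda_min in the sparser half of the grid most of the time
  upper <- 0
  for (s in 1:8) {
    d <- gen_surv(300, rep(0, 20), rate = 0.1, seed = 40 + s)
    cv <- cv_lambda_min(d$x, d$time, d$event, seed = s)
    upper <- upper + (cv$index_min <= length(cv$lambda) / 2)
  }
  expect_gte(upper, 6)
})
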