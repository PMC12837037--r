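test_that("Barlow weights follow the case-cohort definition", {
  # alpha = 1: every weight is 1
  w <- barlow_weights(c(1, 1, 1), c(0, 1, 0), 1)
  expect_equal(w$pre_weight, c(1, 1, 1))
  expect_equal(w$event_weight[2], 1)
  # alpha = 0.5: non-case sub-cohort member carries 1/alpha = 2 before events
  w <- barlow_weights(c(1, 1, 0), c(0, 1, 1), 0.5)
  expect_equal(w$pre_weight, c(2, 2, 0))   # outside-sub-cohort case: 0 pre-event
  expect_equal(w$event_weight, c(NA, 1, 1))
  expect_error(barlow_weights(c(1, 0), c(0, 0), 0.5), "sub-cohort or .* case")
  expect_error(barlow_weights(c(1, 1), c(0, 1), 0), "alpha")
})

test_that("a single binary covariate matches the scalar score-equation root", {
  set.seed(10)
  n <- 150
  x <- matrix(rbinom(n, 1, 0.4), n, 1, dimnames = list(NULL, "g"))
  time <- rexp(n, 0.3 * exp(0.7 * x[, 1]))  # continuous: no ties
  event <- rep(1L, n)
  f <- fit_cox(x, time, event)
  # independent 1-d root finding on the Breslow score equation
  score <- function(b) {
    ord <- order(time)
    xs <- x[ord, 1]; elp <- exp(b * xs)
    s <- 0
    for (i in seq_len(n)) {
      at <- i:n
      s <- s + xs[i] - sum(xs[at] * elp[at]) / sum(elp[at])
    }
    s
  }
  root <- uniroot(score, c(-3, 3), tol = 1e-12)$root
  expect_lt(abs(coef(f)[["g"]] - root), 1e-7)
})

test_that("unit-weight fits agree with the reference Cox implementation", {
  d <- gen_surv(400, c(0.5, -0.3, 0.2), seed = 11)
  f <- fit_cox(d$x, d$time, d$event)
  ref <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x,
                         ties = "breslow", robust = TRUE)
  expect_lt(max(abs(coef(f) - coef(ref))), 1e-6)
  expect_lt(max(abs(f$se - sqrt(diag(ref$naive.var)))), 1e-6)
  expect_lt(max(abs(f$robust_se - sqrt(diag(ref$var)))), 1e-6)
  expect_lt(abs(f$loglik[["final"]] - ref$loglik[2]), 1e-8)
  expect_true(f$converged)
  # baseline cumulative hazard matches the reference Breslow estimator
  bh <- survival::basehaz(survival::coxph(survival::Surv(d$time, d$event) ~ d$x,
                                          ties = "breslow"), centered = TRUE)
  ours <- survomics:::baseline_hazard_at(f, c(2, 5, 8))
  ref_h <- approx(bh$time, bh$hazard, xout = c(2, 5, 8), method = "constant",
                  f = 0, rule = 2)$y
  expect_lt(max(abs(ours - ref_h)), 1e-8)
})

test_that("exactly collinear predictors are rejected", {
  d <- gen_surv(100, c(0.5, -0.3), seed = 12)
  x <- cbind(d$x, dup = d$x[, 1])
  expect_error(fit_cox(x, d$time, d$event), "collinear")
})

test_that("alpha = 1 Barlow expansion equals the unweighted full-cohort fit", {
  d <- gen_surv(300, c(0.5, -0.3), seed = 13)
  f0 <- fit_cox(d$x, d$time, d$event)
  f1 <- fit_cox(d$x, d$time, d$event, in_subcohort = rep(1, 300), alpha = 1)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-12)
  expect_equal(f0$loglik, f1$loglik, tolerance = 1e-10)
})

test_that("the formula interface reproduces the matrix interface", {
  d <- gen_surv(200, c(0.4, -0.2), seed = 14)
  df <- data.frame(time = d$time, event = d$event, a = d$x[, 1], b = d$x[, 2])
  ff <- fit_cox(survival::Surv(time, event) ~ a + b, data = df)
  fm <- fit_cox(d$x, d$time, d$event)
  expect_equal(unname(coef(ff)), unname(coef(fm)), tolerance = 1e-10)
  # predictions through newdata
  expect_equal(unname(predict(ff, newdata = df[1:5, ], type = "lp")),
               unname(predict(fm, newx = d$x[1:5, , drop = FALSE], type = "lp")),
               tolerance = 1e-10)
})

test_that("absolute risks follow the baseline-hazard identity and match incidence", {
  d <- gen_surv(5000, c(0.5, -0.3), rate = 0.05, seed = 15)
  f <- fit_cox(d$x, d$time, d$event)
  # an average subject (lp = 0 after centring) has risk 1 - exp(-H0(h))
  xbar <- matrix(f$means, 1)
  h <- 8
  expect_equal(predict_absolute_risk(f, xbar, h),
               1 - exp(-survomics:::baseline_hazard_at(f, h)), tolerance = 1e-10)
  # mean predicted risk tracks the empirical incidence closely
  risks <- predict_absolute_risk(f, d$x, h)
  emp <- mean(d$time <= h & d$event == 1)
  # compare against censoring-free incidence via KM
  km <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  obs <- 1 - approx(c(0, km$time), c(1, km$surv), xout = h, method = "constant",
                    f = 0, rule = 2)$y
  expect_lt(abs(mean(risks) - obs), 0.01)
  expect_true(all(risks >= 0 & risks <= 1))
  expect_error(predict_absolute_risk(f, xbar, 1e5), "horizon")
})

test_that("per-SD hazard ratios are scale invariant and detect planted signal", {
  coh <- generate_cohort(planted_config(n = 1500, n_prot = 3, seed = 16))
  d <- coh$data
  h1 <- hazard_ratio_per_sd(d, "prot_1", "M")
  d2 <- d
  d2$prot_1 <- d2$prot_1 * 10
  h2 <- hazard_ratio_per_sd(d2, "prot_1", "M")
  expect_equal(h1$hr_per_sd, h2$hr_per_sd, tolerance = 1e-8)
  expect_gt(h1$hr_per_sd, 1)
  expect_lt(h1$p, 0.001)
  dz <- d
  dz$prot_3 <- 1
  expect_error(hazard_ratio_per_sd(dz, "prot_3", "M"), "zero variance")
})

test_that("Barlow-weighted case-cohort fits are nearly unbiased for the cohort fit", {
  d <- gen_surv(4000, c(0.5, -0.4, 0.3), rate = 0.012, shape = 1.2,
                drop_rate = 0.01, seed = 17)
  f_full <- fit_cox(d$x, d$time, d$event)
  reps <- 40
  est <- matrix(NA, reps, 3)
  ses <- matrix(NA, reps, 3)
  for (r in seq_len(reps)) {
    set.seed(200 + r)
    sub <- sample.int(4000, 800)
    insub <- seq_len(4000) %in% sub
    keep <- insub | d$event == 1
    fcc <- fit_cox(d$x[keep, ], d$time[keep], d$event[keep],
                   in_subcohort = insub[keep], alpha = 0.2)
    est[r, ] <- coef(fcc)
    ses[r, ] <- fcc$robust_se
  }
  rel_bias <- (colMeans(est) - coef(f_full)) / coef(f_full)
  expect_lt(max(abs(rel_bias)), 0.05)
  cover <- mean(abs(sweep(est, 2, coef(f_full))) <= 1.96 * ses)
  expect_gt(cover, 0.88)
})
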