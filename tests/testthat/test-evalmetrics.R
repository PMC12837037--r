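test_that("Harrell's C equals brute-force pair enumeration, with ties and censoring", {
  for (s in 1:10) {
    set.seed(50 + s)
    n <- 120
    time <- sample(1:40, n, replace = TRUE)          # tied times
    event <- rbinom(n, 1, 0.6)
    risk <- round(rnorm(n), 1)                       # tied scores
    res <- harrell_c(risk, time, event)
    oracle <- brute_force_c(risk, time, event)
    expect_equal(res$C, oracle$C, tolerance = 1e-12)
    expect_equal(res$pairs, oracle$pairs)
  }
})

test_that("C-index hits its analytic endpoints and the worked 5-subject value", {
  # perfect ranking on uncensored data
  time <- c(1, 2, 3, 4, 5)
  expect_equal(harrell_c(-time, time, rep(1, 5))$C, 1)
  # constant risk scores only ever tie
  expect_equal(harrell_c(rep(2, 5), time, rep(1, 5))$C, 0.5)
  # mixed-censoring fixture, value frozen from the enumeration oracle
  ev <- c(1, 1, 0, 1, 0)
  sc <- c(5, 4, 3, 2, 1)
  oracle <- brute_force_c(sc, time, ev)
  expect_equal(harrell_c(sc, time, ev)$C, oracle$C)
  expect_equal(harrell_c(sc, time, ev)$C, 1)  # scores reverse the event order
  expect_error(harrell_c(1, 1, 0), "comparable")
})

test_that("C agrees with the survival package on untied data", {
  d <- gen_surv(300, c(0.7, -0.4), seed = 55)
  risk <- drop(d$x %*% c(0.7, -0.4))
  ours <- harrell_c(risk, d$time, d$event)
  ref <- survival::concordance(survival::Surv(d$time, d$event) ~ risk,
                               reverse = TRUE)
  expect_equal(ours$C, ref$concordance, tolerance = 1e-12)
  expect_equal(ours$var, ref$var, tolerance = 0.05)
})

test_that("comparing a model with itself gives delta C = 0, p = 1", {
  d <- gen_surv(150, c(0.6), seed = 56)
  r <- drop(d$x)
  cmp <- compare_c(r, r, d$time, d$event)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p, 1)
  expect_error(compare_c(r[-1], r, d$time, d$event), "same subjects")
})

test_that("the correlated-C test is calibrated and has power", {
  # type-I error at nominal 0.05 under independent noise scores
  set.seed(57)
  n <- 300
  rej <- 0
  reps <- 120
  for (r in seq_len(reps)) {
    t_ev <- rexp(n); cens <- rexp(n, 0.5)
    time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
    cmp <- compare_c(rnorm(n), rnorm(n), time, event)
    rej <- rej + (cmp$p < 0.05)
  }
  expect_gte(rej / reps, 0.01)
  expect_lte(rej / reps, 0.09)
  # power when the new score adds a real predictor
  pow <- 0
  for (r in 1:10) {
    d <- gen_surv(600, c(0.6, 0.5), rate = 0.2, seed = 60 + r)
    r_ref <- d$x[, 1] * 0.6
    r_new <- drop(d$x %*% c(0.6, 0.5))
    pow <- pow + (compare_c(r_ref, r_new, d$time, d$event)$p < 0.05)
  }
  expect_gte(pow, 8)
})

test_that("categorical NRI matches hand counts on an uncensored toy", {
  # 8 subjects, 3 events; two events reclassified up, one non-event up
  time <- c(2, 3, 4, 12, 12, 12, 12, 12)
  event <- c(1, 1, 1, 0, 0, 0, 0, 0)
  p_ref <- c(0.10, 0.10, 0.20, 0.10, 0.10, 0.20, 0.40, 0.10)
  p_new <- c(0.20, 0.20, 0.20, 0.10, 0.20, 0.20, 0.40, 0.10)
  res <- categorical_nri(p_ref, p_new, time, event, cuts = c(0.15, 0.30),
                         horizon = 10, n_boot = 0)
  # hand enumeration: up|event = 2/3, down|event = 0; up|non-event = 1/5
  expect_equal(res$nri[["events"]], 100 * (2 / 3), tolerance = 1e-10)
  expect_equal(res$nri[["non_events"]], 100 * (-1 / 5), tolerance = 1e-10)
  expect_equal(res$nri[["total"]], res$nri[["events"]] + res$nri[["non_events"]],
               tolerance = 1e-10)
  # identity at equal models, antisymmetry under swap
  id <- categorical_nri(p_ref, p_ref, time, event, n_boot = 0)
  expect_equal(unname(id$nri), c(0, 0, 0))
  swap <- categorical_nri(p_new, p_ref, time, event, cuts = c(0.15, 0.30),
                          horizon = 10, n_boot = 0)
  expect_equal(swap$nri[["total"]], -res$nri[["total"]], tolerance = 1e-10)
  expect_error(categorical_nri(p_ref, p_new, time, event, cuts = c(0.3, 0.2)),
               "increasing")
})

test_that("continuous NRI obeys identity, antisymmetry and hand counts", {
  time <- c(1, 2, 11, 11)
  event <- c(1, 1, 0, 0)
  p_ref <- c(0.1, 0.3, 0.2, 0.2)
  p_new <- c(0.2, 0.2, 0.1, 0.3)
  res <- continuous_nri(p_ref, p_new, time, event, horizon = 10, n_boot = 0)
  # events: up 1/2 - down 1/2 = 0; non-events: down 1/2 - up 1/2 = 0
  expect_equal(res$nri[["total"]], 0, tolerance = 1e-10)
  p_new2 <- c(0.2, 0.4, 0.1, 0.1)
  res2 <- continuous_nri(p_ref, p_new2, time, event, horizon = 10, n_boot = 0)
  expect_equal(res2$nri[["events"]], 100, tolerance = 1e-10)
  expect_equal(res2$nri[["non_events"]], 100, tolerance = 1e-10)
  swap <- continuous_nri(p_new2, p_ref, time, event, horizon = 10, n_boot = 0)
  expect_equal(swap$nri[["total"]], -res2$nri[["total"]], tolerance = 1e-10)
})

test_that("IDI equals the discrimination-slope difference and is antisymmetric", {
  time <- c(1, 2, 11, 11, 11)
  event <- c(1, 1, 0, 0, 0)
  p_ref <- c(0.5, 0.3, 0.2, 0.1, 0.3)
  p_new <- c(0.6, 0.5, 0.1, 0.1, 0.2)
  res <- idi(p_ref, p_new, time, event, horizon = 10, n_boot = 0)
  slope_ref <- mean(c(0.5, 0.3)) - mean(c(0.2, 0.1, 0.3))
  slope_new <- mean(c(0.6, 0.5)) - mean(c(0.1, 0.1, 0.2))
  expect_equal(res$idi, slope_new - slope_ref, tolerance = 1e-10)
  expect_equal(idi(p_ref, p_ref, time, event, n_boot = 0)$idi, 0)
  expect_equal(idi(p_new, p_ref, time, event, n_boot = 0)$idi, -res$idi,
               tolerance = 1e-12)
})

test_that("calibration deciles reduce to bin event fractions when uncensored", {
  set.seed(70)
  n <- 500
  p <- runif(n)
  event <- rbinom(n, 1, p)
  time <- ifelse(event == 1, runif(n, 0, 9), 11)
  tab <- calibration_deciles(p, time, event, horizon = 10, n_bins = 5)
  for (b in seq_len(5)) {
    idx <- rank(p, ties.method = "first") > (b - 1) * n / 5 &
      rank(p, ties.method = "first") <= b * n / 5
    expect_equal(tab$observed[b], mean(event[idx]), tolerance = 1e-10)
  }
  expect_equal(sum(tab$n), n)
  # all-identical risks collapse into stable equal-count bins
  tab2 <- calibration_deciles(rep(0.2, 100), time[1:100], event[1:100],
                              n_bins = 4)
  expect_equal(tab2$n, rep(25, 4))
})

test_that("Spearman matrices are symmetric, unit-diagonal and rank invariant", {
  coh <- generate_cohort(sim_config(
    n_full_cohort = 5000, n_proteins = 4, n_metabolites = 0,
    include_prs = FALSE,
    correlation_spec = data.frame(feature_i = "prot_1", feature_j = "prot_2",
                                  rho = 0.64),
    missingness_rates = numeric(0),
    lod_quantiles = setNames(numeric(0), character(0)), seed = 71))
  d <- coh$data
  d$exp1 <- exp(3 * d$prot_1)
  m <- spearman_matrix(d, c("prot_1", "prot_2", "exp1"))
  expect_equal(diag(m), setNames(rep(1, 3), colnames(m)))
  expect_equal(m, t(m))
  expect_equal(m["prot_1", "exp1"], 1)                 # monotone invariance
  expect_lt(abs(m["prot_1", "prot_2"] - 0.64), 0.05)   # planted strong pair
  expect_error(spearman_matrix(d, "prot_1"), "2 features")
})

test_that("incremental C is null for redundant features and positive for signal", {
  coh <- generate_cohort(planted_config(n = 1200, n_prot = 3, seed = 72,
                                        male_fraction = 0.5))
  d <- coh$data
  # an exact duplicate of a base covariate surfaces the collinearity error
  d$prot_dup <- d$age
  expect_error(incremental_c(d, "prot_dup"), "collinear")
  d$prot_dup <- NULL
  # features independent of the outcome add essentially nothing
  deltas <- vapply(1:8, function(r) {
    dd <- d
    set.seed(400 + r)
    dd$prot_null <- rnorm(nrow(dd))
    incremental_c(dd, "prot_null")$delta_c
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.01)
  # a genuinely informative feature increases C
  inc1 <- incremental_c(d, "prot_1")
  expect_gt(inc1$delta_c, 0)
})
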