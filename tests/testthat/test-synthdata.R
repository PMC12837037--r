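test_that("copula hits planted Spearman targets and stays deterministic", {
  cfg <- sim_config(n_full_cohort = 5000, n_proteins = 12, n_metabolites = 2,
                    seed = 11,
                    correlation_spec = data.frame(
                      feature_i = c("prot_1", "prot_3", "age"),
                      feature_j = c("prot_2", "prot_4", "age_diag"),
                      rho = c(0.64, 0.45, 0.65)),
                    missingness_rates = numeric(0),
                    lod_quantiles = setNames(numeric(0), character(0)))
  coh <- generate_cohort(cfg)
  d <- coh$data
  r1 <- cor(d$prot_1, d$prot_2, method = "spearman")
  expect_gt(r1, 0.59)
  expect_lt(r1, 0.69)
  expect_lt(abs(cor(d$prot_3, d$prot_4, method = "spearman") - 0.45), 0.05)
  expect_lt(abs(cor(d$age, d$age_diag, method = "spearman") - 0.65), 0.05)
  # unspecified pairs stay near zero
  expect_lt(abs(cor(d$prot_5, d$prot_6, method = "spearman")), 0.05)
  # byte-identical regeneration under the same seed
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$data, coh2$data)
  expect_identical(coh$truth, coh2$truth)
})

test_that("non-positive-definite correlation targets are rejected by name", {
  expect_error(
    sim_config(n_proteins = 5, n_metabolites = 0, include_prs = FALSE,
               correlation_spec = data.frame(
                 feature_i = c("prot_1", "prot_1", "prot_2"),
                 feature_j = c("prot_2", "prot_3", "prot_3"),
                 rho = c(0.95, 0.95, -0.95))),
    "positive definite.*prot_1~prot_2")
})

test_that("null-effect configuration reproduces the baseline-implied incidence", {
  eff <- data.frame(feature = "age", beta_male = 0, beta_female = 0)
  cfg <- sim_config(n_full_cohort = 4000, n_proteins = 0, n_metabolites = 0,
                    include_prs = FALSE, true_effects = eff,
                    correlation_spec = NULL,
                    baseline_hazard = list(male = c(shape = 1.2, scale = 40),
                                           female = c(shape = 1.2, scale = 40)),
                    censoring_rate = 0, missingness_rates = numeric(0),
                    lod_quantiles = setNames(numeric(0), character(0)),
                    seed = 5)
  coh <- generate_cohort(cfg)
  implied <- 1 - exp(-(10 / 40)^1.2)
  expect_lt(abs(mean(coh$data$event) - implied), 3 * sqrt(implied / 4000))
  # ground-truth risks agree with the analytic law and are monotone in lp
  expect_true(all(coh$truth$true_10y_risk >= 0 & coh$truth$true_10y_risk <= 1))
})

test_that("defaults emulate the study's case-cohort frame", {
  cfg <- sim_config(seed = 3)
  coh <- generate_cohort(cfg)
  cc <- draw_case_cohort(coh$data, cfg$subcohort_fraction, seed = 4)
  n_sub <- sum(cc$in_subcohort)
  expect_equal(n_sub, round(0.707 * 2364))          # sub-cohort ~1672
  extra <- sum(cc$in_subcohort == 0)                # appended cases ~79
  expect_gt(extra, 40)
  expect_lt(extra, 120)
  expect_gt(nrow(cc), 1650)                         # analysis sample ~1751
  expect_lt(nrow(cc), 1850)
  # ~15.4% 10-year events in the case-cohort analysis sample
  expect_lt(abs(mean(cc$event) - 0.154), 0.02)
  # ~60% male
  expect_lt(abs(mean(coh$data$sex == "M") - 0.597), 0.03)
  expect_equal(attr(cc, "alpha"), n_sub / 2364)
})

test_that("case-cohort draw covers degenerate and deterministic cases", {
  coh <- generate_cohort(planted_config(n = 300, n_prot = 2, seed = 8))
  full <- draw_case_cohort(coh$data, 1, seed = 1)
  expect_equal(nrow(full), nrow(coh$data))
  expect_equal(attr(full, "alpha"), 1)
  s1 <- draw_case_cohort(coh$data, 0.3, seed = 9)
  s2 <- draw_case_cohort(coh$data, 0.3, seed = 9)
  expect_identical(s1$id, s2$id)
  expect_true(all(s1$in_subcohort == 1 | s1$event == 1))
  no_cases <- coh$data
  no_cases$event <- 0
  expect_error(draw_case_cohort(no_cases, 0.3), "no cases")
})

test_that("missingness injection hits target rates and is MAR on age", {
  coh <- generate_cohort(planted_config(n = 5000, n_prot = 2, seed = 12,
                                        male_fraction = 0.5))
  d0 <- coh$data
  # zero rates leave the table untouched
  expect_identical(inject_missingness(d0, c(hdl = 0), seed = 1), d0)
  # HDL at 12% in a 1751-subject sample gives ~210 missing values
  d1751 <- d0[1:1751, ]
  dm <- inject_missingness(d1751, c(hdl = 0.12), "MCAR", seed = 2)
  expect_lt(abs(sum(is.na(dm$hdl)) - 210), 4 * sqrt(1751 * 0.12 * 0.88))
  # MAR masking depends detectably on age
  dmar <- inject_missingness(d0, c(hdl = 0.2), "MAR", seed = 3)
  pval <- t.test(d0$age[is.na(dmar$hdl)], d0$age[!is.na(dmar$hdl)])$p.value
  expect_lt(pval, 0.01)
  expect_lt(abs(mean(is.na(dmar$hdl)) - 0.2), 0.03)
  # outcome and sex are never maskable
  expect_error(inject_missingness(d0, c(sex = 0.1)), "protected")
  expect_error(inject_missingness(d0, c(hdl = 1)), "rates")
})

test_that("an oracle Cox fit on the full cohort recovers the planted effects", {
  reps <- 8
  cover <- matrix(NA, reps, 4)
  for (r in seq_len(reps)) {
    coh <- generate_cohort(planted_config(n = 2000, n_prot = 4, seed = 100 + r))
    d <- coh$data
    X <- as.matrix(d[c("age", "smoking", "sbp", "hba1c", paste0("prot_", 1:4))])
    X[, "age"] <- scale(X[, "age"])  # effects are per SD of the latent scale
    X[, "sbp"] <- scale(X[, "sbp"])
    X[, "hba1c"] <- scale(X[, "hba1c"])
    f <- fit_cox(X, d$time_years, d$event)
    b <- coef(f)[paste0("prot_", 1:4)]
    se <- f$se[paste0("prot_", 1:4)]
    truth <- c(0.45, -0.42, 0.40, 0.40)
    cover[r, ] <- abs(b - truth) <= 1.96 * se
  }
  # 95% CIs cover the planted coefficients at close to nominal rate
  expect_gte(mean(cover), 0.85)
})

test_that("cohort tables round-trip through the delimited format", {
  coh <- generate_cohort(planted_config(n = 120, n_prot = 3, seed = 6))
  cc <- draw_case_cohort(coh$data, 0.5, seed = 2)
  f <- file.path(tempdir(), "cohort.csv")
  write_cohort(cc, f, truth = coh$truth)
  back <- read_cohort(f)
  expect_equal(attr(back, "alpha"), attr(cc, "alpha"))
  expect_equal(back$id, cc$id)
  expect_equal(back$prot_1, cc$prot_1, tolerance = 1e-12)
  expect_true(file.exists(paste0(f, ".truth.json")))
  unlink(c(f, paste0(f, c(".meta.json", ".truth.json"))))
})
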