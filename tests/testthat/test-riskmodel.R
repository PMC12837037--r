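test_that("sex-specific fits nest properly and respect symmetry", {
  coh <- generate_cohort(planted_config(n = 1200, n_prot = 4, seed = 80,
                                        male_fraction = 0.5))
  d <- coh$data
  spec0 <- model_spec()
  spec1 <- model_spec(layers = "proteins",
                      proteins = list(male = paste0("prot_", 1:2),
                                      female = paste0("prot_", 1:2)))
  m0 <- fit_sex_specific(spec0, d)
  m1 <- fit_sex_specific(spec1, d)
  # adding a layer never decreases the in-sample partial likelihood
  expect_gte(m1$male$loglik[["final"]], m0$male$loglik[["final"]] - 1e-10)
  expect_gte(m1$female$loglik[["final"]], m0$female$loglik[["final"]] - 1e-10)
  # duplicated data across sexes yields identical stratum estimates
  dd <- rbind(d, d)
  dd$sex <- rep(c("M", "F"), each = nrow(d))
  md <- fit_sex_specific(spec1, dd)
  expect_equal(coef(md$male), coef(md$female), tolerance = 1e-10)
  expect_error(model_spec(layers = "lipidomics"), "unknown layer")
})

test_that("a male-only planted effect shows up asymmetrically across strata", {
  bigger_m <- 0
  for (r in 1:12) {
    eff <- data.frame(feature = c("age", "prot_1"),
                      beta_male = c(0.35, 0.6), beta_female = c(0.35, 0))
    cfg <- sim_config(n_full_cohort = 1200, male_fraction = 0.5,
                      n_proteins = 1, n_metabolites = 0, include_prs = FALSE,
                      true_effects = eff, correlation_spec = NULL,
                      target_incidence = c(male = 0.2, female = 0.2),
                      missingness_rates = numeric(0),
                      lod_quantiles = setNames(numeric(0), character(0)),
                      seed = 300 + r)
    d <- generate_cohort(cfg)$data
    spec <- model_spec(layers = "proteins",
                       proteins = list(male = "prot_1", female = "prot_1"))
    m <- fit_sex_specific(spec, d)
    bigger_m <- bigger_m +
      (abs(coef(m$male)[["prot_1"]]) > abs(coef(m$female)[["prot_1"]]))
  }
  expect_gte(bigger_m, 11)
})

test_that("pooled risks agree with per-stratum predictions and bound checks", {
  coh <- generate_cohort(planted_config(n = 1000, n_prot = 2, seed = 81,
                                        male_fraction = 0.5))
  d <- coh$data
  spec <- model_spec(layers = "proteins",
                     proteins = list(male = "prot_1", female = "prot_1"))
  m <- fit_sex_specific(spec, d)
  pooled <- pooled_risk(m, d)
  males <- d[d$sex == "M", ]
  expect_equal(pooled[d$sex == "M"], pooled_risk(m, males), tolerance = 1e-12)
  expect_true(all(pooled >= 0 & pooled <= 1))
  # pooled discrimination beats chance and the base model on planted data
  base <- pooled_risk(fit_sex_specific(model_spec(), d), d)
  c_base <- harrell_c(base, d$time_years, d$event)$C
  c_ext <- harrell_c(pooled, d$time_years, d$event)$C
  expect_gt(c_ext, 0.5)
  expect_gt(c_ext, c_base)
  bad <- d
  bad$sex[1] <- "X"
  expect_error(pooled_risk(m, bad), "sex")
})
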