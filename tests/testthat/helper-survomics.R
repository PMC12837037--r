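# Shared fixtures: small survival datasets with known structure, an O(n^2)
# concordance oracle, and compact simulation configurations.

# quick Weibull proportional-hazards fixture (no copula machinery)
gen_surv <- function(n, beta, rate = 0.2, shape = 1.2, cens_max = 10,
                     drop_rate = 0.05, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  lp <- drop(x %*% beta)
  t_ev <- (-log(runif(n)) / (rate * exp(lp)))^(1 / shape)
  cens <- pmin(rexp(n, drop_rate), cens_max)
  list(x = x, time = pmin(t_ev, cens), event = as.integer(t_ev <= cens),
       lp = lp)
}

# independent O(n^2) concordance oracle: pairwise enumeration in plain R
brute_force_c <- function(risk, time, event) {
  n <- length(time)
  conc <- 0
  usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- b <- NULL
      if (time[i] < time[j] && event[i] == 1) { a <- i; b <- j }
      else if (time[j] < time[i] && event[j] == 1) { a <- j; b <- i }
      else if (time[i] == time[j] && event[i] != event[j]) {
        if (event[i] == 1) { a <- i; b <- j } else { a <- j; b <- i }
      }
      if (is.null(a)) next
      usable <- usable + 1
      conc <- conc + if (risk[a] > risk[b]) 1 else if (risk[a] == risk[b]) 0.5 else 0
    }
  }
  list(C = conc / usable, pairs = usable)
}

# compact generator configuration: one sex, planted protein effects, no
# missingness or detection limits unless requested
planted_config <- function(n = 1500, n_prot = 154, betas = c(0.45, -0.42, 0.40, 0.40),
                           incidence = 0.15, seed = 1, male_fraction = 1,
                           missingness = numeric(0)) {
  eff <- data.frame(
    feature = c("age", "smoking", "sbp", "hba1c"),
    beta_male = c(0.3, 0.3, 0.2, 0.2),
    beta_female = c(0.3, 0.3, 0.2, 0.2))
  if (length(betas))
    eff <- rbind(eff, data.frame(feature = paste0("prot_", seq_along(betas)),
                                 beta_male = betas, beta_female = betas))
  sim_config(n_full_cohort = n, male_fraction = male_fraction,
             n_proteins = n_prot, n_metabolites = 0, include_prs = FALSE,
             true_effects = eff,
             correlation_spec = data.frame(feature_i = "age",
                                           feature_j = "age_diag", rho = 0.65),
             target_incidence = c(male = incidence, female = incidence),
             missingness_rates = missingness,
             lod_quantiles = setNames(numeric(0), character(0)),
             seed = seed)
}

# correlated Gaussian fixture for imputation benchmarks
gen_correlated <- function(n = 1000, p = 5, rho = 0.55, seed = 1) {
  set.seed(seed)
  R <- matrix(rho, p, p); diag(R) <- 1
  x <- matrix(rnorm(n * p), n, p) %*% chol(R)
  colnames(x) <- paste0("z", seq_len(p))
  as.data.frame(x)
}
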