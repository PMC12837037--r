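#' Simulation configuration for synthetic T2D cohorts
#'
#' Assembles and validates the parameters of the synthetic-cohort generator.
#' The defaults emulate the structure of a proteomics case-cohort study in
#' people with type 2 diabetes: a full cohort of 2364 subjects of whom 59.7%
#' are male, a randomly drawn sub-cohort of ~70.7% (~1672 subjects) augmented
#' by all out-of-sub-cohort MACE cases (~79, giving an analysis sample of
#' ~1751 with ~15.4% cases), sex-specific 10-year event fractions (13.6%
#' male, 8.2% female in the full cohort), sparse sex-specific protein
#' effects, weak metabolite and polygenic-score effects, and weak cross-layer
#' correlations with one strong within-layer protein pair (Spearman 0.64).
#'
#' Covariates are drawn from a Gaussian copula: every feature has a standard
#' normal latent score; clinical covariates are mapped to natural units
#' (means/SDs of a T2D population aged 40-69) while omics features stay on
#' the standardised latent scale. Pairwise Spearman targets are converted to
#' latent Pearson correlations via rho_P = 2 sin(pi rho_S / 6).
#'
#' @param n_full_cohort Full-cohort size (>= 100).
#' @param male_fraction Proportion of males.
#' @param n_proteins,n_metabolites Number of omics features per layer.
#' @param include_prs Include a single polygenic-score column?
#' @param true_effects Data frame with columns `feature`, `beta_male`,
#'   `beta_female` (log hazard ratios per SD of the latent score; for the
#'   binary smoking indicator, per category). Features absent from the table
#'   have no effect.
#' @param correlation_spec Data frame with columns `feature_i`, `feature_j`,
#'   `rho` of target Spearman rank correlations; unlisted pairs are
#'   uncorrelated on the latent scale.
#' @param baseline_hazard Named list `male`/`female`, each `c(shape=, scale=)`
#'   of the sex-specific Weibull baseline. A scale of `NA` requests
#'   deterministic bisection calibration of the scale so that the expected
#'   observed 10-year event fraction matches `target_incidence`.
#' @param target_incidence Named vector `c(male=, female=)` of target observed
#'   10-year event fractions in the full cohort.
#' @param censoring_rate Yearly exponential dropout hazard (0 disables
#'   dropout; administrative censoring at `horizon` always applies).
#' @param horizon Risk horizon in years.
#' @param subcohort_fraction Sub-cohort sampling fraction for
#'   [draw_case_cohort()].
#' @param multiomics_fraction Fraction of the case-cohort sample with complete
#'   multi-omics data (the nested second-stage cohort).
#' @param missingness_rates Named vector of per-variable missingness
#'   proportions in `[0, 1)` used by [inject_missingness()].
#' @param lod_quantiles Named vector (protein name -> quantile in `[0, 1)`) of
#'   left-censoring points: values below the given quantile of that protein
#'   are set to the detection limit, emulating below-LOD measurements.
#' @param seed Integer seed making generation deterministic.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_full_cohort = 2364,
                       male_fraction = 0.597,
                       n_proteins = 160,
                       n_metabolites = 7,
                       include_prs = TRUE,
                       true_effects = default_true_effects(n_proteins,
                                                           n_metabolites,
                                                           include_prs),
                       correlation_spec = default_correlation_spec(n_proteins,
                                                                   n_metabolites),
                       baseline_hazard = list(male = c(shape = 1.3, scale = NA),
                                              female = c(shape = 1.3, scale = NA)),
                       target_incidence = c(male = 0.136, female = 0.082),
                       censoring_rate = 0.01,
                       horizon = 10,
                       subcohort_fraction = 0.707,
                       multiomics_fraction = 0.565,
                       missingness_rates = default_missingness_rates(n_proteins),
                       lod_quantiles = default_lod_quantiles(n_proteins),
                       seed = 1L) {
  if (n_full_cohort < 100) stop("'n_full_cohort' must be at least 100")
  stopifnot_prob(male_fraction, "male_fraction")
  stopifnot_prob(subcohort_fraction, "subcohort_fraction")
  stopifnot_prob(multiomics_fraction, "multiomics_fraction")
  if (horizon <= 0) stop("'horizon' must be positive")
  if (length(missingness_rates) && any(missingness_rates >= 1))
    stop("missingness rates must be < 1")
  if (length(missingness_rates))
    stopifnot_prob(missingness_rates, "missingness_rates")
  if (censoring_rate < 0) stop("'censoring_rate' must be non-negative")

  cfg <- list(n_full_cohort = as.integer(n_full_cohort),
              male_fraction = male_fraction,
              n_proteins = as.integer(n_proteins),
              n_metabolites = as.integer(n_metabolites),
              include_prs = isTRUE(include_prs),
              true_effects = true_effects,
              correlation_spec = correlation_spec,
              baseline_hazard = baseline_hazard,
              target_incidence = target_incidence,
              censoring_rate = censoring_rate,
              horizon = horizon,
              subcohort_fraction = subcohort_fraction,
              multiomics_fraction = multiomics_fraction,
              missingness_rates = missingness_rates,
              lod_quantiles = lod_quantiles,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"

  # validate the correlation target early so that a bad spec fails loudly
  invisible(latent_correlation(cfg))
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  full cohort: %d (%.1f%% male), horizon %g y\n",
              x$n_full_cohort, 100 * x$male_fraction, x$horizon))
  cat(sprintf("  omics: %d proteins, %d metabolites, PRS: %s\n",
              x$n_proteins, x$n_metabolites, x$include_prs))
  cat(sprintf("  sub-cohort fraction %.3f, multi-omics fraction %.3f\n",
              x$subcohort_fraction, x$multiomics_fraction))
  nz <- x$true_effects[x$true_effects$beta_male != 0 |
                         x$true_effects$beta_female != 0, , drop = FALSE]
  cat(sprintf("  non-null effects: %d features; seed %d\n", nrow(nz), x$seed))
  invisible(x)
}

#' Default true effects for the synthetic generator
#'
#' Clinical covariates carry moderate effects of the sign expected for
#' cardiovascular risk. Protein effects are sparse and sex-specific
#' (8 male-only, 6 female-only, 1 shared), metabolite effects are weak
#' (3 shared, 3 male-only, 1 female-only) and the polygenic score has a weak
#' male-only effect, mirroring the sex asymmetry the analysis is designed to
#' detect.
#'
#' @inheritParams sim_config
#' @return Data frame with columns `feature`, `beta_male`, `beta_female`.
#' @export
default_true_effects <- function(n_proteins = 160, n_metabolites = 7,
                                 include_prs = TRUE) {
  eff <- data.frame(
    feature = c("age", "smoking", "sbp", "tchol", "hdl", "age_diag",
                "hba1c", "egfr"),
    beta_male = c(0.40, 0.35, 0.25, 0.15, -0.20, -0.15, 0.20, -0.15),
    beta_female = c(0.40, 0.35, 0.25, 0.15, -0.20, -0.15, 0.20, -0.15),
    stringsAsFactors = FALSE)

  male_prot <- pmin(8L, max(0L, n_proteins - 7L))
  if (n_proteins >= 15) {
    bm <- c(0.45, 0.42, 0.40, 0.38, 0.35, 0.33, 0.30, 0.28)
    bf <- c(0.45, 0.42, 0.40, 0.36, 0.34, 0.30)
    eff <- rbind(eff, data.frame(
      feature = paste0("prot_", 1:15),
      beta_male = c(bm, rep(0, 6), 0.35),
      beta_female = c(rep(0, 8), bf, 0.35),
      stringsAsFactors = FALSE))
  }
  if (n_metabolites >= 7) {
    eff <- rbind(eff, data.frame(
      feature = paste0("met_", 1:7),
      beta_male = c(0.10, 0.10, 0.10, 0.15, 0.15, 0.15, 0),
      beta_female = c(0.10, 0.10, 0.10, 0, 0, 0, 0.12),
      stringsAsFactors = FALSE))
  }
  if (include_prs)
    eff <- rbind(eff, data.frame(feature = "prs", beta_male = 0.15,
                                 beta_female = 0, stringsAsFactors = FALSE))
  eff
}

#' Default Spearman correlation targets for the synthetic generator
#'
#' Weak cross-layer correlations, one strong within-layer protein pair
#' (rho = 0.64) and a few moderate pairs (<= 0.47), plus natural clinical
#' correlations (age with age at diagnosis, age with SBP).
#'
#' @inheritParams sim_config
#' @return Data frame with columns `feature_i`, `feature_j`, `rho`.
#' @export
default_correlation_spec <- function(n_proteins = 160, n_metabolites = 7) {
  spec <- data.frame(feature_i = c("age", "age", "tchol"),
                     feature_j = c("age_diag", "sbp", "hdl"),
                     rho = c(0.65, 0.20, 0.20),
                     stringsAsFactors = FALSE)
  if (n_proteins >= 10)
    spec <- rbind(spec, data.frame(
      feature_i = c("prot_1", "prot_3", "prot_9"),
      feature_j = c("prot_2", "prot_4", "prot_10"),
      rho = c(0.64, 0.45, 0.40), stringsAsFactors = FALSE))
  if (n_metabolites >= 2 && n_proteins >= 1)
    spec <- rbind(spec, data.frame(
      feature_i = c("met_1", "prot_1"),
      feature_j = c("met_2", "met_4"),
      rho = c(0.45, 0.25), stringsAsFactors = FALSE))
  spec
}

#' Default per-variable missingness rates
#'
#' Clinical rates follow the observed pattern of a UK-style T2D cohort (HDL
#' cholesterol 12.0%, eGFR 6.0%, HbA1c 6.9%, total cholesterol 5.8%, age at
#' diabetes diagnosis 6.6%, smoking 0.8%, SBP 0.3%; age complete). Omics
#' features are mostly complete, with a few proteins up to ~20% missing and
#' one above the QC threshold so that the filter is exercised.
#'
#' @inheritParams sim_config
#' @return Named numeric vector of missingness proportions.
#' @export
default_missingness_rates <- function(n_proteins = 160) {
  rates <- c(hdl = 0.120, egfr = 0.060, hba1c = 0.069, tchol = 0.058,
             age_diag = 0.066, smoking = 0.008, sbp = 0.003)
  if (n_proteins >= 24) {
    # proteins are mostly complete: a handful carry light missingness, a few
    # reach the 10-20% range and one exceeds the QC threshold
    prot <- c(setNames(rep(0.02, 4), paste0("prot_", 1:4)),
              setNames(c(0.10, 0.14, 0.18, 0.19), paste0("prot_", 16:19)),
              prot_20 = 0.22)  # above the 20% QC threshold: dropped at QC
    rates <- c(rates, prot)
  }
  rates
}

#' Default below-LOD left-censoring quantiles
#'
#' A handful of proteins are left-censored at the detection limit; one exceeds
#' the 25% below-LOD QC threshold so that the filter is exercised.
#'
#' @inheritParams sim_config
#' @return Named numeric vector of censoring quantiles.
#' @export
default_lod_quantiles <- function(n_proteins = 160) {
  if (n_proteins < 24) return(setNames(numeric(0), character(0)))
  setNames(c(0.10, 0.15, 0.20, 0.30),
           paste0("prot_", 21:24))  # prot_24 exceeds the 25% threshold
}

# Latent Pearson correlation matrix over all generated features; errors with
# the offending pairs if the target is not positive definite.
latent_correlation <- function(cfg) {
  feats <- c(score2_variables(),
             if (cfg$n_proteins > 0) paste0("prot_", seq_len(cfg$n_proteins)),
             if (cfg$n_metabolites > 0) paste0("met_", seq_len(cfg$n_metabolites)),
             if (cfg$include_prs) "prs")
  d <- length(feats)
  R <- diag(d)
  dimnames(R) <- list(feats, feats)
  spec <- cfg$correlation_spec
  if (!is.null(spec) && nrow(spec)) {
    miss <- setdiff(unique(c(spec$feature_i, spec$feature_j)), feats)
    if (length(miss))
      stop("correlation_spec names unknown features: ",
           paste(miss, collapse = ", "))
    stopifnot_prob(abs(spec$rho), "correlation_spec$rho")
    for (k in seq_len(nrow(spec))) {
      r <- 2 * sin(pi * spec$rho[k] / 6)  # Spearman target -> latent Pearson
      R[spec$feature_i[k], spec$feature_j[k]] <- r
      R[spec$feature_j[k], spec$feature_i[k]] <- r
    }
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    pairs <- if (!is.null(spec) && nrow(spec))
      paste(spec$feature_i, spec$feature_j, sep = "~", collapse = ", ")
    else "(none)"
    stop("correlation target is not positive definite; ",
         "offending specification pairs: ", pairs)
  }
  R
}
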