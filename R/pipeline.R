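#' Configuration of the two-stage multi-omics analysis
#'
#' @param sim A [sim_config()] for synthetic input (ignored when data are
#'   supplied directly to the stage runners).
#' @param B,threshold,n_folds Stability-selection settings (bootstrap
#'   resamples, retention threshold, inner CV folds).
#' @param risk_cuts Absolute-risk category cut-points for the NRI.
#' @param horizon Risk horizon in years.
#' @param n_boot Bootstrap resamples for NRI/IDI confidence intervals.
#' @param p_significant Two-sided significance gate for adding a layer.
#' @param seed Master seed; all stage seeds derive from it.
#' @param output_dir Optional directory for artifacts (CSV/JSON).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(sim = sim_config(), B = 1000L, threshold = 0.95,
                            n_folds = 10L, risk_cuts = c(0.15, 0.30),
                            horizon = 10, n_boot = 200L,
                            p_significant = 0.05, seed = 1L,
                            output_dir = NULL) {
  structure(list(sim = sim, B = as.integer(B), threshold = threshold,
                 n_folds = as.integer(n_folds), risk_cuts = risk_cuts,
                 horizon = horizon, n_boot = as.integer(n_boot),
                 p_significant = p_significant, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "analysis_config")
}

#' Stage 1: QC, imputation and per-sex protein signature selection
#'
#' Runs the first analysis stage on the (larger) proteomics case-cohort
#' sample: omics QC filtering, missForest-style imputation, bootstrap-LASSO
#' stability selection per sex with the clinical base covariates
#' force-included, and the unpenalised refit of each retained signature.
#'
#' @param config An [analysis_config()].
#' @param data Optional prepared `case_cohort` sample; when `NULL` a
#'   synthetic cohort is generated from `config$sim`, sampled into a
#'   case-cohort design and given MAR missingness.
#' @return List of class `stage1_result`: `sample` (imputed analysis table),
#'   `qc_dropped`, `imputation`, `selection` (list `male`/`female`),
#'   `models` (per-sex refits), `signatures`, and `truth` when simulated.
#' @export
run_stage1_selection <- function(config, data = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  truth <- NULL
  if (is.null(data)) {
    sim <- config$sim
    cohort <- generate_cohort(sim)
    truth <- cohort$truth
    cc <- draw_case_cohort(cohort$data, sim$subcohort_fraction,
                           seed = config$seed + 1L)
    data <- inject_missingness(cc, sim$missingness_rates, "MAR",
                               seed = config$seed + 2L)
  }
  qc <- qc_filter_features(data)
  imp <- impute_forest(qc$data, seed = config$seed + 3L)
  sample <- imp$data
  proteins <- omics_columns(sample, "proteins")
  selection <- list()
  models <- list()
  for (s in c(male = "M", female = "F")) {
    key <- names(which(c(male = "M", female = "F") == s))
    sel <- if (length(proteins)) {
      stability_selection(sample, s, features = proteins,
                          B = config$B, threshold = config$threshold,
                          n_folds = config$n_folds,
                          seed = config$seed + 10L + (s == "F"))
    } else {
      # no candidate omics: degrade to the clinical base model
      structure(list(frequency = setNames(numeric(0), character(0)),
                     retained = character(0), B = config$B,
                     threshold = config$threshold, sex = s,
                     seed = config$seed, lambda_min = numeric(0),
                     n_redraws = 0L, adjustment = score2_variables(),
                     stratified = TRUE),
                class = "stability_selection")
    }
    selection[[key]] <- sel
    models[[key]] <- refit_selected(sel, sample)
  }
  structure(list(sample = sample, qc_dropped = qc$dropped,
                 imputation = imp[c("n_iterations", "convergence_trace",
                                    "oob_error")],
                 selection = selection, models = models,
                 signatures = list(male = selection$male$retained,
                                   female = selection$female$retained),
                 truth = truth),
            class = "stage1_result")
}

layer_spec <- function(layers, signatures, data) {
  model_spec(layers = layers,
             proteins = signatures,
             metabolites = omics_columns(data, "metabolites"),
             prs = "prs",
             base = score2_variables())
}

#' Stage 2: sequential omics-layer addition
#'
#' On the complete-multi-omics sample, evaluates each single-layer extension
#' of the clinical base model, adopts the layer with the largest
#' statistically significant gain in Harrell's C as the reference, then
#' greedily adds remaining layers while the correlated-C-index test stays
#' significant (two-sided p < 0.05 by default). The procedure runs
#' separately for the total population and per sex; all models are
#' sex-specific fits, pooled for the total-population metrics. Every
#' comparison also reports categorical/continuous NRI and IDI.
#'
#' @param config An [analysis_config()].
#' @param signatures Named list `male`/`female` of selected protein columns
#'   (e.g. from [run_stage1_selection()]).
#' @param data The stage-2 `case_cohort` sample with all three layers.
#' @return Object of class `layer_report`: `steps` (one row per evaluated
#'   comparison), `sequence` and `stopping_reason` per scope, and the final
#'   fitted models per scope.
#' @export
run_stage2_layering <- function(config, signatures, data) {
  stopifnot(inherits(config, "analysis_config"))
  layers_all <- c("proteins",
                  if (length(omics_columns(data, "metabolites"))) "metabolites",
                  if ("prs" %in% names(data)) "prs")
  fits <- new.env(parent = emptyenv())
  get_fit <- function(layers) {
    key <- if (length(layers)) paste(sort(layers), collapse = "+") else "base"
    if (is.null(fits[[key]]))
      fits[[key]] <- fit_sex_specific(layer_spec(layers, signatures, data),
                                      data)
    fits[[key]]
  }
  risks <- function(layers) pooled_risk(get_fit(layers), data, config$horizon)

  steps <- NULL
  sequence <- list()
  stopping <- list()
  final_layers <- list()
  for (scope in c("overall", "male", "female")) {
    rows <- switch(scope, overall = rep(TRUE, nrow(data)),
                   male = data$sex == "M", female = data$sex == "F")
    tt <- data$time_years[rows]; ee <- data$event[rows]
    current <- character(0)
    seq_added <- character(0)
    reason <- "layers-exhausted"
    step <- 0L
    repeat {
      remaining <- setdiff(layers_all, current)
      if (!length(remaining)) break
      step <- step + 1L
      r_ref <- risks(current)[rows]
      cand <- lapply(remaining, function(l) {
        r_new <- risks(c(current, l))[rows]
        cmp <- compare_c(r_ref, r_new, tt, ee)
        nri_c <- categorical_nri(r_ref, r_new, tt, ee, cuts = config$risk_cuts,
                                 horizon = config$horizon,
                                 n_boot = config$n_boot,
                                 seed = config$seed + 100L)
        nri_f <- continuous_nri(r_ref, r_new, tt, ee,
                                horizon = config$horizon, n_boot = 0)
        id <- idi(r_ref, r_new, tt, ee, horizon = config$horizon, n_boot = 0)
        data.frame(scope = scope, step = step, layer = l,
                   C_ref = cmp$C_ref, C_new = cmp$C_new,
                   delta_c = cmp$delta, p = cmp$p,
                   nri_cat_total = nri_c$nri[["total"]],
                   nri_cat_events = nri_c$nri[["events"]],
                   nri_cat_non_events = nri_c$nri[["non_events"]],
                   nri_continuous = nri_f$nri[["total"]],
                   idi = id$idi, added = FALSE,
                   stringsAsFactors = FALSE)
      })
      cand <- do.call(rbind, cand)
      sig <- which(cand$p < config$p_significant & cand$delta_c > 0)
      if (!length(sig)) {
        reason <- "no-significant-improvement"
        steps <- rbind(steps, cand)
        break
      }
      best <- sig[which.max(cand$delta_c[sig])]
      cand$added[best] <- TRUE
      steps <- rbind(steps, cand)
      current <- c(current, cand$layer[best])
      seq_added <- c(seq_added, cand$layer[best])
    }
    sequence[[scope]] <- seq_added
    stopping[[scope]] <- reason
    final_layers[[scope]] <- current
  }
  structure(list(steps = steps, sequence = sequence,
                 stopping_reason = stopping, final_layers = final_layers,
                 final_models = lapply(final_layers, get_fit)),
            class = "layer_report")
}

#' @export
print.layer_report <- function(x, ...) {
  cat("Sequential omics-layer addition\n")
  for (scope in names(x$sequence)) {
    cat(sprintf("  %-7s: %s (%s)\n", scope,
                if (length(x$sequence[[scope]]))
                  paste(x$sequence[[scope]], collapse = " -> ")
                else "base model retained",
                x$stopping_reason[[scope]]))
  }
  invisible(x)
}

#' Run the full two-stage analysis
#'
#' Simulates (or accepts) a cohort, runs stage-1 protein selection on the
#' proteomics case-cohort sample, draws the nested complete-multi-omics
#' subset, runs the stage-2 sequential layer addition, and computes the
#' descriptive analytics: per-SD hazard ratios of the selected biomarkers,
#' sex-specific Spearman correlation matrices and the decile calibration of
#' the final model. When `config$output_dir` is set, all tables are written
#' as CSV/JSON together with a manifest carrying a hash of the
#' configuration.
#'
#' @param config An [analysis_config()].
#' @return List of class `analysis_result` with elements `stage1`, `stage2`,
#'   `associations`, `correlations`, `calibration`, `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  artifacts <- character(0)
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(obj, name) {
    if (is.null(outdir)) return(invisible(NULL))
    f <- file.path(outdir, name)
    if (grepl("\\.json$", name))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
    else write.csv(obj, f, row.names = FALSE)
    artifacts <<- c(artifacts, f)
  }
  fail <- function(stage, e) {
    if (!is.null(outdir))
      jsonlite::write_json(list(failed_stage = stage, error = conditionMessage(e),
                                artifacts = artifacts),
                           file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  stage1 <- tryCatch(run_stage1_selection(config), error = function(e)
    fail("stage1-selection", e))
  freq <- do.call(rbind, lapply(c("male", "female"), function(s) {
    sel <- stage1$selection[[s]]
    data.frame(feature = names(sel$frequency), sex = s,
               frequency = as.numeric(sel$frequency),
               retained = names(sel$frequency) %in% sel$retained,
               stringsAsFactors = FALSE)
  }))
  emit(freq, "selection_frequencies.csv")
  emit(stage1$qc_dropped, "qc_dropped.csv")
  coefs <- do.call(rbind, lapply(c("male", "female"), function(s) {
    tab <- summary(stage1$models[[s]])$coefficients
    data.frame(sex = s, term = rownames(tab), tab, row.names = NULL)
  }))
  emit(coefs, "stage1_coefficients.csv")

  # nested complete-multi-omics subset with a recomputed sampling fraction
  stage2_data <- tryCatch({
    s1 <- stage1$sample
    set.seed(config$seed + 20L)
    keep <- sort(sample.int(nrow(s1), round(config$sim$multiomics_fraction *
                                              nrow(s1))))
    d2 <- s1[keep, , drop = FALSE]
    a2 <- attr(s1, "alpha") * sum(d2$in_subcohort) / sum(s1$in_subcohort)
    attr(d2, "alpha") <- a2
    attr(d2, "n_full_cohort") <- attr(s1, "n_full_cohort")
    class(d2) <- class(s1)
    d2
  }, error = function(e) fail("stage2-subset", e))

  stage2 <- tryCatch(run_stage2_layering(config, stage1$signatures,
                                         stage2_data),
                     error = function(e) fail("stage2-layering", e))
  emit(stage2$steps, "layer_report.csv")

  associations <- tryCatch({
    rows <- list()
    # a stratum too small for a stable per-SD estimate is skipped, not fatal
    try_hr <- function(data, f, s)
      tryCatch(hazard_ratio_per_sd(data, f, s), error = function(e) NULL)
    for (s in c("M", "F")) {
      key <- if (s == "M") "male" else "female"
      for (f in stage1$signatures[[key]])
        rows[[paste(s, f)]] <- try_hr(stage1$sample, f, s)
      for (f in c(omics_columns(stage2_data, "metabolites"),
                  omics_columns(stage2_data, "prs")))
        rows[[paste(s, f)]] <- try_hr(stage2_data, f, s)
    }
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame()
  }, error = function(e) fail("associations", e))
  emit(associations, "associations_per_sd.csv")

  correlations <- tryCatch({
    lapply(c(male = "M", female = "F"), function(s) {
      key <- if (s == "M") "male" else "female"
      feats <- unique(c(stage1$signatures[[key]],
                        omics_columns(stage2_data, "metabolites"),
                        omics_columns(stage2_data, "prs")))
      if (length(feats) >= 2) spearman_matrix(stage2_data, feats, s) else NULL
    })
  }, error = function(e) fail("correlations", e))
  if (!is.null(correlations$male))
    emit(as.data.frame(correlations$male), "correlation_male.csv")
  if (!is.null(correlations$female))
    emit(as.data.frame(correlations$female), "correlation_female.csv")

  calibration <- tryCatch({
    final <- stage2$final_models$overall
    # assess calibration on the random sub-cohort: it represents the full
    # cohort, whereas the appended outside cases would inflate observed rates
    cal_rows <- if ("in_subcohort" %in% names(stage2_data))
      stage2_data$in_subcohort == 1 else rep(TRUE, nrow(stage2_data))
    d_cal <- stage2_data[cal_rows, , drop = FALSE]
    p <- pooled_risk(final, d_cal, config$horizon)
    calibration_deciles(p, d_cal$time_years, d_cal$event, config$horizon)
  }, error = function(e) fail("calibration", e))
  emit(as.data.frame(calibration), "calibration_deciles.csv")

  hash_cfg <- unclass(config)
  hash_cfg$output_dir <- NULL  # the hash tracks the scientific configuration
  manifest <- list(config_hash = config_hash(hash_cfg),
                   seed = config$seed,
                   n_stage1 = nrow(stage1$sample),
                   n_stage2 = nrow(stage2_data),
                   artifacts = artifacts)
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE)
    artifacts <- c(artifacts, file.path(outdir, "manifest.json"))
  }
  structure(list(stage1 = stage1, stage2 = stage2, stage2_data = stage2_data,
                 associations = associations, correlations = correlations,
                 calibration = calibration, manifest = manifest),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("Two-stage multi-omics risk-model analysis\n")
  cat(sprintf("  stage 1: n = %d; signatures: %d male / %d female proteins\n",
              nrow(x$stage1$sample),
              length(x$stage1$signatures$male),
              length(x$stage1$signatures$female)))
  cat(sprintf("  stage 2: n = %d\n", nrow(x$stage2_data)))
  print(x$stage2)
  invisible(x)
}
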