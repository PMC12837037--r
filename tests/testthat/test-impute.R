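test_that("QC filter drops features beyond the missingness / below-LOD limits", {
  n <- 200
  set.seed(1)
  d <- data.frame(id = 1:n, sex = "M")
  # constructed fractions: 5% / 20% / 21% missing, 26% below LOD, 10% missing
  fr <- c(prot_1 = 0.05, prot_2 = 0.20, prot_3 = 0.21, prot_4 = 0, prot_5 = 0.10)
  for (f in names(fr)) {
    x <- rnorm(n)
    x[seq_len(round(fr[[f]] * n))] <- NA
    d[[f]] <- x
  }
  lod4 <- quantile(d$prot_4, 0.26, names = FALSE)
  d$prot_4 <- pmax(d$prot_4, lod4)
  res <- qc_filter_features(d, paste0("prot_", 1:5), lod = c(prot_4 = lod4))
  expect_setequal(res$dropped$feature, c("prot_3", "prot_4"))
  expect_equal(res$dropped$reason[res$dropped$feature == "prot_3"], "missingness")
  expect_equal(res$dropped$reason[res$dropped$feature == "prot_4"], "below_lod")
  expect_false("prot_3" %in% names(res$data))
  # exactly-at-threshold (20%) and clean features are retained
  expect_true(all(c("prot_1", "prot_2", "prot_5") %in% names(res$data)))
})

test_that("complete data pass through imputation unchanged", {
  d <- gen_correlated(n = 120, seed = 2)
  res <- impute_forest(d, vars = names(d), seed = 1)
  expect_identical(res$data, d)
  expect_equal(res$n_iterations, 0L)
})

test_that("forest imputation never alters observed cells and beats the mean", {
  d0 <- gen_correlated(n = 1000, p = 5, rho = 0.55, seed = 3)
  set.seed(4)
  d <- d0
  mask <- list()
  vars_masked <- c("z2", "z3", "z4", "z5")
  mask[["z1"]] <- rep(FALSE, 1000)
  for (v in vars_masked) {
    m <- runif(1000) < 0.10
    d[[v]][m] <- NA
    mask[[v]] <- m
  }
  res <- impute_forest(d, vars = names(d), seed = 5)
  # observed entries untouched, exactly
  for (v in names(d))
    expect_identical(res$data[[v]][!mask[[v]]], d0[[v]][!mask[[v]]])
  expect_false(anyNA(res$data))
  # NRMSE strictly below mean imputation on the same fixture
  mean_imp <- d
  for (v in names(d)) mean_imp[[v]][mask[[v]]] <- mean(d[[v]], na.rm = TRUE)
  expect_lt(imputation_nrmse(res$data, d0, mask, names(d)),
            imputation_nrmse(mean_imp, d0, mask, names(d)))
  # variable distributions are essentially preserved
  for (v in names(d)) {
    expect_lt(abs(mean(res$data[[v]]) - mean(d0[[v]])) / sd(d0[[v]]), 0.05)
    expect_lt(abs(sd(res$data[[v]]) - sd(d0[[v]])) / sd(d0[[v]]), 0.05)
  }
  # the stopping iteration shows the first increase (or the cap was hit)
  tr <- res$convergence_trace$delta_continuous
  if (nrow(res$convergence_trace) > res$n_iterations)
    expect_gt(tr[length(tr)], tr[length(tr) - 1])
})

test_that("imputation is deterministic and respects binary variables", {
  d0 <- gen_correlated(n = 300, p = 4, rho = 0.5, seed = 6)
  d0$smoke <- as.integer(d0$z1 + rnorm(300, 0, 0.5) > 0)
  d <- d0
  set.seed(7)
  d$z2[runif(300) < 0.15] <- NA
  d$smoke[runif(300) < 0.15] <- NA
  r1 <- impute_forest(d, vars = names(d), seed = 9)
  r2 <- impute_forest(d, vars = names(d), seed = 9)
  expect_identical(r1$data, r2$data)
  expect_true(all(r1$data$smoke %in% c(0L, 1L)))
})

test_that("an entirely missing column is rejected by name", {
  d <- gen_correlated(n = 50, seed = 8)
  d$z3 <- NA_real_
  expect_error(impute_forest(d, vars = names(d), seed = 1), "z3")
})
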