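make_stab_data <- function(n = 400, p = 12, betas = c(0.8, -0.7), seed = 1) {
  d <- gen_surv(n, c(0.3, 0.2, betas, rep(0, p - length(betas))),
                rate = 0.08, seed = seed)
  colnames(d$x) <- c("age", "sbp", paste0("prot_", seq_len(p)))
  out <- data.frame(sex = "M", time_years = d$time, event = d$event, d$x,
                    check.names = FALSE)
  out
}

test_that("B = 1 with threshold 1 returns that single resample's active set", {
  d <- make_stab_data(seed = 2)
  ss <- stability_selection(d, "M", features = paste0("prot_", 1:12),
                            adjustment = c("age", "sbp"), B = 1,
                            threshold = 1, seed = 3)
  expect_setequal(ss$retained, names(ss$frequency)[ss$frequency == 1])
  expect_true(all(ss$frequency %in% c(0, 1)))
})

test_that("the retained set shrinks weakly as the threshold rises", {
  d <- make_stab_data(seed = 4)
  ss <- stability_selection(d, "M", features = paste0("prot_", 1:12),
                            adjustment = c("age", "sbp"), B = 8,
                            threshold = 0.5, seed = 5)
  for (thr in c(0.6, 0.8, 1)) {
    retained_thr <- names(ss$frequency)[ss$frequency >= thr]
    expect_true(all(retained_thr %in% ss$retained))
  }
})

test_that("the whole bootstrap loop is seed deterministic", {
  d <- make_stab_data(seed = 6)
  s1 <- stability_selection(d, "M", features = paste0("prot_", 1:12),
                            adjustment = c("age", "sbp"), B = 3, seed = 11)
  s2 <- stability_selection(d, "M", features = paste0("prot_", 1:12),
                            adjustment = c("age", "sbp"), B = 3, seed = 11)
  expect_identical(s1$frequency, s2$frequency)
  expect_identical(s1$lambda_min, s2$lambda_min)
})

test_that("refitting an empty retained set returns the base model", {
  d <- make_stab_data(seed = 7)
  ss <- stability_selection(d, "M", features = paste0("prot_", 1:12),
                            adjustment = c("age", "sbp"), B = 2, seed = 8)
  ss$retained <- character(0)
  refit <- refit_selected(ss, d)
  base <- fit_cox(as.matrix(d[c("age", "sbp")]), d$time_years, d$event)
  expect_equal(coef(refit), coef(base), tolerance = 1e-12)
  # a retained feature collinear with a base covariate surfaces the error
  d$prot_1 <- d$age
  ss$retained <- "prot_1"
  expect_error(refit_selected(ss, d), "collinear")
})
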