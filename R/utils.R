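#' The clinical base-model covariates
#'
#' Column names of the eight clinical covariates used by the base 10-year
#' risk model (sex is handled by stratification, not as a covariate):
#' age, current smoking status, systolic blood pressure, total cholesterol,
#' HDL cholesterol, age at diabetes diagnosis, HbA1c and eGFR.
#'
#' @return Character vector of column names.
#' @export
score2_variables <- function() {
  c("age", "smoking", "sbp", "tchol", "hdl", "age_diag", "hba1c", "egfr")
}

#' Omics columns of a cohort table
#'
#' @param data A cohort data frame.
#' @param layers Which layers to return: any of `"proteins"`,
#'   `"metabolites"`, `"prs"`.
#' @return Character vector of matching column names (in table order).
#' @export
omics_columns <- function(data, layers = c("proteins", "metabolites", "prs")) {
  nm <- names(data)
  out <- character(0)
  if ("proteins" %in% layers) out <- c(out, grep("^prot_", nm, value = TRUE))
  if ("metabolites" %in% layers) out <- c(out, grep("^met_", nm, value = TRUE))
  if ("prs" %in% layers && "prs" %in% nm) out <- c(out, "prs")
  out
}

weighted_mean_sd <- function(x, w) {
  ok <- !is.na(x) & w > 0
  x <- x[ok]; w <- w[ok]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_))
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  c(mean = m, sd = sqrt(v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the canonical JSON serialisation; used for output manifests
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

# solve f(x) = target on [lo, hi] for monotone f; deterministic bisection
bisect <- function(f, target, lo, hi, tol = 1e-8, max_iter = 200) {
  flo <- f(lo) - target
  fhi <- f(hi) - target
  if (flo * fhi > 0) stop("bisection bracket does not contain the target")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid) - target
    if (abs(fm) < tol || (hi - lo) < tol * max(1, abs(mid))) return(mid)
    if (fm * flo > 0) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

stopifnot_prob <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
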