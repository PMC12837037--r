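#' Inject missing values into a cohort table
#'
#' Masks entries of the named variables at the given per-variable rates,
#' either completely at random (MCAR) or at random given fully observed
#' variables (MAR: the masking probability depends on age and sex through a
#' logistic model whose intercept is calibrated by bisection so that the
#' expected masking rate equals the target). Outcome columns (`time_years`,
#' `event`), `sex`, `id` and case-cohort flags are never masked.
#'
#' @param data Cohort data frame.
#' @param rates Named vector of target missingness proportions in `[0, 1)`.
#' @param mechanism `"MAR"` (default) or `"MCAR"`.
#' @param seed Integer seed.
#' @return The data frame with `NA`s injected (attributes preserved).
#' @export
inject_missingness <- function(data, rates, mechanism = c("MAR", "MCAR"),
                               seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!length(rates)) return(data)
  if (any(rates >= 1) || any(rates < 0))
    stop("missingness rates must lie in [0, 1)")
  protected <- c("id", "sex", "time_years", "event", "in_subcohort",
                 "multiomics")
  bad <- intersect(names(rates), protected)
  if (length(bad))
    stop("refusing to mask protected columns: ", paste(bad, collapse = ", "))
  vars <- intersect(names(rates), names(data))
  set.seed(as.integer(seed))
  n <- nrow(data)
  # MAR driver: standardised age and sex, fully observed by construction
  drv <- if (mechanism == "MAR")
    0.8 * as.numeric(scale(data$age)) + 0.4 * (data$sex == "M") else rep(0, n)
  for (v in vars) {
    r <- rates[[v]]
    if (r == 0) next
    if (mechanism == "MCAR") {
      p <- rep(r, n)
    } else {
      b0 <- bisect(function(b) mean(plogis(b + drv)), r, -20, 20, tol = 1e-10)
      p <- plogis(b0 + drv)
    }
    data[[v]][runif(n) < p] <- NA
  }
  data
}
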