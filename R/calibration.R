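#' Decile calibration table
#'
#' Splits subjects into equal-count bins of predicted absolute risk and
#' contrasts the mean predicted risk per bin with the observed event rate
#' (1 minus the Kaplan-Meier survival at the horizon within the bin). With
#' fully observed follow-up the observed rate equals the bin's event
#' fraction. Ties in predicted risk are broken stably by subject order, so
#' degenerate inputs (all-identical risks) collapse to one effective bin.
#'
#' @param p Predicted absolute risks.
#' @param time,event Outcome.
#' @param horizon Risk horizon in years.
#' @param n_bins Number of bins (default 10).
#' @return Data frame of class `calibration_table`: `bin`, `n`,
#'   `mean_predicted`, `observed` per bin.
#' @export
calibration_deciles <- function(p, time, event, horizon = 10, n_bins = 10L) {
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  n <- length(p)
  ord <- order(p, seq_len(n))  # stable tie-break
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  bin <- pmin(bin, n_bins)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(bin = b, n = sum(idx),
               mean_predicted = mean(p[idx]),
               observed = km_event_prob(time, event, horizon, idx))
  }))
  rownames(out) <- NULL
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' @export
plot.calibration_table <- function(x, ...) {
  lim <- range(0, x$mean_predicted, x$observed, na.rm = TRUE)
  plot(x$mean_predicted, x$observed, xlim = lim, ylim = lim,
       xlab = "mean predicted risk", ylab = "observed event rate (KM)",
       main = "Calibration by risk decile", pch = 19, ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Spearman correlation matrix of selected biomarkers
#'
#' Pairwise Spearman rank correlations (complete pairs) among the given
#' features, optionally within one sex stratum; the standard redundancy
#' check for a selected multi-omics signature.
#'
#' @param data Cohort data frame.
#' @param features Feature columns (at least 2).
#' @param sex Optional stratum (`"M"`/`"F"`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(data, features, sex = NULL) {
  if (length(features) < 2) stop("at least 2 features are required")
  d <- if (is.null(sex)) data else data[data$sex == sex, , drop = FALSE]
  m <- cor(as.matrix(d[features]), method = "spearman",
           use = "pairwise.complete.obs")
  diag(m) <- 1
  m
}
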