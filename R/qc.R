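#' QC filter for omics features
#'
#' Removes features with more than `max_missing` missing values or with more
#' than `max_below_lod` of observed values at or below the detection limit,
#' the standard pre-selection filter for affinity proteomics panels.
#'
#' @param data Cohort data frame.
#' @param features Candidate feature columns (default: all omics columns).
#' @param max_missing Maximum tolerated missing fraction (default 0.20);
#'   features *strictly above* the threshold are dropped.
#' @param max_below_lod Maximum tolerated below-detection-limit fraction
#'   (default 0.25), assessed among observed values.
#' @param lod Named vector of per-feature detection limits (default: the
#'   `lod` attribute written by the generator; features without a recorded
#'   limit are treated as fully quantified).
#' @return List with `data` (filtered table, attributes preserved) and
#'   `dropped` (data frame: `feature`, `frac_missing`, `frac_below_lod`,
#'   `reason`).
#' @export
qc_filter_features <- function(data, features = omics_columns(data),
                               max_missing = 0.20, max_below_lod = 0.25,
                               lod = attr(data, "lod")) {
  if (max_missing <= 0 || max_missing >= 1 || max_below_lod <= 0 ||
      max_below_lod >= 1)
    stop("QC thresholds must lie in (0, 1)")
  drops <- data.frame(feature = character(0), frac_missing = numeric(0),
                      frac_below_lod = numeric(0), reason = character(0),
                      stringsAsFactors = FALSE)
  for (f in features) {
    x <- data[[f]]
    fm <- mean(is.na(x))
    fl <- if (!is.null(lod) && f %in% names(lod) && is.finite(lod[[f]]))
      mean(x[!is.na(x)] <= lod[[f]]) else 0
    reason <- c(if (fm > max_missing) "missingness",
                if (fl > max_below_lod) "below_lod")
    if (length(reason))
      drops <- rbind(drops, data.frame(feature = f, frac_missing = fm,
                                       frac_below_lod = fl,
                                       reason = paste(reason, collapse = "+"),
                                       stringsAsFactors = FALSE))
  }
  if (nrow(drops)) {
    at <- attributes(data)
    data <- data[, setdiff(names(data), drops$feature), drop = FALSE]
    for (a in c("alpha", "n_full_cohort", "class"))
      if (!is.null(at[[a]])) attr(data, a) <- at[[a]]
    if (!is.null(at$lod))
      attr(data, "lod") <- at$lod[setdiff(names(at$lod), drops$feature)]
  }
  list(data = data, dropped = drops)
}
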