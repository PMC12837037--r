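#' Write / read a cohort table
#'
#' The on-disk format is a plain delimited table with one row per subject:
#' `id`, `sex` (`M`/`F`), `time_years`, `event` (0/1), optional
#' `in_subcohort` (0/1), the clinical covariates, then layer-prefixed omics
#' columns (`prot_*`, `met_*`, `prs`). Ground truth (when available) is
#' written to a JSON sidecar next to the table.
#'
#' @param data Cohort data frame (possibly a `case_cohort`).
#' @param file Path to the CSV/TSV file; `.tsv` extension selects tabs.
#' @param truth Optional ground-truth list (as in [generate_cohort()]),
#'   written to `<file>.truth.json`.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(data, file, truth = NULL) {
  sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  meta <- list(alpha = attr(data, "alpha"),
               n_full_cohort = attr(data, "n_full_cohort"),
               lod = as.list(attr(data, "lod")))
  utils::write.table(as.data.frame(data), file, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  meta_file <- paste0(file, ".meta.json")
  jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(truth)) {
    tr <- truth
    tr$true_beta <- as.data.frame(tr$true_beta)
    tr$true_beta$feature <- rownames(truth$true_beta)
    jsonlite::write_json(tr, paste0(file, ".truth.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  data <- utils::read.table(file, sep = sep, header = TRUE, na.strings = "",
                            stringsAsFactors = FALSE)
  meta_file <- paste0(file, ".meta.json")
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    attr(data, "alpha") <- meta$alpha
    attr(data, "n_full_cohort") <- meta$n_full_cohort
    if (length(meta$lod)) attr(data, "lod") <- unlist(meta$lod)
    if (!is.null(meta$alpha) && "in_subcohort" %in% names(data))
      class(data) <- c("case_cohort", "data.frame")
  }
  data
}
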