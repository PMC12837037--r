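#' Draw a case-cohort sample from a full cohort
#'
#' Draws a simple random sub-cohort of the given fraction and appends every
#' case (event) that falls outside it, mirroring a case-cohort design with
#' expensive assays measured only on the sampled subjects. The realised
#' sampling fraction `alpha` (sub-cohort size over full-cohort size) is
#' recorded for Barlow weighting.
#'
#' @param data Full-cohort data frame with `event` column.
#' @param subcohort_fraction Sub-cohort sampling fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return A data frame of class `case_cohort` containing the retained
#'   subjects with an `in_subcohort` column and attributes `alpha`,
#'   `n_full_cohort` (and `lod`, carried through).
#' @export
draw_case_cohort <- function(data, subcohort_fraction, seed = 1L) {
  if (subcohort_fraction <= 0 || subcohort_fraction > 1)
    stop("'subcohort_fraction' must lie in (0, 1]")
  if (!any(data$event == 1))
    stop("no cases in the cohort: the case-cohort design is undefined")
  n <- nrow(data)
  set.seed(as.integer(seed))
  m <- round(subcohort_fraction * n)
  sub <- sort(sample.int(n, m))
  in_sub <- logical(n)
  in_sub[sub] <- TRUE
  keep <- in_sub | data$event == 1
  lod <- attr(data, "lod")
  out <- data[keep, , drop = FALSE]
  out$in_subcohort <- as.integer(in_sub[keep])
  rownames(out) <- NULL
  structure(out, alpha = m / n, n_full_cohort = n, lod = lod,
            class = c("case_cohort", "data.frame"))
}

#' Barlow inverse-probability weights for a case-cohort sample
#'
#' Under Barlow weighting, non-case sub-cohort members carry weight `1/alpha`
#' while at risk; cases carry weight `1/alpha` before their event if they are
#' in the sub-cohort (0 otherwise, i.e. they enter the risk set only at
#' failure) and weight 1 at their own event time. With `alpha = 1` every
#' weight is 1 and the weighted fit equals the full-cohort fit.
#'
#' @param in_subcohort Logical/0-1 vector of sub-cohort membership.
#' @param event 0-1 event indicator.
#' @param alpha Sampling fraction in `(0, 1]`.
#' @return Data frame with per-subject `pre_weight` (while at risk before the
#'   event) and `event_weight` (at the subject's own event time; `NA` for
#'   non-cases).
#' @export
barlow_weights <- function(in_subcohort, event, alpha) {
  if (is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]")
  in_subcohort <- as.logical(in_subcohort)
  event <- as.integer(event)
  if (any(!in_subcohort & event == 0))
    stop("every retained subject must be in the sub-cohort or be a case")
  data.frame(pre_weight = ifelse(in_subcohort, 1 / alpha, 0),
             event_weight = ifelse(event == 1, 1, NA_real_))
}

# Expand a case-cohort sample into weighted counting-process rows
# (start, stop] for the Breslow partial likelihood:
#   - non-case sub-cohort member: (0, T] with weight 1/alpha
#   - sub-cohort case: (0, T-eps] weight 1/alpha, plus (T-eps, T] weight 1
#   - outside-sub-cohort case: (T-eps, T] weight 1 (at risk only at failure)
# eps is half the smallest gap between distinct observed times (capped at
# T/2), so no other event time falls inside the (T-eps, T) window.
cc_expand <- function(x, time, event, in_subcohort = NULL, alpha = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(in_subcohort)) {
    return(list(x = x, start = rep(0, n), stop = time,
                status = as.integer(event), w = rep(1, n), id = seq_len(n)))
  }
  if (is.null(alpha)) stop("'alpha' is required with 'in_subcohort'")
  bw <- barlow_weights(in_subcohort, event, alpha)
  ut <- sort(unique(time))
  eps <- if (length(ut) > 1) min(diff(ut)) / 2 else ut[1] / 2
  eps_i <- pmin(eps, time / 2)

  in_sub <- as.logical(in_subcohort)
  case <- event == 1
  idx <- integer(0); start <- numeric(0); stop_ <- numeric(0)
  status <- integer(0); w <- numeric(0)
  # pre-event exposure for sub-cohort members
  pre <- which(in_sub)
  pre_stop <- ifelse(case[pre], time[pre] - eps_i[pre], time[pre])
  ok <- pre_stop > 0
  idx <- c(idx, pre[ok]); start <- c(start, rep(0, sum(ok)))
  stop_ <- c(stop_, pre_stop[ok]); status <- c(status, rep(0L, sum(ok)))
  w <- c(w, bw$pre_weight[pre][ok])
  # at-event rows for all cases
  ev <- which(case)
  idx <- c(idx, ev); start <- c(start, time[ev] - eps_i[ev])
  stop_ <- c(stop_, time[ev]); status <- c(status, rep(1L, length(ev)))
  w <- c(w, bw$event_weight[ev])
  list(x = x[idx, , drop = FALSE], start = start, stop = stop_,
       status = status, w = w, id = idx)
}
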