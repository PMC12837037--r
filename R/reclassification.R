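# Kaplan-Meier event probability by `horizon` within a subset; NA when the
# subset is empty. Used to handle censoring in reclassification metrics.
km_event_prob <- function(time, event, horizon, subset = NULL) {
  if (!is.null(subset)) {
    time <- time[subset]; event <- event[subset]
  }
  if (!length(time)) return(NA_real_)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(sf, times = horizon, extend = TRUE)$surv
  1 - s
}

nri_components <- function(up, down, time, event, horizon) {
  n <- length(time)
  p_ev <- km_event_prob(time, event, horizon)
  p_up_ev <- km_event_prob(time, event, horizon, up)
  p_down_ev <- km_event_prob(time, event, horizon, down)
  f_up <- mean(up); f_down <- mean(down)
  # P(up & event) etc. via subgroup KM; empty categories contribute 0
  up_ev <- if (is.na(p_up_ev)) 0 else f_up * p_up_ev
  down_ev <- if (is.na(p_down_ev)) 0 else f_down * p_down_ev
  up_ne <- if (is.na(p_up_ev)) 0 else f_up * (1 - p_up_ev)
  down_ne <- if (is.na(p_down_ev)) 0 else f_down * (1 - p_down_ev)
  nri_e <- (up_ev - down_ev) / p_ev
  nri_ne <- (down_ne - up_ne) / (1 - p_ev)
  c(events = nri_e, non_events = nri_ne, total = nri_e + nri_ne)
}

boot_ci <- function(stat, n, n_boot, seed, conf_level) {
  if (n_boot <= 0) return(c(NA_real_, NA_real_))
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    stat(idx)
  }, numeric(1))
  a <- (1 - conf_level) / 2
  unname(quantile(reps, c(a, 1 - a), na.rm = TRUE))
}

#' Categorical net reclassification improvement
#'
#' NRI between two risk models over predefined absolute-risk categories
#' (default 0-15%, >15-30%, >30%). Event status by the horizon is estimated
#' with Kaplan-Meier weighting within reclassification groups, so censored
#' follow-up is handled; on fully observed data the estimates reduce to
#' plain proportions. `NRI_events = P(up|event) - P(down|event)`; for
#' non-events the signs are reversed; the total is their sum. Percentile
#' bootstrap confidence intervals.
#'
#' @param p_ref,p_new Predicted absolute risks under the reference and new
#'   model (same subjects, same order).
#' @param time,event Outcome.
#' @param cuts Strictly increasing category cut-points in (0, 1)
#'   (default `c(0.15, 0.30)`).
#' @param horizon Risk horizon in years.
#' @param n_boot Bootstrap resamples for the CI (0 disables).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return Object of class `nri_result` with `nri` (events, non_events,
#'   total, each in percent), `ci` (percent), counts of up/down moves.
#' @export
categorical_nri <- function(p_ref, p_new, time, event, cuts = c(0.15, 0.30),
                            horizon = 10, n_boot = 1000L, seed = 1L,
                            conf_level = 0.95) {
  if (any(diff(cuts) <= 0) || any(cuts <= 0) || any(cuts >= 1))
    stop("'cuts' must be strictly increasing risk proportions in (0, 1)")
  if (!sum(event)) stop("no events")
  cat_ref <- findInterval(p_ref, cuts)
  cat_new <- findInterval(p_new, cuts)
  up <- cat_new > cat_ref
  down <- cat_new < cat_ref
  est <- nri_components(up, down, time, event, horizon)
  ci <- rbind(
    events = boot_ci(function(i) nri_components(up[i], down[i], time[i],
                                                event[i], horizon)[["events"]],
                     length(time), n_boot, seed, conf_level),
    non_events = boot_ci(function(i) nri_components(up[i], down[i], time[i],
                                                    event[i], horizon)[["non_events"]],
                         length(time), n_boot, seed, conf_level),
    total = boot_ci(function(i) nri_components(up[i], down[i], time[i],
                                               event[i], horizon)[["total"]],
                    length(time), n_boot, seed, conf_level))
  structure(list(nri = 100 * est, ci = 100 * ci, cuts = cuts,
                 n_up = sum(up), n_down = sum(down), horizon = horizon,
                 type = "categorical"),
            class = "nri_result")
}

#' Continuous (category-free) net reclassification improvement
#'
#' As [categorical_nri()] but any increase/decrease in predicted risk counts
#' as an up/down move (NRI > 0).
#'
#' @inheritParams categorical_nri
#' @return Object of class `nri_result` (percent scale).
#' @export
continuous_nri <- function(p_ref, p_new, time, event, horizon = 10,
                           n_boot = 1000L, seed = 1L, conf_level = 0.95) {
  if (!sum(event)) stop("no events")
  up <- p_new > p_ref
  down <- p_new < p_ref
  est <- nri_components(up, down, time, event, horizon)
  ci <- rbind(total = boot_ci(function(i)
    nri_components(up[i], down[i], time[i], event[i], horizon)[["total"]],
    length(time), n_boot, seed, conf_level))
  structure(list(nri = 100 * est, ci = 100 * ci, cuts = NULL,
                 n_up = sum(up), n_down = sum(down), horizon = horizon,
                 type = "continuous"),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("%s NRI at %g years\n",
              if (x$type == "categorical") "Categorical" else "Continuous",
              x$horizon))
  for (k in names(x$nri)) {
    ci <- x$ci[sub("non_events", "non_events", k), ]
    if (k %in% rownames(x$ci) && all(is.finite(x$ci[k, ])))
      cat(sprintf("  %-11s %6.1f%% (%.1f, %.1f)\n", k, x$nri[[k]],
                  x$ci[k, 1], x$ci[k, 2]))
    else
      cat(sprintf("  %-11s %6.1f%%\n", k, x$nri[[k]]))
  }
  invisible(x)
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slope between two models:
#' `(mean p_new - mean p_old | events) - (mean p_new - mean p_old | non-events)`,
#' with event/non-event means estimated under censoring by inverse
#' probability-of-censoring weighting at the horizon (subjects censored
#' before the horizon without an event drop out; the weights use the
#' Kaplan-Meier censoring distribution). On fully observed data this reduces
#' to plain subgroup means. Percentile bootstrap CI.
#'
#' @inheritParams categorical_nri
#' @return List of class `idi_result`: `idi`, `ci`,
#'   `slope_ref`, `slope_new`.
#' @export
idi <- function(p_ref, p_new, time, event, horizon = 10, n_boot = 1000L,
                seed = 1L, conf_level = 0.95) {
  if (!sum(event)) stop("no events")
  point <- function(i) {
    idi_point(p_ref[i], p_new[i], time[i], event[i], horizon)
  }
  est <- point(seq_along(time))
  ci <- boot_ci(function(i) point(i)[["idi"]], length(time), n_boot, seed,
                conf_level)
  structure(list(idi = est[["idi"]], ci = ci,
                 slope_ref = est[["slope_ref"]],
                 slope_new = est[["slope_new"]], horizon = horizon),
            class = "idi_result")
}

idi_point <- function(p_ref, p_new, time, event, horizon) {
  # IPCW weights at the horizon from the censoring Kaplan-Meier
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(t) {
    # right-continuous censoring survival, evaluated just before t
    s <- approx(c(0, cens_fit$time), c(1, cens_fit$surv),
                xout = pmax(t * (1 - 1e-12), 0), method = "constant",
                f = 0, rule = 2)$y
    pmax(s, 1e-10)
  }
  is_event <- event == 1 & time <= horizon
  is_nonev <- time > horizon | (time >= horizon & event == 0)
  w <- numeric(length(time))
  if (any(is_event)) w[is_event] <- 1 / G(time[is_event])
  if (any(is_nonev)) w[is_nonev] <- 1 / G(rep(horizon, sum(is_nonev)))
  m <- function(p, grp) if (any(grp)) sum(w[grp] * p[grp]) / sum(w[grp]) else 0
  slope_ref <- m(p_ref, is_event) - m(p_ref, is_nonev)
  slope_new <- m(p_new, is_event) - m(p_new, is_nonev)
  c(idi = slope_new - slope_ref, slope_ref = slope_ref,
    slope_new = slope_new)
}

#' @export
print.idi_result <- function(x, ...) {
  cat(sprintf("IDI at %g years: %.4f", x$horizon, x$idi))
  if (all(is.finite(x$ci))) cat(sprintf(" (%.4f, %.4f)", x$ci[1], x$ci[2]))
  cat(sprintf("\n  discrimination slope: %.4f (reference) -> %.4f (new)\n",
              x$slope_ref, x$slope_new))
  invisible(x)
}
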