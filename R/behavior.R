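# Reaction-time processing and event-behaviour linkage.

#' Apply reaction-time validity rules
#'
#' A trial is valid iff `100 <= rt_ms <= 500`: faster responses are
#' anticipated movements (false starts), slower ones outliers. Exclusion
#' counts are attached as attributes `n_false_start` and `n_outlier`.
#'
#' @param trials Trial data frame with an `rt_ms` column.
#' @return The trials with the `valid` flag set.
#' @export
filter_rts <- function(trials) {
  check_columns(trials, "rt_ms", "trials")
  if (any(is.na(trials$rt_ms))) stopf("rt_ms contains missing values")
  trials$valid <- trials$rt_ms >= 100 & trials$rt_ms <= 500
  attr(trials, "n_false_start") <- sum(trials$rt_ms < 100)
  attr(trials, "n_outlier") <- sum(trials$rt_ms > 500)
  trials
}

#' Pooled median reaction time over valid trials
#'
#' @param sessions List of trial data frames (with `valid` set).
#' @return Median `rt_ms` over all valid trials pooled across sessions.
#' @export
pooled_median_rt <- function(sessions) {
  rts <- unlist(lapply(sessions, function(tr) tr$rt_ms[tr$valid %in% TRUE]))
  if (length(rts) == 0) stopf("no valid trials")
  median(rts)
}

#' Per-session percentage of reaction times above a pooled median
#'
#' @param sessions Named list of trial data frames (with `valid` set).
#' @param global_median Median computed over all valid trials pooled across
#'   sessions (see [pooled_median_rt()]).
#' @return Named numeric vector: per session, `100 * #\{valid rt >
#'   median\} / #valid` (strictly above; ties count as not above). Sessions
#'   without valid trials are dropped with a warning.
#' @export
percent_above_median <- function(sessions, global_median) {
  out <- vapply(sessions, function(tr) {
    v <- tr$rt_ms[tr$valid %in% TRUE]
    if (length(v) == 0) return(NA_real_)
    100 * sum(v > global_median) / length(v)
  }, 0)
  if (anyNA(out)) {
    warnf("session(s) with no valid trials excluded: %s",
          paste(names(out)[is.na(out)], collapse = ", "))
    out <- out[!is.na(out)]
  }
  out
}

#' Summarise detected events around each stimulus
#'
#' Window `[stim - 0.25 s, stim + 0.5 s)` (half-open: an event exactly at
#' `stim - 0.25` is included, one exactly at `stim + 0.5` is not),
#' covering motor planning through the maximal reaction time.
#'
#' @param events Event data frame (needs `t_neg_s`, `globality_pct`).
#' @param trials Trial data frame (needs `stim_time_s`), sharing the
#'   events' time base.
#' @return Data frame aligned with `trials`: `trial_id`, `n_events`,
#'   `max_globality`, `mean_globality` (0 when eventless) and an
#'   `eventless` flag.
#' @export
events_near_stimulus <- function(events, trials) {
  check_columns(trials, "stim_time_s", "trials")
  res <- lapply(seq_len(nrow(trials)), function(i) {
    s0 <- trials$stim_time_s[i]
    sel <- events$t_neg_s >= s0 - 0.25 & events$t_neg_s < s0 + 0.5
    g <- events$globality_pct[sel]
    data.frame(n_events = sum(sel),
               max_globality = if (length(g)) max(g) else 0,
               mean_globality = if (length(g)) mean(g) else 0,
               eventless = !any(sel))
  })
  out <- do.call(rbind, res)
  cbind(trial_id = trials$trial_id, out)
}

#' Linear regression of reaction time on event globality
#'
#' Ordinary least squares of valid-trial reaction times on the per-trial
#' event globality (maximum in the peristimulus window), with the adjusted
#' R-squared and the F test of zero slope.
#'
#' @param summaries Output of [events_near_stimulus()] (or any data frame
#'   with a `max_globality` column aligned with `trials`).
#' @param trials Trial data frame with `valid` set; at least 10 valid trials.
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r2_adj`, `F`, `df` (= n - 2), `p`, `n`.
#' @export
regress_rt_on_globality <- function(summaries, trials) {
  stopifnot(nrow(summaries) == nrow(trials))
  keep <- trials$valid %in% TRUE
  if (sum(keep) < 10) stopf("need >= 10 valid trials (got %d)", sum(keep))
  g <- summaries$max_globality[keep]
  rt <- trials$rt_ms[keep]
  if (var(g) == 0) stopf("zero variance in the globality predictor")
  fit <- lm(rt ~ g)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2_adj = sm$adj.r.squared, F = fstat[1],
                 df = unname(fstat[3]),
                 p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
                 n = length(rt)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression> slope %.3f ms/%%, adj R2 %.3f, F(1,%d) = %.2f, p = %.3g (n = %d)\n",
    x$slope, x$r2_adj, x$df, x$F, x$p, x$n))
  invisible(x)
}
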