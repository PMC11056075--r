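#' Log odds ratio from a 2x2 table
#'
#' Computes the log odds ratio and its large-sample standard error from arm
#' counts, with the usual continuity correction for zero cells: if any of the
#' four cells (events / non-events per arm) is zero, `correction` is added to
#' all four cells; otherwise the table is used as is.  The correction is never
#' applied selectively to single cells.
#'
#' @param events_treat,total_treat events and sample size in the treatment arm.
#' @param events_ctrl,total_ctrl events and sample size in the control arm.
#' @param correction non-negative continuity correction (default 0.5, the
#'   RevMan/metan convention).
#' @return A list with components `y` (log OR) and `se`.
#' @examples
#' log_odds_ratio(10, 20, 10, 20)  # symmetric table: y = 0
#' @export
log_odds_ratio <- function(events_treat, total_treat, events_ctrl, total_ctrl,
                           correction = 0.5) {
  check_counts(events_treat, total_treat, events_ctrl, total_ctrl, correction)
  a <- events_treat
  b <- total_treat - events_treat
  c <- events_ctrl
  d <- total_ctrl - events_ctrl
  if ((a == 0 && c == 0) || (b == 0 && d == 0))
    stop_incomputable("2x2 table is degenerate (both arms all-events or all-non-events)")
  if (any(c(a, b, c, d) == 0)) {
    if (correction == 0)
      stop_incomputable("zero cell with continuity correction 0")
    a <- a + correction; b <- b + correction
    c <- c + correction; d <- d + correction
  }
  list(y = log(a * d / (b * c)), se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

#' Log risk ratio from a 2x2 table
#'
#' Computes the log risk ratio and its standard error.  If either arm has
#' zero events, `correction` is added to all four cells (so each arm total
#' increases by `2 * correction`); with zero events in both arms the table
#' carries no information about the ratio and an incomputable-study error is
#' signalled.
#'
#' @inheritParams log_odds_ratio
#' @return A list with components `y` (log RR) and `se`.
#' @examples
#' log_risk_ratio(9, 10, 3, 10)  # y = log(3)
#' @export
log_risk_ratio <- function(events_treat, total_treat, events_ctrl, total_ctrl,
                           correction = 0.5) {
  check_counts(events_treat, total_treat, events_ctrl, total_ctrl, correction)
  a <- events_treat; n1 <- total_treat
  c <- events_ctrl;  n2 <- total_ctrl
  if (a == 0 && c == 0)
    stop_incomputable("zero events in both arms")
  if (a == 0 || c == 0) {
    if (correction == 0)
      stop_incomputable("zero events with continuity correction 0")
    a <- a + correction; n1 <- n1 + 2 * correction
    c <- c + correction; n2 <- n2 + 2 * correction
  }
  if (a == n1 && c == n2)
    stop_incomputable("all events in both arms")
  list(y = log((a / n1) / (c / n2)),
       se = sqrt(1 / a - 1 / n1 + 1 / c - 1 / n2))
}

## shared validation for 2x2 tables
check_counts <- function(events_treat, total_treat, events_ctrl, total_ctrl,
                         correction) {
  stopifnot(length(events_treat) == 1, length(total_treat) == 1,
            length(events_ctrl) == 1, length(total_ctrl) == 1)
  if (!is.finite(correction) || correction < 0)
    stop("'correction' must be a non-negative number")
  for (x in list(events_treat, total_treat, events_ctrl, total_ctrl))
    if (!is.finite(x) || x < 0 || x != round(x))
      stop("arm counts must be non-negative integers")
  if (total_treat < 1 || total_ctrl < 1)
    stop("arm totals must be >= 1")
  if (events_treat > total_treat || events_ctrl > total_ctrl)
    stop("events exceed arm total")
  invisible(TRUE)
}

## condition class used so callers can distinguish "this study carries no
## information" from programming errors
stop_incomputable <- function(msg) {
  cond <- structure(
    class = c("bfmeta_incomputable_study", "error", "condition"),
    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

effect_fun <- function(metric) {
  switch(metric, OR = log_odds_ratio, RR = log_risk_ratio,
         stop("unknown metric: ", metric))
}
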