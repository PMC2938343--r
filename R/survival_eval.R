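#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times tau <= t of (1 - d_tau / n_tau)` where
#' `d_tau` is the number of events and `n_tau` the number at risk at `tau`.
#' A subject censored exactly at an event time is counted at risk for that
#' event (the standard convention).
#'
#' @param times follow-up times (> 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return list of class `"km_estimate"`: `event_times` (ascending distinct
#'   times with >= 1 event), `at_risk`, `events`, `survival` (the step
#'   function values after each event time).
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))  # S(1) = 2/3, S(3) = 0
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) stop("times/events length mismatch",
                                            call. = FALSE)
  stopifnot(all(times > 0), all(events %in% c(0, 1)))
  et <- sort(unique(times[events == 1]))
  n_at <- vapply(et, function(tt) sum(times >= tt), numeric(1L))
  d <- vapply(et, function(tt) sum(times == tt & events == 1), numeric(1L))
  surv <- cumprod(1 - d / n_at)
  structure(
    list(event_times = et, at_risk = n_at, events = d, survival = surv),
    class = "km_estimate"
  )
}

#' Evaluate a Kaplan-Meier estimate at given times
#'
#' @param km a [km_estimate()].
#' @param t times at which to evaluate the step function.
#' @return survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_estimate"))
  vapply(t, function(tt) {
    idx <- which(km$event_times <= tt)
    if (length(idx) == 0L) 1 else km$survival[max(idx)]
  }, numeric(1L))
}

#' Two-group log-rank test
#'
#' The standard (unweighted) log-rank test: at every distinct event time the
#' observed events in group A are compared with the expectation under the
#' pooled hazard, with hypergeometric variance; the statistic
#' `(sum(O - E))^2 / sum(V)` is referred to a chi-square distribution with
#' one degree of freedom. When the pooled data contain no events (or no
#' variance), the result degenerates to statistic 0, p = 1.
#'
#' @param times_a,events_a follow-up times and event indicators, group A.
#' @param times_b,events_b same for group B.
#' @return list of class `"logrank_result"`: `statistic`, `p_value`,
#'   `group_sizes` (named counts), `observed`, `expected` (per-group event
#'   totals).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  stopifnot(length(times_a) == length(events_a),
            length(times_b) == length(events_b),
            all(c(events_a, events_b) %in% c(0, 1)),
            all(c(times_a, times_b) > 0))
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  in_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  et <- sort(unique(times[events == 1]))

  o_minus_e <- 0
  v_sum <- 0
  oa <- 0; ea <- 0
  for (tt in et) {
    at_risk <- times >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_a)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & in_a)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    oa <- oa + d1; ea <- ea + e1
    if (n > 1L) {
      v_sum <- v_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (length(et) == 0L || v_sum <= 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- o_minus_e^2 / v_sum
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  d_total <- sum(events)
  structure(
    list(statistic = stat, p_value = p,
         group_sizes = c(a = length(times_a), b = length(times_b)),
         observed = c(a = oa, b = d_total - oa),
         expected = c(a = ea, b = d_total - ea)),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g (1 df), p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  groups n = %d / %d; observed events %g / %g; expected %.2f / %.2f\n",
              x$group_sizes[["a"]], x$group_sizes[["b"]],
              x$observed[["a"]], x$observed[["b"]],
              x$expected[["a"]], x$expected[["b"]]))
  invisible(x)
}

#' Kaplan-Meier step table for export
#'
#' @param km a [km_estimate()].
#' @return data.frame with columns `time`, `at_risk`, `events`, `survival`.
#' @export
km_table <- function(km) {
  stopifnot(inherits(km, "km_estimate"))
  data.frame(time = km$event_times, at_risk = km$at_risk,
             events = km$events, survival = km$survival)
}
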