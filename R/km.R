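# Kaplan-Meier product-limit estimation. Censored flies remain at risk
# through their recorded time (deaths precede censorings at tied times,
# the standard convention) and leave the risk set afterwards.

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive observation times (days).
#' @param events 0/1 indicators; 1 = observed death, 0 = right-censored.
#' @return An object of class `km_curve`: `time` (increasing distinct event
#'   times), `n_risk`, `n_event`, `survival` (non-increasing, in \[0,1\]),
#'   plus totals `n` and `n_events`.
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times)
  events <- as.integer(events)
  if (length(times) != length(events))
    stop("times and events must have equal length")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("times must be positive and finite")
  if (!all(events %in% c(0L, 1L)))
    stop("events must be 0 or 1")
  if (sum(events) == 0L) stop("no deaths observed")

  dt <- sort(times[events == 1L])
  rl <- rle(dt)
  event_times <- rl$values
  n_event <- rl$lengths
  st <- sort(times)
  n_risk <- length(times) - findInterval(event_times, st, left.open = TRUE)
  survival <- cumprod(1 - n_event / n_risk)

  structure(list(time = event_times, n_risk = as.integer(n_risk),
                 n_event = as.integer(n_event), survival = survival,
                 n = length(times), n_events = sum(events)),
            class = "km_curve")
}

#' Survival probability at given times
#'
#' Step-function evaluation of a `km_curve`: 1 before the first event time,
#' then the product-limit value of the last event time at or before `t`.
#'
#' @param curve a [km_estimate] result.
#' @param t numeric vector of times.
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(1, curve$survival)[idx + 1L]
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest event time at which the estimated survival falls to 0.5 or
#' below (with a 1e-9 numerical guard on the comparison). When the curve
#' never reaches 0.5 — heavy censoring or a short assay — the median is
#' undefined and `NA` is returned; this is a value, not an error.
#'
#' @param curve a [km_estimate] result.
#' @return median in days, or `NA_real_` if undefined.
#' @export
km_median <- function(curve) {
  hit <- which(curve$survival <= 0.5 + 1e-9)
  if (length(hit)) curve$time[hit[1L]] else NA_real_
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s days\n",
              x$n, x$n_events,
              format(km_median(x), digits = 4)))
  invisible(x)
}
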