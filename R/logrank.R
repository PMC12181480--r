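# Two-group Mantel-Haenszel log-rank test. At each distinct pooled event
# time the observed deaths in group A are compared with their expectation
# under the hypergeometric null; chi2 = (sum(O - E))^2 / sum(V) on 1 df.

#' Two-group log-rank test
#'
#' @param times_a,events_a observation times and 0/1 event indicators for
#'   group A.
#' @param times_b,events_b the same for group B.
#' @return An object of class `logrank_result`: `chi2`, `df` (1), `p`
#'   (upper chi-square tail), `direction` (`"A_longer"`, `"B_longer"` or
#'   `"none"`, from the sign of observed minus expected deaths in A —
#'   fewer deaths than expected means longer-lived), and the `observed` and
#'   `expected` event totals for group A.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("both groups must be non-empty")
  ta <- as.numeric(times_a); tb <- as.numeric(times_b)
  ea <- as.integer(events_a); eb <- as.integer(events_b)
  if (length(ta) != length(ea) || length(tb) != length(eb))
    stop("times and events must have equal length")
  if (sum(ea) + sum(eb) == 0L) stop("no deaths observed in either group")

  tt <- c(ta, tb)
  dt_all <- sort(tt[c(ea, eb) == 1L])
  rl <- rle(dt_all)
  ot <- rl$values            # distinct pooled event times
  d_tot <- rl$lengths

  st <- sort(tt); sta <- sort(ta)
  n_tot <- length(tt) - findInterval(ot, st, left.open = TRUE)
  n_a <- length(ta) - findInterval(ot, sta, left.open = TRUE)

  d_a <- numeric(length(ot))
  if (any(ea == 1L)) {
    rla <- rle(sort(ta[ea == 1L]))
    d_a[match(rla$values, ot)] <- rla$lengths
  }

  E_a <- d_tot * n_a / n_tot
  V <- ifelse(n_tot > 1,
              d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
                (n_tot - d_tot) / (n_tot - 1),
              0)
  o_minus_e <- sum(d_a - E_a)
  v_sum <- sum(V)
  chi2 <- if (v_sum > 0) o_minus_e^2 / v_sum else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- if (abs(o_minus_e) < 1e-12) "none"
               else if (o_minus_e < 0) "A_longer" else "B_longer"

  structure(list(chi2 = chi2, df = 1L, p = p, direction = direction,
                 observed = sum(d_a), expected = sum(E_a),
                 n_a = length(ta), n_b = length(tb)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g on %d df, p = %.3g (%s)\n",
              x$chi2, x$df, x$p, x$direction))
  invisible(x)
}
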