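# Proportional-hazards diagnostic from Schoenfeld residuals: per dummy
# column, a score test of zero slope in the regression of scaled Schoenfeld
# residuals on transformed event time (the classic zph statistic).

#' Test the proportional-hazards assumption
#'
#' For every death the Schoenfeld residual is the covariate value of the
#' fly that died minus the risk-set weighted mean at that time. Scaled
#' residuals (`d * r V + beta`, with `V` the coefficient covariance and `d`
#' the death count) are regressed on a transform `g(t)` of event time; under
#' proportional hazards the slope is zero and the per-column statistic
#' `(sum (g - gbar) s*)^2 / (d * V_jj * sum (g - gbar)^2)` is chi-square on
#' 1 df. A simple single-death risk-set mean is used at tied times.
#'
#' @param fit a converged [cox_fit] (it carries its own model frame).
#' @param ds ignored; accepted for call-site symmetry with [cox_fit].
#' @param transform time transform: `"km"` (default; `1 -` the pooled
#'   Kaplan-Meier survival at each event time), `"identity"`, or `"rank"`.
#' @return An object of class `ph_test_result`: `table` (data.frame with
#'   one row per dummy column: `statistic`, `df`, `p`) and `transform`.
#' @export
ph_test <- function(fit, ds = NULL, transform = c("km", "identity", "rank")) {
  transform <- match.arg(transform)
  if (!inherits(fit, "cox_fit")) stop("fit must be a cox_fit")
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  d <- fit$n_events
  if (d < 3L) stop("fewer than 3 events; cannot assess proportional hazards")
  p <- ncol(fit$X)
  if (p == 0L) stop("null model has no covariates to test")

  tt <- fit$time
  ord <- order(tt, decreasing = TRUE)
  ts <- tt[ord]
  evs <- fit$event[ord]
  Xs <- fit$X[ord, , drop = FALSE]
  w <- exp(drop(Xs %*% fit$beta))
  S0c <- cumsum(w)
  S1c <- apply(Xs * w, 2L, cumsum)

  rl <- rle(ts)
  ends <- cumsum(rl$lengths)
  run_id <- rep.int(seq_along(ends), rl$lengths)
  idx_death <- which(evs == 1L)
  ie <- ends[run_id[idx_death]]
  xbar <- S1c[ie, , drop = FALSE] / S0c[ie]
  r <- Xs[idx_death, , drop = FALSE] - xbar
  dtimes <- ts[idx_death]
  o2 <- order(dtimes)
  r <- r[o2, , drop = FALSE]
  dtimes <- dtimes[o2]

  g <- switch(transform,
              identity = dtimes,
              rank = rank(dtimes),
              km = {
                km <- km_estimate(fit$time, fit$event)
                1 - km_survival_at(km, dtimes)
              })
  gc_ <- g - mean(g)

  V <- fit$var
  sstar <- d * (r %*% V)                # + beta drops out after centring g
  u <- drop(crossprod(gc_, sstar))
  z <- u^2 / (d * diag(V) * sum(gc_^2))
  tab <- data.frame(covariate = colnames(fit$X),
                    statistic = z, df = 1L,
                    p = stats::pchisq(z, 1, lower.tail = FALSE),
                    row.names = NULL)
  structure(list(table = tab, transform = transform, n_events = d),
            class = "ph_test_result")
}

#' @export
print.ph_test_result <- function(x, ...) {
  cat(sprintf("Proportional-hazards check (%s transform, %d events)\n",
              x$transform, x$n_events))
  print(transform(x$table, statistic = round(statistic, 4),
                  p = signif(p, 3)))
  invisible(x)
}
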