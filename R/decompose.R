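# Likelihood-based attribution of lifespan variance to design factors.
# One full Cox model with all factors is compared against reduced models
# each omitting one factor (all of its dummy columns at once); the drop in
# partial log-likelihood, normalised over factors, is that factor's
# contribution. Contributions are invariant to dummy reference levels and
# to factor ordering because each delta is a difference of maximised
# likelihoods of the same nested pair.

.default_factors <- c("lab", "sex", "diet", "cohort", "genotype")

#' Decompose lifespan variance into factor contributions
#'
#' Fits the full Cox model with all `factors` as categorical covariates and,
#' for each factor, the reduced model omitting it, on identical records.
#' The contribution of factor j is
#' `(loglik_full - loglik_reduced_j) / sum_i (loglik_full - loglik_reduced_i)`.
#' Nested-model theory forbids negative differences; tiny negative values
#' (within 1e-6, numerical noise) are clamped to zero with a warning, larger
#' ones abort. Cox-Snell R-squared is reported for the full and every
#' reduced model.
#'
#' @param ds a [lifespan_dataset] (or compatible data.frame).
#' @param factors character vector of factor columns; each must have at
#'   least two observed levels.
#' @param ties tie correction passed to [cox_fit].
#' @param subset_label free-text label describing the records analysed.
#' @return An object of class `decomposition_result`: `factors`,
#'   `loglik_full`, `loglik_null`, `loglik_reduced`, `delta`,
#'   `contribution` (sums to 1), `contribution_pct`, `r2_full`,
#'   `r2_reduced`, `n`, `n_events`, `ties`, `subset_label`.
#' @export
decompose <- function(ds, factors = .default_factors,
                      ties = c("efron", "breslow"),
                      subset_label = "all records") {
  ties <- match.arg(ties)
  df <- as.data.frame(ds)
  if (length(factors) == 0L) stop("factors must be non-empty")
  if (anyDuplicated(factors)) stop("factors must not contain duplicates")
  for (f in factors) {
    if (!f %in% names(df)) stop("unknown factor: ", f)
    if (length(unique(df[[f]])) < 2L)
      stop("factor '", f, "' is constant in the data")
  }

  full <- cox_fit(df, factors, ties = ties)
  if (!full$converged)
    stop("full model did not converge (max |score| = ",
         format(full$score_max), ")")

  loglik_reduced <- vapply(factors, function(f) {
    red <- cox_fit(df, setdiff(factors, f), ties = ties)
    if (!red$converged)
      stop("reduced model without '", f, "' did not converge")
    red$loglik
  }, numeric(1))

  delta <- full$loglik - loglik_reduced
  if (any(delta < -1e-6))
    stop("reduced model beats the full model beyond numerical tolerance ",
         "for: ", paste(factors[delta < -1e-6], collapse = ", "))
  if (any(delta < 0)) {
    warning("negative log-likelihood difference(s) clamped to zero for: ",
            paste(factors[delta < 0], collapse = ", "))
    delta[delta < 0] <- 0
  }
  if (sum(delta) <= 0)
    stop("no factor changes the partial likelihood; contributions undefined")

  contribution <- delta / sum(delta)
  n <- full$n
  r2_reduced <- 1 - exp((2 / n) * (full$loglik_null - loglik_reduced))

  structure(list(factors = factors,
                 loglik_full = full$loglik,
                 loglik_null = full$loglik_null,
                 loglik_reduced = loglik_reduced,
                 delta = delta,
                 contribution = contribution,
                 contribution_pct = 100 * contribution,
                 r2_full = cox_snell_r2(full),
                 r2_reduced = r2_reduced,
                 n = n, n_events = full$n_events,
                 ties = ties, subset_label = subset_label),
            class = "decomposition_result")
}

#' Decompose a filtered subset of the data
#'
#' @inheritParams decompose
#' @param filter either a logical vector over rows or a predicate function
#'   `function(df) -> logical`, selecting the records to analyse.
#' @param label subset label recorded in the result (e.g. "cohorts 1-3").
#' @return A `decomposition_result` for the filtered records.
#' @export
decompose_subset <- function(ds, factors = .default_factors, filter,
                             label = "subset", ties = c("efron", "breslow")) {
  df <- as.data.frame(ds)
  keep <- if (is.function(filter)) filter(df) else filter
  if (!is.logical(keep) || length(keep) != nrow(df))
    stop("filter must yield one logical per record")
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("filter selects no records")
  decompose(df[keep, , drop = FALSE], factors = factors,
            ties = match.arg(ties), subset_label = label)
}

#' Stratified variance decomposition
#'
#' Runs [decompose] separately within each level of `stratify_by` (which
#' must not itself appear in `factors`). A stratum whose fit fails — a
#' constant factor, no deaths — yields an error entry while the remaining
#' strata are still returned.
#'
#' @inheritParams decompose
#' @param stratify_by the field to stratify on (e.g. `"genotype"`).
#' @param factors factors decomposed within each stratum; defaults to the
#'   canonical five minus `stratify_by`.
#' @return Named list (one element per stratum level) of
#'   `decomposition_result` objects, or `decomposition_error` entries
#'   carrying the stratum's failure message.
#' @export
decompose_stratified <- function(ds, stratify_by,
                                 factors = setdiff(.default_factors,
                                                   stratify_by),
                                 ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  df <- as.data.frame(ds)
  if (!stratify_by %in% names(df)) stop("unknown field: ", stratify_by)
  if (stratify_by %in% factors)
    stop("stratify_by ('", stratify_by, "') must not appear in factors")
  levels_ <- sort(unique(as.character(df[[stratify_by]])))
  out <- lapply(levels_, function(lv) {
    sub <- df[df[[stratify_by]] == lv, , drop = FALSE]
    tryCatch(decompose(sub, factors = factors, ties = ties,
                       subset_label = paste0(stratify_by, " = ", lv)),
             error = function(e) {
               warning("stratum ", lv, " failed: ", conditionMessage(e))
               structure(list(stratum = lv, message = conditionMessage(e)),
                         class = "decomposition_error")
             })
  })
  stats::setNames(out, levels_)
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("Variance decomposition (%s; n = %d, events = %d, %s ties)\n",
              x$subset_label, x$n, x$n_events, x$ties))
  tab <- data.frame(factor = x$factors,
                    delta_loglik = round(x$delta, 3),
                    contribution_pct = round(x$contribution_pct, 2),
                    r2_reduced = round(x$r2_reduced, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("full model: loglik = %.3f, Cox-Snell R2 = %.4f\n",
              x$loglik_full, x$r2_full))
  invisible(x)
}
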