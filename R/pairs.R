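# Per-stratum DR/AL comparisons: in each (lab, cohort, genotype, sex)
# stratum with both diet arms, a two-group log-rank test; Bonferroni
# correction over the tests actually performed; the longer-lived arm of
# each significant pair called from Kaplan-Meier medians.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests performed (>= 1).
#' @return `alpha / m`. For the canonical 64-pair battery at `alpha = 0.05`
#'   this is 0.00078125.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be a positive integer")
  alpha / m
}

#' Run the per-stratum DR versus AL log-rank battery
#'
#' Splits the dataset by (lab, cohort, genotype, sex), tests DR against AL
#' with a log-rank test in every complete stratum, and applies a Bonferroni
#' threshold of `alpha` divided by the number of tests actually performed.
#' Strata missing a diet arm (or with no deaths) are skipped with a warning
#' and do not count toward the correction. The winner of a significant pair
#' is the arm with the larger Kaplan-Meier median; exactly tied or undefined
#' medians fall back to the sign of observed-minus-expected events.
#'
#' @param ds a [lifespan_dataset].
#' @param alpha family-wise error rate (default 0.05).
#' @return A data.frame of class `pair_battery`, one row per tested pair:
#'   `lab`, `cohort`, `genotype`, `sex`, `n_dr`, `n_al`, `median_dr`,
#'   `median_al`, `chi2`, `p`, `significant`, `winner` (`"DR"`, `"AL"` or
#'   `"none"`); attributes `alpha`, `m`, `threshold`.
#' @export
run_pair_battery <- function(ds, alpha = 0.05) {
  df <- as.data.frame(ds)
  key <- interaction(df$lab, df$cohort, df$genotype, df$sex,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(df, key)

  usable <- list()
  skipped <- 0L
  for (g in groups) {
    dr <- g[g$diet == "DR", ]
    al <- g[g$diet == "AL", ]
    if (nrow(dr) == 0L || nrow(al) == 0L ||
        sum(dr$event) + sum(al$event) == 0L) {
      skipped <- skipped + 1L
      next
    }
    usable[[length(usable) + 1L]] <- list(dr = dr, al = al, meta = g[1L, ])
  }
  if (skipped > 0L)
    warning(skipped, " stratum/strata skipped (missing diet arm or no deaths)")
  m <- length(usable)
  if (m == 0L) stop("no complete DR/AL pair in the dataset")
  threshold <- bonferroni_threshold(alpha, m)

  rows <- lapply(usable, function(u) {
    dr <- u$dr; al <- u$al
    lr <- logrank_test(dr$age_days, dr$event, al$age_days, al$event)
    med_dr <- if (sum(dr$event)) km_median(km_estimate(dr$age_days, dr$event))
              else NA_real_
    med_al <- if (sum(al$event)) km_median(km_estimate(al$age_days, al$event))
              else NA_real_
    sig <- lr$p <= threshold
    winner <- "none"
    if (sig) {
      if (!is.na(med_dr) && !is.na(med_al) && med_dr != med_al) {
        winner <- if (med_dr > med_al) "DR" else "AL"
      } else {
        # group A of the test is DR: fewer deaths than expected => DR longer
        winner <- switch(lr$direction, A_longer = "DR", B_longer = "AL",
                         "none")
      }
    }
    data.frame(lab = u$meta$lab, cohort = u$meta$cohort,
               genotype = u$meta$genotype, sex = u$meta$sex,
               n_dr = nrow(dr), n_al = nrow(al),
               median_dr = med_dr, median_al = med_al,
               chi2 = lr$chi2, p = lr$p,
               significant = sig, winner = winner,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lab, out$cohort, out$genotype, out$sex), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  attr(out, "threshold") <- threshold
  class(out) <- c("pair_battery", "data.frame")
  out
}

#' Median lifespan differences per pair
#'
#' The signed AL-minus-DR difference of Kaplan-Meier medians for each pair;
#' pairs with an undefined median propagate `NA`.
#'
#' @param results a [run_pair_battery] result.
#' @return data.frame with the pair key columns and `delta_median`
#'   (`median_al - median_dr`).
#' @export
pair_median_deltas <- function(results) {
  df <- as.data.frame(results)
  data.frame(df[, c("lab", "cohort", "genotype", "sex")],
             delta_median = df$median_al - df$median_dr,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks at ties; the p-value uses the
#' t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks")
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Cross-laboratory concordance of group longevities
#'
#' For every (diet, sex, genotype, cohort) group present in both labs,
#' computes a longevity statistic per lab — the mean age at death of flies
#' that died (`"mean"`, default) or the Kaplan-Meier median (`"median"`) —
#' and the Spearman rank correlation of the two labs' values across groups.
#'
#' @param ds a [lifespan_dataset] containing both labs.
#' @param statistic `"mean"` or `"median"`.
#' @return An object of class `cross_lab_summary`: `points` (data.frame
#'   with the group key and one longevity column per lab), `rho`, `p`,
#'   `statistic`.
#' @export
cross_lab_concordance <- function(ds, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  df <- as.data.frame(ds)
  labs <- sort(unique(df$lab))
  if (length(labs) < 2L) stop("both labs must be present")

  stat_fn <- function(g) {
    if (statistic == "mean") {
      if (!sum(g$event)) return(NA_real_)
      mean(g$age_days[g$event == 1L])
    } else {
      if (!sum(g$event)) return(NA_real_)
      km_median(km_estimate(g$age_days, g$event))
    }
  }

  key <- interaction(df$diet, df$sex, df$genotype, df$cohort,
                     drop = TRUE, lex.order = TRUE)
  pts <- lapply(split(df, key), function(g) {
    if (length(unique(g$lab)) < 2L) return(NULL)
    v1 <- stat_fn(g[g$lab == labs[1L], ])
    v2 <- stat_fn(g[g$lab == labs[2L], ])
    if (is.na(v1) || is.na(v2)) return(NULL)
    cbind(g[1L, c("diet", "sex", "genotype", "cohort")],
          stats::setNames(data.frame(v1, v2), labs))
  })
  pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  if (is.null(pts) || nrow(pts) < 3L)
    stop("fewer than 3 groups matched across labs")
  rownames(pts) <- NULL
  ct <- spearman_rho(pts[[labs[1L]]], pts[[labs[2L]]])
  structure(list(points = pts, rho = ct$rho, p = ct$p,
                 statistic = statistic, labs = labs),
            class = "cross_lab_summary")
}

#' @export
print.cross_lab_summary <- function(x, ...) {
  cat(sprintf(
    "Cross-lab concordance (%s longevity, %d matched groups): rho = %.3f, p = %.3g\n",
    x$statistic, nrow(x$points), x$rho, x$p))
  invisible(x)
}

#' @export
print.pair_battery <- function(x, ...) {
  cat(sprintf(
    "DR/AL pair battery: %d pairs, threshold %.6g (alpha %.3g / %d)\n",
    nrow(x), attr(x, "threshold"), attr(x, "alpha"), attr(x, "m")))
  cat(sprintf("significant: %d (DR longer: %d, AL longer: %d)\n",
              sum(x$significant), sum(x$winner == "DR"),
              sum(x$winner == "AL")))
  print(as.data.frame(x))
  invisible(x)
}
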