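# Cox proportional-hazards fitting by Newton-Raphson maximisation of the
# partial likelihood, with Efron (default) or Breslow handling of tied
# death times. Risk-set sums are accumulated by sorting on time and taking
# cumulative sums, so one likelihood/score/information evaluation is
# O(n * p^2) in vectorised operations; tied event times get a small loop.

# Treatment (dummy) coding; the reference level of each factor is its
# alphabetically first observed level unless the column is already a factor
# with explicit levels.
build_design <- function(df, covariates) {
  mats <- list()
  encoding <- list()
  for (v in covariates) {
    x <- df[[v]]
    f <- if (is.factor(x)) droplevels(x) else factor(x)
    lev <- levels(f)
    if (length(lev) < 2L)
      stop("covariate '", v, "' has fewer than 2 observed levels")
    M <- matrix(0, length(f), length(lev) - 1L,
                dimnames = list(NULL, paste0(v, lev[-1L])))
    for (j in seq_along(lev)[-1L]) M[, j - 1L] <- as.numeric(f == lev[j])
    mats[[v]] <- M
    encoding[[v]] <- list(reference = lev[1L], levels = lev,
                          columns = colnames(M))
  }
  X <- if (length(mats)) do.call(cbind, mats)
       else matrix(0, nrow(df), 0L)
  list(X = X, encoding = encoding)
}

# Shared partial-likelihood machinery. With newton = FALSE only the
# beta = 0 quantities (for the score test) are computed.
cox_engine <- function(tt, dd, X, ties = "efron", tol = 1e-9,
                      max_iter = 50L, newton = TRUE) {
  n <- length(tt)
  p <- ncol(X)
  ord <- order(tt, decreasing = TRUE)
  ts <- tt[ord]
  ev <- dd[ord]
  Xs <- X[ord, , drop = FALSE]

  rl <- rle(ts)
  ends <- cumsum(rl$lengths)          # last sorted row with time >= run value
  nruns <- length(ends)
  run_id <- rep.int(seq_len(nruns), rl$lengths)
  death_rows <- which(ev == 1L)
  dk <- tabulate(run_id[death_rows], nbins = nruns)
  event_runs <- which(dk > 0L)
  ie <- ends[event_runs]
  dvec <- dk[event_runs]
  untied <- which(dvec == 1L)
  tied <- which(dvec > 1L)
  tied_rows <- lapply(tied,
                      function(k) death_rows[run_id[death_rows] == event_runs[k]])

  if (p > 0L) {
    comb <- which(upper.tri(matrix(TRUE, p, p), diag = TRUE), arr.ind = TRUE)
    c1 <- comb[, 1L]; c2 <- comb[, 2L]
    XX <- Xs[, c1, drop = FALSE] * Xs[, c2, drop = FALSE]
    sum_x_death <- colSums(Xs[death_rows, , drop = FALSE])
    unpack <- function(v) {
      M <- matrix(0, p, p)
      M[cbind(c1, c2)] <- v
      M[cbind(c2, c1)] <- v
      M
    }
  }

  eval_fn <- function(beta) {
    eta <- if (p) drop(Xs %*% beta) else numeric(n)
    w <- exp(eta)
    S0 <- cumsum(w)[ie]
    if (p) {
      wX <- Xs * w
      wXX <- XX * w
      S1 <- apply(wX, 2L, cumsum)[ie, , drop = FALSE]
      S2 <- apply(wXX, 2L, cumsum)[ie, , drop = FALSE]
      g <- sum_x_death
      Hp <- numeric(length(c1))
    } else {
      g <- numeric(0)
      Hp <- numeric(0)
    }
    ll <- sum(eta[death_rows])

    if (length(untied)) {               # single deaths: Efron == Breslow
      S0u <- S0[untied]
      ll <- ll - sum(log(S0u))
      if (p) {
        U <- S1[untied, , drop = FALSE] / S0u
        g <- g - colSums(U)
        Hp <- Hp + colSums(S2[untied, , drop = FALSE] / S0u) -
          colSums(U[, c1, drop = FALSE] * U[, c2, drop = FALSE])
      }
    }
    for (j in seq_along(tied)) {
      k <- tied[j]
      dkk <- dvec[k]
      rows <- tied_rows[[j]]
      s0d <- sum(w[rows])
      S0k <- S0[k]
      if (p) {
        s1d <- colSums(wX[rows, , drop = FALSE])
        s2d <- colSums(wXX[rows, , drop = FALSE])
        S1k <- S1[k, ]
        S2k <- S2[k, ]
      }
      for (l in seq_len(dkk) - 1L) {
        f <- if (ties == "efron") l / dkk else 0
        phi <- S0k - f * s0d
        ll <- ll - log(phi)
        if (p) {
          P1 <- (S1k - f * s1d) / phi
          g <- g - P1
          Hp <- Hp + (S2k - f * s2d) / phi - P1[c1] * P1[c2]
        }
      }
    }
    list(ll = ll, g = g, Hp = Hp)
  }

  e0 <- eval_fn(if (p) rep(0, p) else numeric(0))
  loglik_null <- e0$ll
  if (!newton || p == 0L) {
    return(list(beta = stats::setNames(numeric(p), colnames(X)),
                loglik = loglik_null, loglik_null = loglik_null,
                score0 = e0$g,
                imat0 = if (p) unpack(e0$Hp) else matrix(0, 0L, 0L),
                var = matrix(NA_real_, p, p), se = rep(NA_real_, p),
                converged = p == 0L, iterations = 0L,
                score_max = if (p) max(abs(e0$g)) else 0))
  }

  beta <- rep(0, p)
  ll <- e0$ll
  g <- e0$g
  H <- unpack(e0$Hp)
  converged <- FALSE
  iter <- 0L
  repeat {
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    step <- tryCatch(solve(H, g), error = function(err) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {                            # step-halving on loglik decrease
      cand <- beta + lam * step
      ec <- eval_fn(cand)
      if (is.finite(ec$ll) && ec$ll >= ll) break
      lam <- lam / 2
      if (lam < 2^-30) break
    }
    if (!is.finite(ec$ll) || ec$ll < ll) break
    gain <- ec$ll - ll
    beta <- cand; ll <- ec$ll; g <- ec$g; H <- unpack(ec$Hp)
    iter <- iter + 1L
    if (gain < 1e-13 * max(1, abs(ll)) && max(abs(g)) < 1e-5) {
      converged <- TRUE                 # likelihood flat at solver precision
      break
    }
  }
  if (!converged && max(abs(g)) < tol) converged <- TRUE

  V <- tryCatch(solve(H), error = function(err) matrix(NA_real_, p, p))
  list(beta = stats::setNames(beta, colnames(X)),
       loglik = ll, loglik_null = loglik_null,
       var = V, se = sqrt(pmax(diag(V), 0)),
       converged = converged, iterations = iter,
       score_max = max(abs(g)))
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial log-likelihood over treatment-coded dummy
#' columns of the requested categorical covariates by Newton-Raphson with
#' step-halving, starting at `beta = 0`. Convergence is declared when the
#' largest score component falls below `tol`. Reference levels are the
#' alphabetically first observed level of each covariate (AL, CantonS,
#' cohort 1, F, Hoffman for the canonical schema); pass a factor column
#' with reordered levels to override. `cohort` is always treated as an
#' unordered factor, never a numeric trend.
#'
#' @param ds a [lifespan_dataset] or data.frame with `age_days`, `event`
#'   and the covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty, giving the null model).
#' @param ties tie correction for the partial likelihood, `"efron"`
#'   (default, matching standard survival software) or `"breslow"`.
#' @param tol convergence tolerance on the maximum absolute score.
#' @param max_iter maximum Newton-Raphson iterations.
#' @return An object of class `cox_fit`: `beta` (log-hazard scale), `se`,
#'   `var`, `loglik`, `loglik_null`, `n`, `n_events`, `ties`, `converged`,
#'   `iterations`, `encoding` (reference level and dummy columns per
#'   covariate), and the model frame (`X`, `time`, `event`) for residual
#'   diagnostics.
#' @export
cox_fit <- function(ds, covariates, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  df <- as.data.frame(ds)
  if (!all(c("age_days", "event") %in% names(df)))
    stop("data must contain age_days and event columns")
  unknown <- setdiff(covariates, names(df))
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  tt <- as.numeric(df$age_days)
  dd <- as.integer(df$event)
  if (sum(dd) < 1L) stop("no deaths observed; cannot fit")

  des <- build_design(df, covariates)
  X <- des$X
  p <- ncol(X)
  if (p > 0L) {
    qrX <- qr(X)
    if (qrX$rank < p) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
  }

  eng <- cox_engine(tt, dd, X, ties = ties, tol = tol, max_iter = max_iter)
  structure(list(covariate_names = covariates, encoding = des$encoding,
                 beta = eng$beta, se = eng$se, var = eng$var,
                 loglik = eng$loglik, loglik_null = eng$loglik_null,
                 n = length(tt), n_events = sum(dd), ties = ties,
                 converged = eng$converged, iterations = eng$iterations,
                 score_max = eng$score_max,
                 X = X, time = tt, event = dd),
            class = "cox_fit")
}

#' Score test of a Cox model at beta = 0
#'
#' The efficient-score chi-square `U' I^{-1} U` evaluated at `beta = 0`.
#' For a single binary covariate without tied death times this is exactly
#' the two-group log-rank chi-square.
#'
#' @inheritParams cox_fit
#' @return list with `chi2`, `df` and `p`.
#' @export
cox_score_test <- function(ds, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  df <- as.data.frame(ds)
  tt <- as.numeric(df$age_days)
  dd <- as.integer(df$event)
  des <- build_design(df, covariates)
  eng <- cox_engine(tt, dd, des$X, ties = ties, newton = FALSE)
  chi2 <- drop(crossprod(eng$score0, solve(eng$imat0, eng$score0)))
  df_ <- ncol(des$X)
  list(chi2 = chi2, df = df_,
       p = stats::pchisq(chi2, df_, lower.tail = FALSE))
}

#' Cox-Snell pseudo R-squared
#'
#' `R^2 = 1 - exp((2 / n) * (loglik_null - loglik))` with `n` the number of
#' records used in the fit (not the number of events), the conventional
#' definition reported by standard survival software.
#'
#' @param fit a converged [cox_fit].
#' @return a value in `[0, 1)`.
#' @export
cox_snell_r2 <- function(fit) {
  if (!inherits(fit, "cox_fit")) stop("fit must be a cox_fit")
  if (!isTRUE(fit$converged))
    stop("fit did not converge; refusing to compute R-squared")
  1 - exp((2 / fit$n) * (fit$loglik_null - fit$loglik))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d, %s in %d iter\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (length(x$beta)) {
    tab <- data.frame(coef = x$beta, `exp.coef` = exp(x$beta), se = x$se)
    print(round(tab, 5))
  }
  cat(sprintf("loglik = %.4f (null %.4f)\n", x$loglik, x$loglik_null))
  invisible(x)
}
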