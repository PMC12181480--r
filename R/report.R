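# Machine-readable reports: the decomposition table (one row per factor,
# with the model log-likelihoods and Cox-Snell R-squared values) and the
# pair-battery table (one row per DR/AL comparison). Both serialise
# losslessly to CSV (17 significant digits) or JSON (full precision,
# fixed sorted keys) and read back to within 1e-10.

.fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write a decomposition or pair-battery report
#'
#' @param result a `decomposition_result` or `pair_battery` object.
#' @param path output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("csv", "json")) {
  UseMethod("write_report")
}

#' @export
write_report.decomposition_result <- function(result, path,
                                              format = c("csv", "json")) {
  if (missing(format) && grepl("\\.json$", path, ignore.case = TRUE))
    format <- "json"
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(type = "decomposition_result",
                subset_label = result$subset_label,
                ties = result$ties,
                n = result$n, n_events = result$n_events,
                loglik_full = result$loglik_full,
                loglik_null = result$loglik_null,
                r2_full = result$r2_full,
                factors = result$factors,
                loglik_reduced = as.list(result$loglik_reduced),
                delta = as.list(result$delta),
                contribution = as.list(result$contribution),
                r2_reduced = as.list(result$r2_reduced))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    tab <- data.frame(factor = result$factors,
                      loglik_reduced = .fmt_num(result$loglik_reduced),
                      delta = .fmt_num(result$delta),
                      contribution = .fmt_num(result$contribution),
                      contribution_pct = .fmt_num(result$contribution_pct),
                      r2_reduced = .fmt_num(result$r2_reduced),
                      loglik_full = .fmt_num(result$loglik_full),
                      loglik_null = .fmt_num(result$loglik_null),
                      r2_full = .fmt_num(result$r2_full),
                      n = result$n, n_events = result$n_events,
                      ties = result$ties,
                      subset_label = result$subset_label,
                      stringsAsFactors = FALSE)
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
write_report.pair_battery <- function(result, path,
                                      format = c("csv", "json")) {
  if (missing(format) && grepl("\\.json$", path, ignore.case = TRUE))
    format <- "json"
  format <- match.arg(format)
  df <- as.data.frame(result)
  if (format == "json") {
    obj <- list(type = "pair_battery",
                alpha = attr(result, "alpha"),
                m = attr(result, "m"),
                threshold = attr(result, "threshold"),
                pairs = df)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    out <- df
    for (v in c("median_dr", "median_al", "chi2", "p"))
      out[[v]] <- .fmt_num(out[[v]])
    out$alpha <- .fmt_num(attr(result, "alpha"))
    out$m <- attr(result, "m")
    out$threshold <- .fmt_num(attr(result, "threshold"))
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a report written by [write_report]
#'
#' The report type (decomposition versus pair battery) is detected from the
#' file's fields; numeric values round-trip to within 1e-10.
#'
#' @param path path to a `.csv` or `.json` report.
#' @return A `decomposition_result` or `pair_battery` object.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (identical(obj$type, "decomposition_result")) {
      fac <- obj$factors
      num <- function(x) stats::setNames(as.numeric(x[fac]), fac)
      res <- list(factors = fac,
                  loglik_full = obj$loglik_full,
                  loglik_null = obj$loglik_null,
                  loglik_reduced = num(obj$loglik_reduced),
                  delta = num(obj$delta),
                  contribution = num(obj$contribution),
                  contribution_pct = 100 * num(obj$contribution),
                  r2_full = obj$r2_full,
                  r2_reduced = num(obj$r2_reduced),
                  n = as.integer(obj$n), n_events = as.integer(obj$n_events),
                  ties = obj$ties, subset_label = obj$subset_label)
      return(structure(res, class = "decomposition_result"))
    }
    if (identical(obj$type, "pair_battery")) {
      df <- as.data.frame(obj$pairs)
      for (v in c("median_dr", "median_al"))
        if (is.null(df[[v]])) df[[v]] <- NA_real_ else
          df[[v]] <- as.numeric(df[[v]])
      attr(df, "alpha") <- obj$alpha
      attr(df, "m") <- as.integer(obj$m)
      attr(df, "threshold") <- obj$threshold
      class(df) <- c("pair_battery", "data.frame")
      return(df)
    }
    stop("unrecognised JSON report type")
  }

  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("contribution" %in% names(tab)) {
    fac <- tab$factor
    num <- function(x) stats::setNames(as.numeric(x), fac)
    res <- list(factors = fac,
                loglik_full = as.numeric(tab$loglik_full[1L]),
                loglik_null = as.numeric(tab$loglik_null[1L]),
                loglik_reduced = num(tab$loglik_reduced),
                delta = num(tab$delta),
                contribution = num(tab$contribution),
                contribution_pct = num(tab$contribution_pct),
                r2_full = as.numeric(tab$r2_full[1L]),
                r2_reduced = num(tab$r2_reduced),
                n = as.integer(tab$n[1L]),
                n_events = as.integer(tab$n_events[1L]),
                ties = tab$ties[1L], subset_label = tab$subset_label[1L])
    return(structure(res, class = "decomposition_result"))
  }
  if ("winner" %in% names(tab)) {
    alpha <- as.numeric(tab$alpha[1L])
    m <- as.integer(tab$m[1L])
    thr <- as.numeric(tab$threshold[1L])
    df <- tab[, c("lab", "cohort", "genotype", "sex", "n_dr", "n_al",
                  "median_dr", "median_al", "chi2", "p", "significant",
                  "winner")]
    for (v in c("median_dr", "median_al", "chi2", "p"))
      df[[v]] <- as.numeric(df[[v]])
    df$significant <- as.logical(df$significant)
    attr(df, "alpha") <- alpha
    attr(df, "m") <- m
    attr(df, "threshold") <- thr
    class(df) <- c("pair_battery", "data.frame")
    return(df)
  }
  stop("unrecognised CSV report layout")
}
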