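# Canonical schema for one fly per row:
#   lab, cohort, genotype, sex, diet, age_days, event (+ optional vial).
# Factor levels are stored as character with canonical spellings; reference
# levels used downstream are the alphabetically first of each set
# (AL, CantonS, cohort 1, F, Hoffman).

.canonical_levels <- list(
  lab      = c("Hoffman", "Lyu"),
  genotype = c("CantonS", "OregonR", "w1118", "wDahomey"),
  sex      = c("F", "M"),
  diet     = c("AL", "DR")
)

# case/punctuation-insensitive aliases -> canonical label
.level_alias <- list(
  lab      = c(hoffman = "Hoffman", hoffmanlab = "Hoffman",
               lyu = "Lyu", lyulab = "Lyu"),
  genotype = c(cantons = "CantonS", cs = "CantonS",
               oregonr = "OregonR", or = "OregonR",
               w1118 = "w1118",
               wdahomey = "wDahomey", wdah = "wDahomey"),
  sex      = c(f = "F", female = "F", m = "M", male = "M"),
  diet     = c(dr = "DR", al = "AL")
)

.norm_key <- function(x) gsub("[^a-z0-9]", "", tolower(as.character(x)))

.required_columns <- c("lab", "cohort", "genotype", "sex", "diet",
                       "age_days", "event")

#' Construct and validate a lifespan dataset
#'
#' Builds the canonical one-row-per-fly lifespan table used by every stage
#' of the pipeline. Category labels are normalised case-insensitively to the
#' canonical sets (labs Hoffman/Lyu; genotypes CantonS, OregonR, w1118,
#' wDahomey; sexes F/M; diets DR/AL). Rows violating an invariant (age not
#' a positive number, event not 0/1, unknown category level, non-integer
#' cohort) abort with row-numbered diagnostics.
#'
#' @param records data.frame with columns `lab`, `cohort`, `genotype`,
#'   `sex`, `diet`, `age_days`, `event` (and optionally `vial`).
#' @param provenance free-text source label attached to the dataset.
#' @return A `data.frame` of class `lifespan_dataset` with normalised
#'   character columns, integer `cohort` and `event`, numeric `age_days`,
#'   and a `provenance` attribute.
#' @export
lifespan_dataset <- function(records, provenance = "") {
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_columns, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  problems <- character(0)
  note <- function(rows, rule) {
    if (length(rows))
      problems <<- c(problems,
                     paste0("row(s) ", paste(utils::head(rows, 8L), collapse = ", "),
                            if (length(rows) > 8L) sprintf(" (and %d more)", length(rows) - 8L),
                            ": ", rule))
  }

  age <- suppressWarnings(as.numeric(df$age_days))
  note(which(is.na(age)), "age_days is not numeric")
  note(which(!is.na(age) & age <= 0), "age_days must be > 0")

  ev_raw <- df$event
  ev <- suppressWarnings(as.integer(as.numeric(ev_raw)))
  if (is.logical(ev_raw)) ev <- as.integer(ev_raw)
  note(which(is.na(ev) | !(ev %in% c(0L, 1L))),
       "event must be 0 (censored) or 1 (death)")

  co <- suppressWarnings(as.numeric(df$cohort))
  bad_co <- which(is.na(co) | co < 1 | co != round(co))
  note(bad_co, "cohort must be a positive integer")

  for (v in names(.canonical_levels)) {
    key <- .norm_key(df[[v]])
    mapped <- .level_alias[[v]][key]
    bad <- which(is.na(mapped))
    note(bad, paste0(v, " has an unknown level (permitted: ",
                     paste(.canonical_levels[[v]], collapse = ", "), ")"))
    df[[v]] <- unname(mapped)
  }

  if (length(problems))
    stop("invalid lifespan records:\n  ", paste(problems, collapse = "\n  "))

  out <- data.frame(lab = df$lab, cohort = as.integer(co),
                    genotype = df$genotype, sex = df$sex, diet = df$diet,
                    age_days = age, event = ev,
                    stringsAsFactors = FALSE)
  if (!is.null(df$vial)) out$vial <- as.character(df$vial)
  attr(out, "provenance") <- provenance
  class(out) <- c("lifespan_dataset", "data.frame")
  out
}

#' Derive the DR protocol from the cohort number
#'
#' Cohorts 1-3 ran protocol 1 (CT as the restricted diet versus SY10);
#' cohort 4 ran protocol 2 (S10Y5 versus S10Y15, varying only yeast).
#'
#' @param cohort integer vector of cohort numbers.
#' @return integer vector: 1, 2, or `NA` for cohorts outside 1-4.
#' @export
dr_protocol <- function(cohort) {
  out <- rep(NA_integer_, length(cohort))
  out[cohort %in% 1:3] <- 1L
  out[cohort == 4L] <- 2L
  out
}

#' Read a lifespan CSV into a validated dataset
#'
#' Reads a plain UTF-8 CSV with a header row, resolves column names to the
#' canonical schema (`lab`, `cohort`, `genotype`, `sex`, `diet`, `age_days`,
#' `event`), and validates every row. Supplementary files from other
#' pipelines rarely share one schema, so `column_map` renames arbitrary
#' headers; a few common synonyms (`age`, `lifespan`, `status`, `strain`,
#' ...) are also recognised case-insensitively.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(age_days = "AgeAtDeath")`.
#' @return A [lifespan_dataset] with `provenance = path`. Strata missing one
#'   of the two diets are reported with a warning (they are retained but
#'   will be skipped by the pair battery).
#' @export
read_lifespan_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")

  synonyms <- list(
    lab = c("lab", "laboratory"),
    cohort = c("cohort", "replicate", "block"),
    genotype = c("genotype", "strain", "line"),
    sex = c("sex", "gender"),
    diet = c("diet", "treatment", "dietarytreatment"),
    age_days = c("agedays", "age", "lifespan", "ageatdeath", "time", "days"),
    event = c("event", "status", "dead", "death", "uncensored"),
    vial = c("vial", "vialid")
  )
  got <- .norm_key(names(raw))
  resolve <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      hit <- which(names(raw) == column_map[[canon]])
      if (!length(hit))
        stop("column_map names '", column_map[[canon]], "' for ", canon,
             ", but the file has no such column")
      return(hit[1L])
    }
    hit <- which(got %in% synonyms[[canon]])
    if (length(hit)) hit[1L] else NA_integer_
  }
  idx <- vapply(names(synonyms), resolve, integer(1))
  missing_req <- setdiff(.required_columns,
                         names(synonyms)[!is.na(idx)])
  if (length(missing_req))
    stop("cannot resolve required column(s): ",
         paste(missing_req, collapse = ", "),
         "; supply a column_map")

  df <- raw[, idx[.required_columns]]
  names(df) <- .required_columns
  if (!is.na(idx[["vial"]])) df$vial <- raw[[idx[["vial"]]]]

  ds <- lifespan_dataset(df, provenance = path)
  up <- unpaired_strata(ds)
  if (nrow(up))
    warning(nrow(up), " stratum/strata lack one diet arm and will be ",
            "skipped by pairwise comparisons")
  ds
}

#' Write a lifespan dataset to CSV
#'
#' Deterministic full-precision serialisation; `read_lifespan_csv()` on the
#' result reproduces every field (ages to better than 1e-10).
#'
#' @param ds a [lifespan_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lifespan_csv <- function(ds, path) {
  df <- as.data.frame(ds)
  df$age_days <- sprintf("%.17g", df$age_days)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count flies and deaths per stratum
#'
#' @param ds a [lifespan_dataset] (or compatible data.frame).
#' @param keys non-empty character vector of stratifying fields.
#' @return data.frame with one row per observed stratum: the key columns,
#'   `n` (flies) and `n_events` (observed deaths). `sum(n)` always equals
#'   `nrow(ds)`.
#' @export
stratum_counts <- function(ds, keys) {
  if (length(keys) == 0L) stop("keys must be a non-empty list of fields")
  df <- as.data.frame(ds)
  unknown <- setdiff(keys, names(df))
  if (length(unknown))
    stop("unknown field(s): ", paste(unknown, collapse = ", "))
  f <- interaction(df[keys], drop = TRUE, lex.order = TRUE)
  n <- as.integer(table(f))
  nev <- as.integer(rowsum(as.numeric(df$event), f)[, 1L])
  key_df <- df[match(levels(f), as.character(f)), keys, drop = FALSE]
  out <- cbind(key_df, n = n, n_events = nev)
  rownames(out) <- NULL
  out
}

#' Strata missing one of the two diet arms
#'
#' Every (lab, cohort, genotype, sex) stratum in a complete study design
#' carries both a DR and an AL arm; strata where one arm is absent cannot
#' enter pairwise DR/AL comparisons.
#'
#' @param ds a [lifespan_dataset].
#' @return data.frame of incomplete strata (possibly 0 rows).
#' @export
unpaired_strata <- function(ds) {
  df <- as.data.frame(ds)
  key <- interaction(df$lab, df$cohort, df$genotype, df$sex,
                     drop = TRUE, lex.order = TRUE)
  two <- tapply(df$diet, key, function(d) length(unique(d)) == 2L)
  bad <- names(two)[!two]
  info <- unique(df[as.character(key) %in% bad,
                    c("lab", "cohort", "genotype", "sex")])
  rownames(info) <- NULL
  info
}
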