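# Synthetic lifespan generator. Gompertz proportional-hazards lifespans on
# the study's factorial layout: fixed log-hazard effects for genotype, sex,
# diet and lab; a random per-(lab, cohort) log-hazard shift modelling
# cohort-to-cohort (stochastic) variation; optional independent right
# censoring emulating husbandry losses.

#' Draw Gompertz-distributed lifespans
#'
#' Hazard `a * exp(b * t)`; survival `S(t) = exp(-(a/b) (e^{bt} - 1))`.
#' Sampling is by closed-form inversion of the survival function.
#'
#' @param n number of draws.
#' @param a baseline hazard scale (per day), > 0.
#' @param b hazard shape (per day), > 0; the hazard doubles every
#'   `log(2)/b` days.
#' @return numeric vector of lifespans in days.
#' @export
rgompertz <- function(n, a, b) {
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  u <- stats::runif(n)
  log1p(-(b / a) * log(u)) / b
}

.effect_defaults <- function() {
  list(genotype = c(CantonS = 0, OregonR = 0, w1118 = 0, wDahomey = 0),
       sex = c(F = 0, M = 0),
       diet = c(AL = 0, DR = 0),
       lab = c(Hoffman = 0, Lyu = 0))
}

#' Configure the lifespan simulator
#'
#' @param gompertz_a,gompertz_b baseline Gompertz hazard scale and shape
#'   (per day).
#' @param effects named list of named numeric vectors of log-hazard shifts,
#'   one per factor (`genotype`, `sex`, `diet`, `lab`), levels drawn from
#'   the canonical sets. The alphabetically first (reference) level of each
#'   factor must carry effect 0 for identifiability.
#' @param cohort_sd standard deviation of the per-(lab, cohort) random
#'   log-hazard shift (the stochastic component); 0 disables it.
#' @param n_per_cell flies per design cell (lab x cohort x genotype x sex x
#'   diet).
#' @param cohorts number of cohorts per lab.
#' @param censor_prob probability, in \[0, 1), that a fly is right-censored
#'   (husbandry loss); a censored fly's recorded age is uniform below its
#'   drawn death time.
#' @param seed integer RNG seed; identical seed and config give a
#'   bit-identical dataset.
#' @param baseline `"gompertz"` (default) or `"weibull"` (cumulative hazard
#'   `a * t^shape`), for robustness checks.
#' @param weibull_shape Weibull shape when `baseline = "weibull"`.
#' @param round_to_third_day round recorded ages to the nearest 1/3 day,
#'   mimicking thrice-weekly death scoring (off by default).
#' @param tv_flip optional non-proportional-hazards toggle:
#'   `list(factor =, level =, time =)` flips the sign of that level's
#'   log-hazard effect at `time` days (crossing hazards), for power studies
#'   of the proportional-hazards check.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(gompertz_a = 3e-4, gompertz_b = 0.1,
                              effects = list(), cohort_sd = 0,
                              n_per_cell = 25L, cohorts = 4L,
                              censor_prob = 0, seed = 1L,
                              baseline = c("gompertz", "weibull"),
                              weibull_shape = 3,
                              round_to_third_day = FALSE,
                              tv_flip = NULL) {
  baseline <- match.arg(baseline)
  if (gompertz_a <= 0 || gompertz_b <= 0)
    stop("gompertz_a and gompertz_b must be positive")
  if (cohort_sd < 0) stop("cohort_sd must be non-negative")
  if (n_per_cell < 1L) stop("n_per_cell must be positive")
  if (cohorts < 1L) stop("cohorts must be positive")
  if (censor_prob < 0 || censor_prob >= 1)
    stop("censor_prob must lie in [0, 1)")

  eff <- .effect_defaults()
  for (nm in names(effects)) {
    if (!nm %in% names(eff)) stop("unknown effect factor: ", nm)
    vals <- effects[[nm]]
    bad <- setdiff(names(vals), names(eff[[nm]]))
    if (length(bad))
      stop("unknown ", nm, " level(s): ", paste(bad, collapse = ", "))
    eff[[nm]][names(vals)] <- vals
  }
  for (nm in names(eff)) {              # identifiability: reference at 0
    ref <- sort(names(eff[[nm]]))[1L]
    if (eff[[nm]][[ref]] != 0)
      stop("reference level ", ref, " of ", nm, " must carry effect 0")
  }
  if (!is.null(tv_flip)) {
    if (!all(c("factor", "level", "time") %in% names(tv_flip)))
      stop("tv_flip needs fields factor, level, time")
    if (!tv_flip$factor %in% names(eff) ||
        !tv_flip$level %in% names(eff[[tv_flip$factor]]))
      stop("tv_flip names an unknown factor or level")
  }

  structure(list(gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 effects = eff, cohort_sd = cohort_sd,
                 n_per_cell = as.integer(n_per_cell),
                 cohorts = as.integer(cohorts),
                 censor_prob = censor_prob, seed = as.integer(seed),
                 baseline = baseline, weibull_shape = weibull_shape,
                 round_to_third_day = round_to_third_day,
                 tv_flip = tv_flip),
            class = "sim_config")
}

# cumulative baseline hazard and its inverse
.H0 <- function(t, cfg) {
  if (cfg$baseline == "gompertz")
    (cfg$gompertz_a / cfg$gompertz_b) * expm1(cfg$gompertz_b * t)
  else cfg$gompertz_a * t^cfg$weibull_shape
}
.H0inv <- function(y, cfg) {
  if (cfg$baseline == "gompertz")
    log1p(cfg$gompertz_b * y / cfg$gompertz_a) / cfg$gompertz_b
  else (y / cfg$gompertz_a)^(1 / cfg$weibull_shape)
}

#' Simulate a factorial lifespan dataset
#'
#' Draws `n_per_cell` lifespans per design cell of the 2 lab x `cohorts` x
#' 4 genotype x 2 sex x 2 diet layout. Each fly's hazard multiplier is
#' `exp(sum of its factor effects + its (lab, cohort) random shift)`; death
#' times come from the proportional-hazards inverse of the baseline
#' cumulative hazard. Censored flies (probability `censor_prob`) record a
#' uniform time below their drawn death time and `event = 0`.
#'
#' @param config a [simulation_config].
#' @return A [lifespan_dataset]; provenance records the seed. The caller's
#'   RNG state is preserved.
#' @export
simulate_lifespans <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must come from simulation_config()")
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  eff <- config$effects
  grid <- expand.grid(diet = names(eff$diet), sex = names(eff$sex),
                      genotype = names(eff$genotype),
                      cohort = seq_len(config$cohorts),
                      lab = names(eff$lab),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = config$n_per_cell), ]
  n <- nrow(grid)

  # shared environmental shift per (lab, cohort), drawn in fixed order
  shift_tab <- expand.grid(cohort = seq_len(config$cohorts),
                           lab = names(eff$lab),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shift_tab$shift <- stats::rnorm(nrow(shift_tab), 0, config$cohort_sd)
  shift <- shift_tab$shift[match(paste(grid$lab, grid$cohort),
                                 paste(shift_tab$lab, shift_tab$cohort))]

  eta <- eff$lab[grid$lab] + eff$genotype[grid$genotype] +
    eff$sex[grid$sex] + eff$diet[grid$diet] + shift
  m <- exp(unname(eta))

  u <- stats::runif(n)
  A <- -log(u)                          # exponential deviate: H(t) = A
  if (is.null(config$tv_flip)) {
    death <- .H0inv(A / m, config)
  } else {
    fl <- config$tv_flip
    flips <- grid[[fl$factor]] == fl$level
    e <- eff[[fl$factor]][[fl$level]]
    m2 <- m * ifelse(flips, exp(-2 * e), 1)   # post-flip multiplier
    Hcut <- .H0(fl$time, config)
    death <- numeric(n)
    pre <- A <= m * Hcut
    death[pre] <- .H0inv(A[pre] / m[pre], config)
    death[!pre] <- .H0inv(Hcut + (A[!pre] - m[!pre] * Hcut) / m2[!pre],
                          config)
  }

  censored <- stats::runif(n) < config$censor_prob
  ctime <- stats::runif(n) * death
  age <- ifelse(censored, ctime, death)
  if (config$round_to_third_day) age <- pmax(round(age * 3) / 3, 1 / 3)
  age <- pmax(age, .Machine$double.eps)

  lifespan_dataset(
    data.frame(lab = grid$lab, cohort = grid$cohort,
               genotype = grid$genotype, sex = grid$sex, diet = grid$diet,
               age_days = age, event = as.integer(!censored),
               stringsAsFactors = FALSE),
    provenance = sprintf("simulated (seed %d)", config$seed))
}

#' Study-like simulator configuration
#'
#' The default conditions the pipeline is exercised under: a large genotype
#' log-hazard spread, a moderate sex effect, cohort noise sized for a
#' double-digit cohort contribution, near-zero lab and diet effects, and
#' 125 flies per cell over the full 2 x 4 x 4 x 2 x 2 layout (16,000 flies),
#' with 4% husbandry censoring. Baseline Gompertz a = 3e-4/day, b = 0.1/day
#' puts the pooled median lifespan near 54 days, typical for these strains
#' at 25 degrees C.
#'
#' @param seed integer RNG seed.
#' @return A [simulation_config].
#' @export
study_like_config <- function(seed = 1L) {
  simulation_config(
    gompertz_a = 3e-4, gompertz_b = 0.1,
    effects = list(
      genotype = c(CantonS = 0, OregonR = -0.6, w1118 = 0.45,
                   wDahomey = -0.2),
      sex = c(F = 0, M = 0.35),
      diet = c(AL = 0, DR = -0.05),
      lab = c(Hoffman = 0, Lyu = 0.1)),
    cohort_sd = 0.25,
    n_per_cell = 125L, cohorts = 4L,
    censor_prob = 0.04, seed = seed)
}
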