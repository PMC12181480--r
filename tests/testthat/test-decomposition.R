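# Likelihood-based factor contributions.

sim_single_active <- function(seed) {
  # only genotype carries signal; ~4000 flies
  simulation_config(
    effects = list(genotype = c(CantonS = 0, OregonR = -0.7, w1118 = 0.5,
                                wDahomey = -0.25)),
    cohort_sd = 0, n_per_cell = 64L, cohorts = 2L,
    censor_prob = 0.03, seed = seed)
}

test_that("a single active factor collects almost all of the contribution", {
  ds <- simulate_lifespans(sim_single_active(101L))
  expect_equal(nrow(ds), 4096L)
  dec <- decompose(ds)
  cp <- setNames(dec$contribution, dec$factors)
  expect_gt(cp[["genotype"]], 0.9)
  expect_equal(sum(dec$contribution), 1, tolerance = 1e-10)
  expect_true(all(dec$delta >= -1e-6))
  expect_true(all(dec$r2_full >= dec$r2_reduced - 1e-8))
})

test_that("contributions are invariant to factor order and to the dummy
           reference level", {
  ds <- simulate_lifespans(sim_single_active(202L))
  a <- decompose(ds, factors = c("lab", "sex", "diet", "cohort", "genotype"))
  b <- decompose(ds, factors = c("genotype", "cohort", "diet", "sex", "lab"))
  expect_equal(as.list(setNames(a$contribution, a$factors)),
               as.list(setNames(b$contribution, b$factors))[a$factors],
               tolerance = 1e-8)
  expect_equal(a$loglik_full, b$loglik_full, tolerance = 1e-8)

  # relevel genotype so wDahomey is the reference: coefficients change,
  # contributions must not
  ds2 <- ds
  ds2$genotype <- factor(ds2$genotype,
                         levels = c("wDahomey", "CantonS", "OregonR", "w1118"))
  c_ <- decompose(ds2)
  expect_equal(unname(c_$contribution), unname(a$contribution),
               tolerance = 1e-7)
})

test_that("factors with identical simulated effects share the contribution
           equally on average", {
  diffs <- sexes <- numeric(50)
  for (s in 1:50) {
    cfg <- simulation_config(
      effects = list(sex = c(F = 0, M = 0.3), diet = c(AL = 0, DR = 0.3)),
      n_per_cell = 15L, cohorts = 2L, seed = 500L + s)
    ds <- simulate_lifespans(cfg)
    dec <- decompose(ds, factors = c("sex", "diet"))
    cp <- setNames(dec$contribution, dec$factors)
    sexes[s] <- cp[["sex"]]
    diffs[s] <- cp[["sex"]] - cp[["diet"]]
  }
  expect_lt(abs(mean(sexes) - 0.5), 0.05)
  expect_lt(abs(mean(diffs)), 0.1)
})

test_that("a pure-noise factor contributes little", {
  contribs <- numeric(20)
  for (s in 1:20) {
    ds <- simulate_lifespans(sim_single_active(700L + s))
    set.seed(s)
    ds$noise <- sample(ds$genotype)          # permuted labels: no signal
    dec <- decompose(ds, factors = c("genotype", "sex", "noise"))
    contribs[s] <- setNames(dec$contribution, dec$factors)[["noise"]]
  }
  expect_lt(median(contribs), 0.05)
})

test_that("contribution rank order recovers the simulated effect-spread
           rank order", {
  hits <- 0L
  for (s in 1:25) {
    cfg <- simulation_config(
      effects = list(
        genotype = c(CantonS = 0, OregonR = -0.8, w1118 = 0.6, wDahomey = -0.3),
        sex = c(F = 0, M = 0.45),
        diet = c(AL = 0, DR = 0.18)),
      cohort_sd = 0, n_per_cell = 63L, cohorts = 1L, seed = 900L + s)
    ds <- simulate_lifespans(cfg)
    dec <- decompose(ds, factors = c("genotype", "sex", "diet"))
    cp <- setNames(dec$contribution, dec$factors)
    if (cp[["genotype"]] > cp[["sex"]] && cp[["sex"]] > cp[["diet"]])
      hits <- hits + 1L
  }
  expect_gte(hits, 23L)   # >= 90% of seeds
})

test_that("an identity filter reproduces the full decomposition and empty
           filters fail", {
  ds <- simulate_lifespans(sim_single_active(303L))
  full <- decompose(ds)
  sub <- decompose_subset(ds, filter = function(df) rep(TRUE, nrow(df)),
                          label = "everything")
  expect_equal(sub$contribution, full$contribution, tolerance = 1e-12)
  expect_identical(sub$subset_label, "everything")
  expect_error(decompose_subset(ds, filter = function(df) df$cohort > 99),
               "no records")

  # cohort-subset plumbing: protocol-1 style filter keeps cohorts 1-2 here
  s13 <- decompose_subset(ds, filter = function(df) df$cohort %in% 1L,
                          label = "cohort 1",
                          factors = c("genotype", "sex", "diet"))
  expect_identical(s13$n, sum(ds$cohort == 1L))
})

test_that("stratified decomposition runs per level and rejects a stratifier
           inside the factor set", {
  ds <- simulate_lifespans(sim_single_active(404L))
  expect_error(decompose_stratified(ds, "genotype",
                                    factors = c("genotype", "sex")),
               "must not appear")
  res <- decompose_stratified(ds, "genotype",
                              factors = c("sex", "diet", "lab", "cohort"))
  expect_identical(names(res), c("CantonS", "OregonR", "w1118", "wDahomey"))
  for (r in res) {
    expect_s3_class(r, "decomposition_result")
    expect_equal(sum(r$contribution), 1, tolerance = 1e-10)
  }
})

test_that("stratified results match the pooled decomposition when effects
           are homogeneous across strata", {
  cfg <- simulation_config(
    effects = list(sex = c(F = 0, M = 0.5), diet = c(AL = 0, DR = 0.25)),
    n_per_cell = 50L, cohorts = 2L, seed = 42L)
  ds <- simulate_lifespans(cfg)
  pooled <- decompose(ds, factors = c("sex", "diet"))
  strat <- decompose_stratified(ds, "lab", factors = c("sex", "diet"))
  pooled_sex <- setNames(pooled$contribution, pooled$factors)[["sex"]]
  for (r in strat) {
    expect_lt(abs(setNames(r$contribution, r$factors)[["sex"]] - pooled_sex),
              0.15)
  }
})

test_that("degenerate decompositions fail loudly", {
  ds <- simulate_lifespans(sim_single_active(505L))
  one_lab <- ds[ds$lab == "Hoffman", ]
  expect_error(decompose(one_lab), "constant")
  expect_error(decompose(ds, factors = character(0)), "non-empty")
  expect_error(decompose(ds, factors = c("sex", "sex")), "duplicates")
})
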