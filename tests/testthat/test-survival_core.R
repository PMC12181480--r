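# Kaplan-Meier, log-rank, Cox fitting, Cox-Snell R2, PH diagnostics.

test_that("product-limit estimate matches hand computation", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, c(4L, 3L, 2L, 1L))

  # censoring at 2: risk set at 3 has one fly left
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))

  set.seed(21)
  for (s in 1:5) {
    d <- rand_surv_data(s)
    km3 <- km_estimate(d$age_days, d$event)
    oracle <- km_brute(d$age_days, d$event)
    expect_equal(km3$time, oracle$time)
    expect_equal(km3$survival, oracle$survival)
  }
})

test_that("KM survival is non-increasing and matches the empirical survival
           function on uncensored data", {
  for (s in 1:10) {
    d <- rand_surv_data(s)
    km <- km_estimate(d$age_days, d$event)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(diff(km$n_risk) <= 0))
    # uncensored: S(t) = fraction with time > t
    dd <- d
    dd$event <- 1L
    km_u <- km_estimate(dd$age_days, dd$event)
    emp <- sapply(km_u$time, function(u) mean(dd$age_days > u))
    expect_equal(km_u$survival, emp)
  }
})

test_that("KM median follows the smallest-time-at-or-below-0.5 rule", {
  expect_equal(km_median(km_estimate(1:10, rep(1, 10))), 5)
  # heavy censoring: survival never reaches 0.5 -> undefined, not an error
  km <- km_estimate(c(1, 2, 3, 4, 5), c(1, 1, 0, 0, 0))
  expect_gt(min(km$survival), 0.5)
  expect_true(is.na(km_median(km)))
})

test_that("km_estimate rejects degenerate input", {
  expect_error(km_estimate(c(1, 2), c(0, 0)), "no deaths")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "positive")
  expect_error(km_estimate(c(1, 2), c(1)), "equal length")
})

test_that("log-rank matches the brute-force hypergeometric accumulation", {
  # two small printed groups, with ties and censoring
  ta <- c(3, 5, 5, 8, 11); ea <- c(1, 1, 1, 0, 1)
  tb <- c(2, 4, 5, 9, 12); eb <- c(1, 1, 0, 1, 1)
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$chi2, logrank_brute(ta, ea, tb, eb), tolerance = 1e-12)
  expect_equal(lr$p, pchisq(lr$chi2, 1, lower.tail = FALSE))

  for (s in 1:8) {
    d <- rand_surv_data(s)
    a <- d[d$s == "F", ]; b <- d[d$s == "M", ]
    lr <- logrank_test(a$age_days, a$event, b$age_days, b$event)
    expect_equal(lr$chi2,
                 logrank_brute(a$age_days, a$event, b$age_days, b$event),
                 tolerance = 1e-10)
  }
})

test_that("log-rank is symmetric: identical groups give 0, swapped labels
           flip the direction only", {
  ta <- c(4, 7, 9, 13, 20); ea <- c(1, 1, 0, 1, 1)
  same <- logrank_test(ta, ea, ta, ea)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_identical(same$direction, "none")

  tb <- c(2, 5, 6, 10, 11); eb <- c(1, 1, 1, 1, 0)
  ab <- logrank_test(ta, ea, tb, eb)
  ba <- logrank_test(tb, eb, ta, ea)
  expect_equal(ab$chi2, ba$chi2, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_identical(sort(c(ab$direction, ba$direction)),
                   c("A_longer", "B_longer"))
  expect_error(logrank_test(numeric(0), integer(0), tb, eb), "non-empty")
})

test_that("log-rank chi-square equals the Cox score test for a binary
           covariate on tie-free data", {
  for (s in 1:6) {
    d <- rand_surv_data(s, tie = FALSE)
    a <- d[d$s == "F", ]; b <- d[d$s == "M", ]
    lr <- logrank_test(a$age_days, a$event, b$age_days, b$event)
    sc <- cox_score_test(d, "s")
    expect_equal(sc$chi2, lr$chi2, tolerance = 1e-8)
  }
})

test_that("Cox fit on mirrored groups returns beta near zero", {
  tt <- c(2, 5, 9, 14, 21, 30)
  d <- data.frame(age_days = c(tt, tt), event = 1L,
                  arm = rep(c("x", "y"), each = length(tt)))
  fit <- cox_fit(d, "arm")
  expect_true(fit$converged)
  expect_lt(abs(fit$beta), 1e-6)
  expect_equal(fit$loglik, fit$loglik_null, tolerance = 1e-10)
})

test_that("partial-likelihood estimate recovers a known hazard ratio", {
  set.seed(1234)
  n <- 200
  d <- data.frame(
    age_days = c(rexp(n, 1), rexp(n, 2)),
    event = 1L,
    arm = rep(c("ref", "fast"), each = n))
  d$arm <- factor(d$arm, levels = c("ref", "fast"))
  fit <- cox_fit(d, "arm")
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - log(2)) / fit$se, 3)
})

test_that("Cox fits agree with the survival package on random datasets", {
  for (s in 1:10) {
    d <- rand_surv_data(s)
    fit <- cox_fit(d, c("g", "s"))
    oracle <- survival::coxph(
      survival::Surv(age_days, event) ~ g + s, data = d, ties = "efron",
      control = survival::coxph.control(eps = 1e-11, iter.max = 100))
    expect_equal(unname(fit$beta), unname(coef(oracle)), tolerance = 1e-6)
    expect_equal(fit$loglik, oracle$loglik[2], tolerance = 1e-6)
    expect_equal(fit$loglik_null, oracle$loglik[1], tolerance = 1e-8)

    fitb <- cox_fit(d, c("g", "s"), ties = "breslow")
    oracleb <- survival::coxph(
      survival::Surv(age_days, event) ~ g + s, data = d, ties = "breslow",
      control = survival::coxph.control(eps = 1e-11, iter.max = 100))
    expect_equal(unname(fitb$beta), unname(coef(oracleb)), tolerance = 1e-6)
    expect_equal(fitb$loglik, oracleb$loglik[2], tolerance = 1e-6)
  }
})

test_that("null partial likelihood is tie-method-invariant on tie-free data
           and likelihood is monotone over nested covariate sets", {
  for (s in 1:6) {
    d <- rand_surv_data(s, tie = FALSE)
    fe <- cox_fit(d, c("g", "s"), ties = "efron")
    fb <- cox_fit(d, c("g", "s"), ties = "breslow")
    expect_equal(fe$loglik_null, fb$loglik_null, tolerance = 1e-12)
    f1 <- cox_fit(d, "g")
    expect_gte(fe$loglik, f1$loglik - 1e-8)
    expect_gte(f1$loglik, fe$loglik_null - 1e-8)
  }
})

test_that("rank-deficient designs fail naming the collinear columns and
           unconverged fits are refused downstream", {
  d <- rand_surv_data(2)
  d$g2 <- d$g   # exact copy => collinear dummies
  expect_error(cox_fit(d, c("g", "g2")), "collinear.*g2")

  # a fit cut off before the score tolerance is reached is flagged and
  # refused by downstream consumers
  fit <- cox_fit(d, c("g", "s"), max_iter = 1L)
  expect_false(fit$converged)
  expect_error(cox_snell_r2(fit), "converge")
  expect_error(ph_test(fit), "converge")
})

test_that("Cox-Snell R2 follows its closed form", {
  mock <- structure(list(n = 10L, loglik = -20, loglik_null = -20,
                         converged = TRUE), class = "cox_fit")
  expect_equal(cox_snell_r2(mock), 0)
  mock$loglik_null <- mock$loglik - mock$n / 2   # ll0 - ll = -n/2
  expect_equal(cox_snell_r2(mock), 1 - exp(-1))
  # strictly increasing in the likelihood gain at fixed n
  gains <- seq(0, 50, by = 5)
  vals <- sapply(gains, function(g) {
    m <- mock; m$loglik_null <- -20 - g; cox_snell_r2(m)
  })
  expect_true(all(diff(vals) > 0))
  # real fit: value in [0, 1)
  d <- rand_surv_data(4)
  r2 <- cox_snell_r2(cox_fit(d, "g"))
  expect_gte(r2, 0)
  expect_lt(r2, 1)
})

test_that("proportional-hazards check is calibrated under exact PH", {
  reject <- logical(200)
  for (s in 1:200) {
    cfg <- simulation_config(effects = list(diet = c(AL = 0, DR = -0.4)),
                             n_per_cell = 63L, cohorts = 1L, seed = 1000L + s)
    ds <- simulate_lifespans(cfg)
    sub <- ds[ds$genotype == "CantonS" & ds$sex == "F" & ds$lab == "Hoffman", ]
    fit <- cox_fit(sub, "diet")
    z <- ph_test(fit)
    expect_gte(z$table$p, 0)
    expect_lte(z$table$p, 1)
    reject[s] <- z$table$p < 0.05
  }
  # under the null the rejection rate should sit inside a 99.9% binomial
  # band around 0.05 (1..21 rejections out of 200)
  expect_gte(sum(reject), qbinom(0.0005, 200, 0.05))
  expect_lte(sum(reject), qbinom(0.9995, 200, 0.05))
})

test_that("proportional-hazards check detects crossing hazards", {
  hits <- 0L
  for (s in 1:100) {
    cfg <- simulation_config(
      effects = list(diet = c(AL = 0, DR = 0.8)),
      n_per_cell = 63L, cohorts = 1L, seed = 3000L + s,
      tv_flip = list(factor = "diet", level = "DR", time = 54))
    ds <- simulate_lifespans(cfg)
    sub <- ds[ds$genotype == "CantonS" & ds$sex == "F" & ds$lab == "Hoffman", ]
    fit <- cox_fit(sub, "diet")
    if (ph_test(fit)$table$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits, 50L)
})

test_that("ph_test refuses unusable fits", {
  d <- data.frame(age_days = c(3, 9), event = c(1L, 1L),
                  arm = c("x", "y"))
  fit <- cox_fit(d, "arm")
  expect_error(ph_test(fit), "fewer than 3 events")
})
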