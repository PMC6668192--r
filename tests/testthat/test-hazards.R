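test_that("baseline hazards follow their defining formulas", {
  expect_equal(baseline_hazard(c(0.1, 3, 7), "constant"), c(1, 1, 1))
  expect_equal(baseline_hazard(0.5, "weibull"), 1)
  expect_equal(baseline_hazard(c(1, 2), "weibull"), c(2, 4))
  expect_equal(baseline_hazard(1, "plausible"), exp(-18 + 7.3 + 9.5),
               tolerance = 1e-12) # log(1) = 0 kills the sqrt(t)log(t) term
  expect_equal(baseline_hazard(0, "plausible"), exp(-18), tolerance = 1e-12)
  expect_error(baseline_hazard(-1, "constant"),
               class = "crconfound_invalid_parameter")
})

test_that("cumulative baseline matches closed forms and an independent quadrature", {
  expect_equal(cumulative_baseline(3, "constant"), 3)
  expect_equal(cumulative_baseline(3, "weibull"), 9)
  expect_equal(cumulative_baseline(0, "plausible"), 0)
  # independent oracle: fine-grid trapezoid of the printed hazard
  for (tt in c(0.3, 1, 2.5)) {
    s <- seq(0, tt, length.out = 400001L)
    lam <- baseline_hazard(s, "plausible")
    trap <- sum((lam[-1] + lam[-length(lam)]) / 2) * (s[2] - s[1])
    expect_equal(cumulative_baseline(tt, "plausible"), trap,
                 tolerance = 1e-6)
  }
  # strictly increasing
  tg <- exp(seq(log(1e-3), log(15), length.out = 60))
  expect_true(all(diff(cumulative_baseline(tg, "plausible")) > 0))
})

test_that("inverse cumulative baseline round-trips all kinds", {
  expect_equal(inverse_cumulative_baseline(4, "weibull"), 2)
  expect_equal(inverse_cumulative_baseline(0, "plausible"), 0)
  tt <- exp(seq(log(1e-3), log(20), length.out = 100))
  for (kind in c("constant", "weibull", "plausible")) {
    back <- inverse_cumulative_baseline(cumulative_baseline(tt, kind), kind)
    expect_lt(max(abs(back - tt) / tt), 1e-8)
  }
  # and the other direction, across many orders of magnitude
  hh <- exp(seq(log(1e-8), log(100), length.out = 50))
  fwd <- cumulative_baseline(inverse_cumulative_baseline(hh, "plausible"),
                             "plausible")
  expect_lt(max(abs(fwd - hh) / hh), 1e-8)
})

test_that("null-effect simulations recover exponential times and cause shares", {
  pop <- tibble::tibble(u = rnorm(1e5), z = rep(0:1, 5e4))
  sim <- simulate_events(pop, hazard_params(), seed = 1) # k = 1, constant
  expect_true(all(sim$t > 0))
  expect_true(all(sim$delta %in% c(1L, 2L)))
  # total rate 2 => mean T = 0.5; P(delta = 1) = 1/2
  expect_lt(abs(mean(sim$t) - 0.5) / 0.5, 4 / sqrt(1e5))
  expect_lt(abs(mean(sim$delta == 1) - 0.5), 4 * 0.5 / sqrt(1e5))
  sim2 <- simulate_events(pop, hazard_params(k = 2), seed = 2)
  expect_lt(abs(mean(sim2$delta == 1) - 2 / 3), 4 * 0.5 / sqrt(1e5))
  # Weibull: H0(t) = t^2, so T^2 ~ Exponential(2)
  simw <- simulate_events(pop, hazard_params(baseline = "weibull"), seed = 3)
  ks <- suppressWarnings(stats::ks.test(simw$t^2, "pexp", rate = 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("all-cause cumulative hazard transform is Exponential(1) under confounding", {
  hp <- hazard_params(beta1 = -1, gamma1 = -1, gamma2 = 1,
                      baseline = "weibull")
  pop <- generate_confounded_covariates(1e5, rho = 0.4, pi = 0.5, seed = 5)
  sim <- simulate_events(pop, hp, seed = 6)
  a <- hp$k * exp(hp$beta1 * sim$u + hp$gamma1 * sim$z) +
    exp(hp$beta2 * sim$u + hp$gamma2 * sim$z)
  ks <- suppressWarnings(
    stats::ks.test(a * cumulative_baseline(sim$t, "weibull"), "pexp", rate = 1)
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("cause assignment matches the analytic cause ratio per subject", {
  # beta1 = 1, U = 1, Z = 0, k = 1, beta2 = 0: P(delta = 1) = e/(e + 1)
  pop <- tibble::tibble(u = rep(1, 4e4), z = rep(0L, 4e4))
  sim <- simulate_events(pop, hazard_params(beta1 = 1), seed = 9)
  p <- exp(1) / (exp(1) + 1)
  expect_lt(abs(mean(sim$delta == 1) - p), 4 * sqrt(p * (1 - p) / 4e4))
})

test_that("event ranks and types are invariant to the baseline kind", {
  pop <- generate_confounded_covariates(3000, rho = 0.4, pi = 0.5, seed = 11)
  hps <- lapply(c("constant", "weibull", "plausible"),
                function(kk) hazard_params(beta1 = 1, gamma1 = -1, baseline = kk))
  sims <- lapply(hps, function(hp) simulate_events(pop, hp, seed = 12))
  for (i in 2:3) {
    expect_identical(sims[[i]]$delta, sims[[1]]$delta)
    expect_identical(order(sims[[i]]$t), order(sims[[1]]$t))
  }
})

test_that("raising gamma1 shifts treated subjects toward the event of interest", {
  pop <- generate_confounded_covariates(20000, rho = 0, pi = 0.5, seed = 13)
  frac1 <- vapply(c(-1, 0, 1), function(g1) {
    sim <- simulate_events(pop, hazard_params(gamma1 = g1), seed = 14)
    mean(sim$delta[sim$z == 1] == 1)
  }, numeric(1))
  expect_true(all(diff(frac1) > 0))
})
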