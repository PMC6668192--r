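test_that("worked six-subject dataset matches the brute-force likelihood oracle", {
  d <- worked_sample()
  # event-2 cause-specific is separated on this tiny set (its only late
  # event has no treated subject at risk), so the finite-MLE combinations
  # are Cox for event 1 and Fine-Gray for both events
  combos <- list(c("cause_specific", 1), c("subdistribution", 1),
                 c("subdistribution", 2))
  for (cm in combos) {
    model <- cm[[1]]; ev <- as.integer(cm[[2]])
    fitfun <- if (model == "cause_specific") cox_cause_specific else fine_gray
    fit <- fitfun(d, event = ev)
    oracle <- brute_force_coef(d$t, d$delta, d$z, ev, model)
    expect_equal(fit$coef, oracle, tolerance = 1e-6)
    expect_true(fit$converged)
    expect_gt(fit$se, 0)
  }
  # the subdistribution risk set retains competing-event subjects, so the
  # two models genuinely differ on this dataset
  expect_gt(abs(fine_gray(d, 1)$coef - cox_cause_specific(d, 1)$coef), 1e-3)
})

test_that("both fitters match brute-force maximisation on random small datasets", {
  set.seed(2024)
  for (i in 1:20) {
    d <- random_small_sample(n = sample(6:12, 1))
    ev <- sample(1:2, 1)
    expect_equal(cox_cause_specific(d, ev)$coef,
                 brute_force_coef(d$t, d$delta, d$z, ev, "cause_specific"),
                 tolerance = 1e-6)
    expect_equal(fine_gray(d, ev)$coef,
                 brute_force_coef(d$t, d$delta, d$z, ev, "subdistribution"),
                 tolerance = 1e-6)
  }
})

test_that("estimates agree with survival and cmprsk on random datasets", {
  skip_if_not_installed("survival")
  skip_if_not_installed("cmprsk")
  set.seed(77)
  for (i in 1:20) {
    d <- random_small_sample(n = sample(8:12, 1))
    ev <- sample(1:2, 1)
    cph <- survival::coxph(
      survival::Surv(t, delta == ev) ~ z, data = d, ties = "breslow",
      control = survival::coxph.control(eps = 1e-12, toler.chol = 1e-14,
                                        iter.max = 100)
    )
    expect_equal(cox_cause_specific(d, ev)$coef, unname(coef(cph)),
                 tolerance = 1e-6)
    fg <- cmprsk::crr(d$t, d$delta, cov1 = matrix(d$z), failcode = ev,
                      cencode = 0, gtol = 1e-12)
    expect_equal(fine_gray(d, ev)$coef, unname(fg$coef), tolerance = 1e-5)
  }
})

test_that("model-based standard errors match the survival package", {
  skip_if_not_installed("survival")
  hp <- hazard_params(beta1 = 1, gamma1 = -0.5)
  d <- sim_population(2000, rho = 0.2, pi = 0.5, hp, seed = 31)
  fit <- cox_cause_specific(d, 1)
  cph <- survival::coxph(survival::Surv(t, delta == 1) ~ z, data = d,
                         ties = "breslow")
  expect_equal(fit$se, sqrt(vcov(cph)[1, 1]), tolerance = 1e-6)
})

test_that("Fine-Gray equals Cox exactly when no competing events exist", {
  d <- random_small_sample(12)
  d$delta <- rep(1L, 12)
  expect_identical(fine_gray(d, 1)$coef, cox_cause_specific(d, 1)$coef)
  # and removing the competing events changes the subdistribution fit
  d2 <- worked_sample()
  full <- fine_gray(d2, 1)$coef
  dropped <- fine_gray(d2[d2$delta == 1, ], 1)$coef
  expect_gt(abs(full - dropped), 1e-6)
})

test_that("degenerate inputs raise classed errors", {
  d <- worked_sample()
  d_one_arm <- d
  d_one_arm$z <- rep(1L, 6)
  expect_error(cox_cause_specific(d_one_arm, 1),
               class = "crconfound_non_identifiable")
  d_no_ev <- d
  d_no_ev$delta <- rep(2L, 6)
  expect_error(cox_cause_specific(d_no_ev, 1),
               class = "crconfound_degenerate_data")
  expect_error(fine_gray(d_no_ev, 1), class = "crconfound_degenerate_data")
  d_bad <- d
  d_bad$delta[1] <- 0L
  expect_error(fine_gray(d_bad, 1), class = "crconfound_invalid_parameter")
})

test_that("tied event times are handled by the Breslow approximation", {
  skip_if_not_installed("survival")
  set.seed(5)
  d <- tibble::tibble(
    t = rep(c(1, 2, 3, 4), each = 3),
    delta = sample(c(1L, 2L), 12, replace = TRUE),
    z = rep(c(0L, 1L, 1L), 4)
  )
  if (!1L %in% d$delta) d$delta[1] <- 1L
  cph <- survival::coxph(survival::Surv(t, delta == 1) ~ z, data = d,
                         ties = "breslow",
                         control = survival::coxph.control(eps = 1e-12, toler.chol = 1e-14))
  expect_equal(cox_cause_specific(d, 1)$coef, unname(coef(cph)),
               tolerance = 1e-8)
  expect_equal(fine_gray(d, 1)$coef,
               brute_force_coef(d$t, d$delta, d$z, 1, "subdistribution"),
               tolerance = 1e-6)
})

test_that("unconfounded large-sample fit recovers the prescribed effect", {
  hp <- hazard_params(gamma1 = -1) # beta1 = beta2 = gamma2 = 0, k = 1
  d <- sim_population(50000, rho = 0, pi = 0.5, hp, seed = 101)
  fit <- cox_cause_specific(d, 1)
  expect_lt(abs(fit$coef - (-1)), 3 * fit$se)
  # null setting: both Fine-Gray effects within 3 SE of zero
  d0 <- sim_population(50000, rho = 0, pi = 0.5, hazard_params(), seed = 103)
  for (ev in 1:2) {
    f <- fine_gray(d0, ev)
    expect_lt(abs(f$coef), 3 * f$se)
  }
})

test_that("tidy and glance return well-formed summaries", {
  d <- worked_sample()
  fit <- fine_gray(d, 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate, fit$coef)
  gl <- glance(fit)
  expect_identical(gl$model, "subdistribution")
  expect_identical(gl$n, 6L)
  expect_true(gl$converged)
})
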