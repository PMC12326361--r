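test_that("linear_fit matches the closed-form normal equations", {
  set.seed(11)
  xs <- runif(50, -3, 5)
  ys <- 1.7 - 0.4 * xs + rnorm(50, 0, 0.3)
  lf <- linear_fit(xs, ys)
  # independent closed-form OLS oracle
  n <- length(xs)
  sxx <- sum((xs - mean(xs))^2)
  b <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
  a <- mean(ys) - b * mean(xs)
  res <- ys - a - b * xs
  s2 <- sum(res^2) / (n - 2)
  expect_equal(lf$slope, b, tolerance = 1e-10)
  expect_equal(lf$intercept, a, tolerance = 1e-10)
  expect_equal(lf$se_slope, sqrt(s2 / sxx), tolerance = 1e-10)
  expect_equal(lf$se_intercept, sqrt(s2 * (1 / n + mean(xs)^2 / sxx)),
               tolerance = 1e-10)
  expect_equal(lf$r_squared,
               1 - sum(res^2) / sum((ys - mean(ys))^2), tolerance = 1e-10)

  exact <- linear_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$r_squared, 1)
  expect_error(linear_fit(c(0, 1), c(1, 2)), "at least 3")
  expect_error(linear_fit(rep(2, 4), 1:4), "degenerate")
})

test_that("both methods recover the configured log K_OW on noise-free data", {
  for (case in list(list("acid", 4.18, 3), list("base", 7.92, 1.5))) {
    sol <- solute("x", case[[1]], case[[2]])
    truth <- case[[3]]
    sys <- biphasic_system(P_neutral_0 = 10^truth)
    ser <- simulate(sys, seed = 1, solute = sol, noise = noise_model(0, 0))
    f1 <- fit_method1(ser)
    f2 <- fit_method2(ser)
    expect_equal(f1$log_value, truth, tolerance = 0.02)
    expect_equal(f2$log_value, truth, tolerance = 1e-6)
    # with no concentration dependence the two routes estimate one limit
    expect_lt(abs(f1$log_value - f2$log_value), 0.02)
    # method 1's intermediate equals the closed-form D_OW within fit slack
    expect_equal(f1$intermediate_logDow,
                 log10(closed_form_dow(sol, 10^truth)), tolerance = 0.02)
  }
})

test_that("method 2 tracks a concentration-dependent partition coefficient", {
  # simulated neutral series with a known slope on the log10 scale
  sys <- biphasic_system(P_neutral_0 = 10^2, conc_slope_s = 0.5)
  ser <- simulate(sys, seed = 1, solute = griseofulvin,
                  c_total_grid = c(1e-3, 3e-3, 6e-3, 1e-2),
                  noise = noise_model(0, 0))
  f <- fit_logp_vs_conc(ser)
  expect_equal(f$log_value, 2, tolerance = 0.02)
  expect_equal(f$fit_slope, 0.5, tolerance = 0.02)
})

test_that("flat neutral data give intercept equal to the constant log P", {
  f <- fit_logp_vs_conc(flat_neutral_series(logP = 1.34))
  expect_equal(f$log_value, 1.34, tolerance = 1e-9)
  expect_equal(f$fit_slope, 0, tolerance = 1e-9)
})

test_that("estimates are invariant under measurement reordering", {
  sys <- biphasic_system(P_neutral_0 = 10^2.6)
  ser <- simulate(sys, seed = 3, solute = ibuprofen)
  perm <- c(3, 1, 4, 2)
  ser_perm <- measurement_series(ser$solute, ser$measurements[perm, ],
                                 ser$volume_ratio_org_to_aq,
                                 ser$ionic_strength)
  for (f in list(fit_method1, fit_method2)) {
    expect_equal(f(ser)$log_value, f(ser_perm)$log_value, tolerance = 1e-12)
    expect_equal(f(ser)$std_error, f(ser_perm)$std_error, tolerance = 1e-12)
  }
})

test_that("degenerate and undersized series are rejected with clear errors", {
  two <- make_series(naproxen, c(1e-3, 2e-3), c(1e-2, 1.1e-2),
                     c(1e-3, 1e-3), pH = c(4.5, 4.4))
  expect_error(fit_method1(two), "at least 3")
  same_ph <- make_series(naproxen, c(1e-3, 2e-3, 3e-3),
                         c(1e-2, 1.1e-2, 1.2e-2), c(1e-3, 1e-3, 1e-3),
                         pH = c(4.5, 4.5, 4.5))
  expect_error(fit_method1(same_ph), "degenerate")
  dup_c <- make_series(naproxen, c(1e-3, 1e-3, 1e-3),
                       c(1e-2, 1.1e-2, 1.2e-2), c(1e-3, 1e-3, 1e-3),
                       pH = c(4.5, 4.4, 4.3))
  expect_error(fit_method2(dup_c), "distinct")
  expect_error(fit_method1(flat_neutral_series()), "unsupported")
  expect_error(fit_method2(flat_neutral_series()), "ionizable")
  expect_warning(fit_logp_vs_conc(simulate(biphasic_system(), seed = 1,
                                           solute = naproxen)),
                 "preferred")
})

test_that("span warning fires when extrapolating beyond the data range", {
  # pH data far from 7 and narrow: distance to 7 exceeds the span
  narrow <- make_series(naproxen, c(1e-3, 2e-3, 3e-3, 4e-3),
                        c_org = 10^c(2.50, 2.45, 2.40, 2.35) * 1e-3,
                        c_aq = rep(1e-3, 4), pH = c(4.0, 4.2, 4.4, 4.6))
  expect_true(fit_method1(narrow)$extrapolation_span_warning)
  wide <- simulate(biphasic_system(P_neutral_0 = 1e3), seed = 1,
                   solute = naproxen,
                   c_total_grid = 10^seq(-6, -2, length.out = 5),
                   noise = noise_model(0, 0))
  expect_false(fit_method1(wide)$extrapolation_span_warning)
})

test_that("replicate standard deviations switch on inverse-variance weights", {
  sys <- biphasic_system(P_neutral_0 = 1e3)
  ser <- simulate(sys, seed = 5, solute = naproxen,
                  noise = noise_model(0.05, 0.02))
  m <- ser$measurements
  m$c_org_sd <- 0.05 * m$c_org
  m$c_aq_sd <- 0.05 * m$c_aq
  weighted <- measurement_series(ser$solute, m, ser$volume_ratio_org_to_aq)
  fw <- fit_method1(weighted)
  fu <- fit_method1(ser)
  expect_false(is.null(fw$fit$weights))
  expect_true(is.null(fu$fit$weights))
  # equal relative sds mean equal weights: same point estimate
  expect_equal(fw$log_value, fu$log_value, tolerance = 1e-9)
})

test_that("kow_fit objects support the standard modelling verbs", {
  ser <- simulate(biphasic_system(P_neutral_0 = 1e3), seed = 2,
                  solute = naproxen)
  f <- kow_fit(ser)                       # auto -> pH extrapolation
  expect_identical(f$method, "ph_extrapolation")
  expect_named(coef(f), c("log_KOW", "intercept", "slope"))
  expect_length(residuals(f), 4L)
  expect_equal(sum(residuals(f)), 0, tolerance = 1e-9)
  # predict at pH 7 reproduces the intermediate log D_OW
  expect_equal(predict(f, newdata = 7), f$intermediate_logDow)
  ci <- confint(f)
  expect_true(ci[1] < f$log_value && f$log_value < ci[2])
  expect_output(print(f), "pH extrapolation")
  expect_output(print(summary(f)), "OECD QC")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
  # neutral series auto-routes to the concentration extrapolation
  expect_identical(kow_fit(flat_neutral_series())$method,
                   "conc_extrapolation")
})
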