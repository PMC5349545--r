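test_that("noiseless logistic3 data are recovered to 6+ significant digits", {
  cv <- make_logistic3_curve(e_max = 1, n = 1, ec50 = 1e-7)
  f <- fit_logistic3(cv)
  expect_sigdigits(f$par[["e_max"]], 1)
  expect_sigdigits(f$par[["slope_n"]], 1)
  expect_sigdigits(exp(f$par[["ln_ec50"]]), 1e-7)

  # linear scale equivariance: responses x0.5 halves e_max only
  cv2 <- cv; cv2$resp <- cv$resp * 0.5
  f2 <- fit_logistic3(cv2)
  expect_sigdigits(f2$par[["e_max"]], 0.5)
  expect_sigdigits(f2$par[["slope_n"]], 1)
  expect_sigdigits(exp(f2$par[["ln_ec50"]]), 1e-7)

  # steep curve: slope recovered, fitted response at EC50 is E_max/2
  cv3 <- make_logistic3_curve(e_max = 0.8, n = 2, ec50 = 3e-8)
  f3 <- fit_logistic3(cv3)
  expect_sigdigits(f3$par[["slope_n"]], 2)
  expect_equal(predict(f3, exp(f3$par[["ln_ec50"]])),
               f3$par[["e_max"]] / 2, tolerance = 1e-9)
})

test_that("monotone-decreasing data are rejected", {
  conc <- 10^seq(-9, -5, length.out = 6)
  resp <- rev(1 / (1 + 1e-7 / conc))
  expect_error(fit_logistic3(cr_curve("ANT", "A", conc, resp)),
               "monotone decreasing")
})

test_that("logistic2 recovers noiseless parameters and its band shrinks with noise", {
  cv <- make_logistic3_curve(e_max = 1, n = 1, ec50 = 1e-8,
                             conc = 10^seq(-11, -5, length.out = 9))
  f <- fit_logistic2(cv)
  expect_sigdigits(exp(f$par[["ln_c"]]), 1e-8)
  expect_sigdigits(f$par[["slope_b"]], 1)
  # noiseless fit: asymptotic band collapses
  bd <- f$band(c(1e-9, 1e-8, 1e-7))
  expect_lt(max(bd$upper - bd$lower), 1e-10)
  # noisy fit: band at the EC50 is finite and wider
  set.seed(5)
  cvn <- cv; cvn$resp <- cv$resp + rnorm(length(cv$resp), 0, 0.03)
  cvn$resp_sd <- rep(0.03, length(cv$resp))
  fn <- fit_logistic2(cvn)
  bdn <- fn$band(1e-8)
  expect_gt(bdn$upper - bdn$lower, 1e-3)
})

test_that("logistic2 band has near-nominal pointwise coverage", {
  # 500 simulated refits; the 95% band at the true EC50 should contain the
  # true half-maximal response in roughly 95% of repeats
  conc <- 10^seq(-11, -5, length.out = 9)
  mu <- 1 / (1 + 1e-8 / conc)
  set.seed(11)
  cover <- logical(500)
  for (i in seq_along(cover)) {
    cv <- cr_curve("REF", "A", conc, mu + rnorm(length(mu), 0, 0.04),
                   rep(0.04, length(mu)))
    f <- fit_logistic2(cv)
    bd <- f$band(1e-8)
    cover[i] <- bd$lower <= 0.5 && 0.5 <= bd$upper
  }
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("operational model: noiseless recovery, saturation limit, EC50 identity", {
  cv <- make_operational_curve(r_max = 1, n = 1, tau = 10, kd = 1e-6)
  f <- fit_operational(cv, kd = 1e-6)
  expect_sigdigits(exp(f$par[["ln_tau"]]), 10)
  expect_sigdigits(f$par[["r_max"]], 1)

  # tau -> infinity: plateau approaches r_max
  cvh <- make_operational_curve(tau = 1e4, kd = 1e-6,
                                conc = 10^seq(-12, -3, length.out = 10))
  fh <- fit_logistic3(cvh)
  expect_lt(abs(fh$par[["e_max"]] - 1), 1e-3)

  # at n = 1 the fitted curve's midpoint sits at Kd/(1+tau)
  ec50_imp <- 1e-6 / (1 + exp(f$par[["ln_tau"]]))
  emax_fit <- f$par[["r_max"]] * exp(f$par[["ln_tau"]]) /
    (1 + exp(f$par[["ln_tau"]]))
  expect_equal(predict(f, ec50_imp), emax_fit / 2, tolerance = 1e-9)
})

test_that("free-Kd operational fit converges and reports the tau/Kd composite", {
  cv <- make_operational_curve(r_max = 1, n = 1, tau = 0.5, kd = 1e-6)
  f <- fit_operational(cv)   # partial agonist: composite well-defined
  expect_true(is.finite(f$ln_tau_over_kd))
  expect_gt(f$se_ln_tau_over_kd, 0)
  # pinning the system maximum makes the composite exact for any ligand
  fp <- fit_operational(cv, r_max = 1)
  expect_equal(fp$ln_tau_over_kd, log(0.5 / 1e-6), tolerance = 1e-5)
})

test_that("a fixed Kd far below the tested range warns", {
  cv <- make_operational_curve(kd = 1e-6, conc = 10^seq(-7, -3, length.out = 8))
  expect_warning(fit_operational(cv, kd = 1e-12), "1000-fold")
})

test_that("inverse_response is the closed-form inverse of the fitted logistic", {
  f <- fit_logistic3(make_logistic3_curve(e_max = 0.9, n = 1, ec50 = 1e-7))
  expect_equal(inverse_response(f, 0.45), 1e-7, tolerance = 1e-9)
  expect_equal(inverse_response(f, 0.9 * 0.9), 9e-7, tolerance = 1e-8)
  set.seed(2)
  levels <- runif(100, 1e-3, 0.9 - 1e-3)
  round_trip <- predict(f, inverse_response(f, levels))
  expect_equal(round_trip, levels, tolerance = 1e-12)
  expect_error(inverse_response(f, 0.95), "out of range")
})

test_that("parameter RMSE shrinks with more points per curve", {
  set.seed(23)
  rmse_for <- function(npts) {
    conc <- 10^seq(-10, -4, length.out = npts)
    mu <- 1 / (1 + 1e-7 / conc)
    errs <- replicate(60, {
      cv <- cr_curve("L", "A", conc, mu + rnorm(npts, 0, 0.05))
      f <- fit_logistic3(cv)
      f$par[["ln_ec50"]] - log(1e-7)
    })
    sqrt(mean(errs^2))
  }
  expect_lt(rmse_for(32), rmse_for(8))
})
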