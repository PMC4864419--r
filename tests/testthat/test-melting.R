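test_that("the two-state model is anchored at alpha(Tm) = 1/2", {
  a <- ptdna:::two_state_alpha(76.55, 76.55, 300, 3e-4)
  expect_equal(a, 0.5, tolerance = 1e-12)
  # alpha decreases with temperature (melting)
  Ts <- seq(40, 95, 1)
  a <- ptdna:::two_state_alpha(Ts, 76.55, 300, 3e-4)
  expect_true(all(diff(a) < 0))
  expect_gt(a[1], 0.99)
})

test_that("the noiseless curve area equals the generating enthalpy", {
  cu <- simulate_dsc_curve(76.55, 300, grid = seq(25, 120, 0.2))
  expect_equal(integrate_enthalpy(cu), 300, tolerance = 300 * 1e-3)
  # dS consistency: dH / Tm(K) for a sharp transition
  expect_equal(integrate_entropy(cu), 300 / (76.55 + 273.15),
               tolerance = 0.01)
  # zero curve integrates to zero
  z <- cu; z$dCp <- 0
  expect_equal(integrate_enthalpy(z), 0)
  expect_equal(integrate_entropy(z), 0)
  # the bimolecular model peak follows the anchored Tm by roughly
  # R*Tm^2/(2.6*dH); within 2 C for dH >= 200 and shrinking with dH
  shifts <- vapply(c(200, 300, 450), function(dh) {
    cc <- simulate_dsc_curve(70, dh, grid = seq(30, 110, 0.1))
    cc$T_C[which.max(cc$dCp)] - 70
  }, numeric(1))
  expect_true(all(shifts > 0 & shifts < 2))
  expect_true(all(diff(shifts) < 0))
})

test_that("simulation is reproducible under a fixed seed", {
  c1 <- simulate_dsc_curve(76.55, 300, noise_sd = 0.1, seed = 7)
  c2 <- simulate_dsc_curve(76.55, 300, noise_sd = 0.1, seed = 7)
  expect_identical(c1$dCp, c2$dCp)
  c3 <- simulate_dsc_curve(76.55, 300, noise_sd = 0.1, seed = 8)
  expect_false(identical(c1$dCp, c3$dCp))
  expect_error(simulate_dsc_curve(200, 300), "cover")
  expect_error(simulate_dsc_curve(76, -5), "positive")
})

test_that("two-state fits recover generating parameters", {
  cu <- simulate_dsc_curve(76.55, 300, seed = 1)
  fit <- fit_two_state(cu)
  expect_s3_class(fit, "melt_fit")
  expect_equal(fit$tm, 76.55, tolerance = 0.05)
  expect_equal(fit$dh_vh, 300, tolerance = 1)
  expect_equal(unname(coef(fit)["tm"]), fit$tm)
  expect_equal(length(residuals(fit)), nrow(cu))

  # with a linear baseline and noise
  cu2 <- simulate_dsc_curve(71.99, 320, baseline = c(0.5, 0.01),
                            noise_sd = 0.2, seed = 3)
  fit2 <- fit_two_state(cu2)
  expect_equal(fit2$tm, 71.99, tolerance = 0.2)
  expect_equal(fit2$baseline[1], 0.5, tolerance = 0.2)
})

test_that("fitted Tm difference reproduces the destabilization shift", {
  fit_hi <- fit_two_state(simulate_dsc_curve(76.55, 300))
  fit_lo <- fit_two_state(simulate_dsc_curve(71.99, 300))
  expect_equal(fit_hi$tm - fit_lo$tm, 4.56, tolerance = 0.05)
})

test_that("noisy fits are unbiased over seeded replicates", {
  cu0 <- simulate_dsc_curve(76.55, 300)
  noise <- 0.02 * max(cu0$dCp)
  tms <- vapply(1:20, function(s)
    fit_two_state(simulate_dsc_curve(76.55, 300, noise_sd = noise,
                                     seed = s))$tm, numeric(1))
  dhs <- vapply(1:20, function(s)
    fit_two_state(simulate_dsc_curve(76.55, 300, noise_sd = noise,
                                     seed = s))$dh_vh, numeric(1))
  expect_lt(abs(mean(tms) - 76.55), 0.1)
  expect_lt(abs(mean(dhs) - 300) / 300, 0.03)
})

test_that("non-two-state curves are rejected", {
  c1 <- simulate_dsc_curve(60, 400, grid = seq(25, 95, 0.2))
  c2 <- simulate_dsc_curve(80, 400, grid = seq(25, 95, 0.2))
  two_peak <- c1
  two_peak$dCp <- c1$dCp + c2$dCp
  expect_error(fit_two_state(two_peak), "multiple peaks|two-state")
  flat <- c1; flat$dCp <- -abs(flat$dCp)
  expect_error(fit_two_state(flat), "no melting peak")
})

test_that("the default strand concentration reflects the duplex load", {
  ct <- default_ct()
  # 0.9 mg/ml of a ~6.2 kDa decamer duplex, two strands per duplex
  expect_gt(ct, 2e-4); expect_lt(ct, 4e-4)
})
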