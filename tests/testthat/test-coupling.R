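test_that("the Karplus relationship evaluates and is even in theta", {
  expect_equal(karplus_j(90, karplus_hh()), 0)         # C = 0 for HH set
  expect_equal(karplus_j(90, karplus_hp()), 1.5)       # C term only
  expect_equal(karplus_j(180, karplus_hh()), 11.0)     # A + |B|
  th <- seq(-180, 180, 7.5)
  expect_equal(karplus_j(th, karplus_hh()), karplus_j(-th, karplus_hh()))
  expect_error(karplus_params(-1, 0, 0), "A > 0")
})

test_that("pseudorotation forward/inverse is an exact round trip", {
  expect_equal(unname(pucker_to_endocyclic(0, 35)["nu2"]), 35)
  expect_equal(unname(pucker_to_endocyclic(162, 35)["nu2"]),
               35 * cos(162 * pi / 180))
  # machine-precision round trip over a (P, phi) lattice
  for (P in seq(0, 350, 10)) for (phi in seq(25, 45, 5)) {
    pk <- endocyclic_to_pucker(pucker_to_endocyclic(P, phi))
    expect_false(pk$degenerate)
    expect_equal(pk$P, P, tolerance = 1e-9)
    expect_equal(pk$phi_m, phi, tolerance = 1e-9)
  }
  # planar ring is flagged, not silently inverted
  expect_true(endocyclic_to_pucker(rep(0, 5))$degenerate)
})

test_that("predicted couplings separate S-type from N-type sugars", {
  jS <- predict_sugar_couplings(162, 35)
  jN <- predict_sugar_couplings(18, 38)
  expect_gte(jS[["J_H1'H2'"]] - jN[["J_H1'H2'"]], 5)
  expect_gte(jS[["J_H1'H2'"]], 8)
  for (phi in seq(26, 44, 3))
    expect_gt(predict_sugar_couplings(162, phi)[["J_H1'H2'"]],
              predict_sugar_couplings(18, phi)[["J_H1'H2'"]])
  # degenerate amplitude still yields finite couplings
  expect_true(all(is.finite(predict_sugar_couplings(162, 0))))
})

test_that("pucker estimation recovers generating parameters", {
  # noiseless: grid-resolution recovery
  fit <- estimate_pucker(predict_sugar_couplings(160, 36))
  expect_equal(fit$P, 160, tolerance = 1)
  expect_equal(fit$phi_m, 36, tolerance = 0.5)
  expect_lt(fit$rss, 1e-3)

  # noisy (0.5 Hz sd): phase recovered within 10 degrees on average over a
  # fixed seed set (single draws can land further; the grid LSQ is the MLE
  # and inherits the noise dispersion)
  for (P0 in c(90, 162, 200)) {
    errs <- vapply(1:10, function(s) {
      set.seed(s)
      j <- predict_sugar_couplings(P0, 36) + stats::rnorm(4, 0, 0.5)
      abs(estimate_pucker(j)$P - P0)
    }, numeric(1))
    expect_lt(mean(errs), 10)
  }

  expect_error(estimate_pucker(c("J_H1'H2'" = 9)), "at least two")
})

test_that("backbone torsion restraints follow the B-DNA conventions", {
  hp <- karplus_hp()
  # J at the curve maximum inverts to theta = 180
  jmax <- karplus_j(180, hp)
  e <- epsilon_from_j(jmax, hp)
  expect_equal(e$center, 60, tolerance = 1e-6)   # 180 - 120, no B branch
  # J = C corresponds to theta = 90; the -120 shift and branch selection
  # land epsilon in the B-DNA region
  e90 <- epsilon_from_j(hp$C, hp)
  expect_true(e90$center >= 150 || e90$center <= -120)
  expect_error(epsilon_from_j(25, hp), "exceeds")
  expect_error(epsilon_from_j(-1, hp), "non-negative")

  z <- zeta_from_epsilon(-175)
  expect_equal(z$center, -85)
  z2 <- zeta_from_epsilon(-145, width = 30)
  expect_equal(c(z2$lower, z2$upper), c(-85, -25))
  expect_error(zeta_from_epsilon(0), "outside")

  b <- beta_classify(3)
  expect_equal(b$center, 180)
  expect_identical(beta_classify(10), "unclassified")
  expect_error(beta_classify(-1), "non-negative")

  # all emitted restraints live in (-180, 180] with positive width
  for (J in c(1, 4, 8, 12)) {
    e <- epsilon_from_j(J, hp)
    expect_true(e$center > -180 - 1e-9 && e$center <= 180)
    expect_gt(e$width, 0)
  }
})

test_that("coupling tables yield per-residue pucker reports", {
  tab <- do.call(rbind, lapply(1:3, function(r) {
    j <- predict_sugar_couplings(150 + 5 * r, 36)
    data.frame(residue = r, J_name = names(j), value_Hz = unname(j))
  }))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  rep <- pucker_report(path)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$P, 150 + 5 * (1:3), tolerance = 1)
  expect_true(all(rep$type == "S"))
})
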