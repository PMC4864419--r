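test_that("superposition recovers rigid motions exactly", {
  tmpl <- fixture_template("none")
  expect_equal(superpose(tmpl, tmpl)$rmsd, 0, tolerance = 1e-12)
  moved <- random_rigid(tmpl, seed = 11)
  expect_lt(superpose(moved, tmpl)$rmsd, 1e-9)
  expect_lt(superpose(moved, tmpl, "heavy")$rmsd, 1e-9)
})

test_that("superposition matches a brute-force rotation-grid oracle", {
  # small asymmetric cloud with one displaced atom
  set.seed(3)
  ref <- matrix(stats::runif(15, -3, 3), 5, 3)
  mob <- ref
  mob[5, 1] <- mob[5, 1] + 1
  mk <- function(xyz) {
    ptdna:::as_structure_model(data.frame(
      atom = paste0("C", 1:5), element = "C", resno = 1:5, resname = "DG",
      chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  }
  got <- superpose(mk(mob), mk(ref), "heavy")$rmsd

  # oracle: exhaustive Euler-angle grid after centroid alignment
  cref <- sweep(ref, 2, colMeans(ref)); cmob <- sweep(mob, 2, colMeans(mob))
  ang <- seq(-pi, pi, length.out = 49)
  best <- Inf
  for (a in ang) for (b in seq(-pi / 2, pi / 2, length.out = 25)) for (c in ang) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    r <- sqrt(mean(rowSums((cmob %*% (Rz1 %*% Ry %*% Rz2) - cref)^2)))
    if (r < best) best <- r
  }
  expect_lte(got, best + 1e-9)          # Kabsch is optimal
  expect_lt(best - got, 0.03)           # within grid granularity

  # dual route: bio3d least-squares fit agrees
  xyz_fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                                             mobile = as.numeric(t(mob))))
  bio3d_rmsd <- sqrt(mean(rowSums(
    (matrix(xyz_fit, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(got, bio3d_rmsd, tolerance = 1e-6)
})

test_that("average pairwise RMSD equals brute force and is rigid-invariant", {
  tmpl <- fixture_template("none")
  ens <- synth_ensemble(tmpl, synth_config(seed = 5, n_models = 4,
                                           jitter_sd = 0.15))
  rep <- average_pairwise_rmsd(ens, "backbone")
  expect_equal(rep$matrix, t(rep$matrix))
  expect_true(all(diag(rep$matrix) == 0))

  # brute force over explicit pairs
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4)
    vals <- c(vals, superpose(ens$models[[j]], ens$models[[i]],
                              "backbone")$rmsd)
  expect_equal(rep$mean, mean(vals), tolerance = 1e-12)
  expect_equal(rep$sd, stats::sd(vals), tolerance = 1e-12)

  # rigid transform of any model leaves the report unchanged
  ens2 <- ens
  ens2$models[[2]] <- random_rigid(ens$models[[2]], seed = 9)
  rep2 <- average_pairwise_rmsd(ens2, "backbone")
  expect_equal(rep2$mean, rep$mean, tolerance = 1e-9)

  expect_error(average_pairwise_rmsd(
    structure_ensemble(ens$models[1])), "at least 2")
})

test_that("jittered ensembles reproduce the analytic RMSD expectation", {
  tmpl <- fixture_template("none")
  sigma <- 0.1
  means <- vapply(1:3, function(s) {
    ens <- synth_ensemble(tmpl, synth_config(seed = s, n_models = 6,
                                             jitter_sd = sigma))
    average_pairwise_rmsd(ens, "backbone")$mean
  }, numeric(1))
  # pairwise difference of two jittered copies: sd sqrt(2) sigma per
  # coordinate, RMSD ~ sigma sqrt(6) before the (small) fitting shrinkage;
  # model 1 is unperturbed, contributing sigma sqrt(3) pairs
  n <- 6
  w1 <- (n - 1) / choose(n, 2)          # pairs involving model 1
  expected <- w1 * sigma * sqrt(3) + (1 - w1) * sigma * sqrt(6)
  expect_equal(mean(means), expected, tolerance = 0.1 * expected)
})

test_that("cross-ensemble RMSD is zero against itself and maps sulfur", {
  rp <- fixture_template("Rp")
  free <- fixture_template("none")
  ens_rp <- synth_ensemble(rp, synth_config(seed = 2, n_models = 3,
                                            jitter_sd = 0))
  ens_free <- synth_ensemble(free, synth_config(seed = 2, n_models = 3,
                                                jitter_sd = 0))
  expect_equal(cross_ensemble_rmsd(ens_free, ens_free, mode = "model1"), 0,
               tolerance = 1e-12)
  # Rp vs PT-free templates differ only in the S/O substitution, which the
  # S2P <-> O2P mapping absorbs almost entirely
  r <- cross_ensemble_rmsd(ens_rp, ens_free, mode = "model1")
  expect_lt(r, 0.1)
  expect_gt(r, 0)
})

test_that("ensemble distances pool symmetric sites and are invariant", {
  tmpl <- fixture_template("none")
  ens <- synth_ensemble(tmpl, synth_config(seed = 8, n_models = 5,
                                           jitter_sd = 0.05))
  d1 <- ensemble_distance(ens, list(2, "H2''", 3, "O2P"))
  pooled <- ensemble_distance(ens, list(list(2, "H2''", 3, "O2P"),
                                        list(16, "H2''", 17, "O2P")))
  expect_equal(ncol(pooled$per_model), 2L)
  expect_equal(pooled$mean, mean(pooled$per_model), tolerance = 1e-12)
  expect_true(pooled$mean >= min(pooled$per_model) &&
              pooled$mean <= max(pooled$per_model))

  # same atom twice -> 0 +/- 0
  same <- ensemble_distance(ens, list(2, "H2''", 2, "H2''"))
  expect_equal(same$mean, 0)
  expect_equal(same$sd, 0)

  # rigid transform and model order leave the mean unchanged
  ens2 <- ens
  ens2$models <- rev(lapply(ens$models, random_rigid, seed = 4))
  d2 <- ensemble_distance(ens2, list(2, "H2''", 3, "O2P"))
  expect_equal(d2$mean, d1$mean, tolerance = 1e-9)

  expect_error(ensemble_distance(ens, list(2, "XX", 3, "O2P")), "not found")

  # 3-4-5 sanity on a hand-built model
  toy <- ptdna:::as_structure_model(data.frame(
    atom = c("A1", "A2", "A3"), element = "C", resno = 1:3, resname = "DG",
    chain = "A", x = c(0, 3, 0), y = c(0, 4, 0), z = 0))
  ens_toy <- structure_ensemble(list(toy))
  expect_equal(ensemble_distance(ens_toy, list(1, "A1", 2, "A2"))$mean, 5)
})

test_that("ensemble distance spread grows with jitter", {
  tmpl <- fixture_template("none")
  sds <- vapply(c(0.05, 0.1, 0.2), function(s) {
    ens <- synth_ensemble(tmpl, synth_config(seed = 1, n_models = 12,
                                             jitter_sd = s))
    ensemble_distance(ens, list(2, "H2''", 3, "O2P"))$sd
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("groove assignment is self-consistent on the template", {
  tmpl <- fixture_template("none")
  # every purine N7 (a major-groove edge atom) classifies major
  for (r in sort(unique(tmpl$resno))) {
    if (any(tmpl$resno == r & tmpl$atom == "N7"))
      expect_equal(groove_assign(tmpl, r, "N7")$label, "major")
  }
  # pyrimidine O2 sits on the minor edge
  expect_equal(groove_assign(tmpl, 5, "O2")$label, "minor")
})

test_that("coordinate pucker labels N and S conformers correctly", {
  tmpl <- fixture_template("none")
  pk <- pucker_from_coords(tmpl, 3)
  expect_equal(pk$type, "S")
  expect_equal(pk$P, 162, tolerance = 8)

  # synthetic N-type sugar: rebuild one residue with P = 18
  par <- bform_params(); par$pucker_P <- 18; par$pucker_amp <- 38
  m <- build_bform_template(duplex_spec("G", "C"), par)
  pkN <- pucker_from_coords(m, 1)
  expect_equal(pkN$type, "N")
  expect_equal(pkN$P, 18, tolerance = 10)

  # flat ring flags degenerate
  flat <- ptdna:::as_structure_model(data.frame(
    atom = c("C1'", "C2'", "C3'", "C4'", "O4'"), element = c(rep("C", 4), "O"),
    resno = 1, resname = "DG", chain = "A",
    x = cos(2 * pi * (0:4) / 5), y = sin(2 * pi * (0:4) / 5), z = 0))
  expect_true(pucker_from_coords(flat, 1)$degenerate)
})
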