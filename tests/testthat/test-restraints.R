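test_that("ISPA calibration inverts sixth-power volumes", {
  expect_equal(calibrate_distance(100, 100), 2.45)
  expect_equal(calibrate_distance(100 / 64, 100), 4.90, tolerance = 1e-12)
  expect_error(calibrate_distance(0, 100), "positive")
  expect_error(calibrate_distance(-1, 100), "positive")
  expect_error(calibrate_distance(100, 0), "positive")
})

test_that("calibration is monotone decreasing and scale-invariant", {
  v <- sort(stats::runif(50, 0.1, 100))
  d <- calibrate_distance(v, 10)
  expect_true(all(diff(d) < 0))
  for (c0 in c(0.01, 3, 1e4))
    expect_equal(calibrate_distance(c0 * v, c0 * 10), d, tolerance = 1e-12)
})

test_that("NOE classification uses the standard distance bins", {
  mk <- function(exch = FALSE, cls = NA, mt = 150, vol = NA)
    list(res_a = 1, atom_a = "H8", res_b = 2, atom_b = "H1'",
         exchangeable = exch, class = cls, mixing_time_ms = mt, volume = vol)

  expect_equal(unlist(classify_noe(mk(cls = "strong"))[c("lower", "upper")],
                      use.names = FALSE), c(1.8, 2.9))
  expect_equal(classify_noe(mk(cls = "medium"))$upper, 3.5)
  expect_equal(classify_noe(mk(cls = "weak"))$upper, 6.0)
  # exchangeable bins are wider
  expect_equal(classify_noe(mk(TRUE, "strong"))$upper, 4.0)
  expect_equal(classify_noe(mk(TRUE, "medium"))$upper, 5.0)
  expect_equal(classify_noe(mk(TRUE, "weak"))$upper, 8.0)
  # exchangeable observed only at 200 ms -> weak
  expect_equal(classify_noe(mk(TRUE, NA, mt = 200))$class, "weak")
  # calibrated-distance thresholding
  expect_equal(classify_noe(mk(), 2.5)$class, "strong")
  expect_equal(classify_noe(mk(), 3.2)$class, "medium")
  expect_equal(classify_noe(mk(), 3.2)$upper, 3.5)
  expect_equal(classify_noe(mk(), 5.0)$class, "weak")
  expect_error(classify_noe(mk()), "unclassifiable")

  # every emitted restraint satisfies 1.8 <= lower < upper <= 8
  for (cls in c("strong", "medium", "weak")) for (exch in c(TRUE, FALSE)) {
    r <- classify_noe(mk(exch, cls))
    expect_true(r$lower >= 1.8 && r$lower < r$upper && r$upper <= 8.0)
  }
})

test_that("pseudoatom correction widens upper bounds for degenerate groups", {
  r <- classify_noe(list(res_a = 11, atom_a = "M7", res_b = 11,
                         atom_b = "H6", exchangeable = FALSE,
                         class = "weak"))
  rc <- pseudoatom_correction(r, "methyl")
  expect_equal(rc$upper, 7.0)
  expect_true(rc$pseudoatom)
  expect_equal(pseudoatom_correction(r, "methyl", correction = 0)$upper, 6.0)
  single <- classify_noe(list(res_a = 1, atom_a = "H8", res_b = 2,
                              atom_b = "H1'", exchangeable = FALSE,
                              class = "weak"))
  expect_error(pseudoatom_correction(single, "methyl"), "degenerate")
})

test_that("Watson-Crick enumeration matches pair composition", {
  wc <- generate_wc_restraints(fixture_spec("none"))
  expect_equal(nrow(wc$hbonds), 29L)          # 9 GC x 3 + 1 AT x 2
  expect_equal(length(wc$planarity), 10L)
  expect_equal(nrow(generate_wc_restraints(duplex_spec("A", "T"))$hbonds), 2L)
  expect_equal(nrow(generate_wc_restraints(duplex_spec("G", "C"))$hbonds), 3L)
  # bounds as configured
  expect_true(all(wc$hbonds$heavy_lo == 2.8 & wc$hbonds$heavy_hi == 3.0))
  expect_true(all(wc$hbonds$h_lo == 1.8 & wc$hbonds$h_hi == 2.0))
})

test_that("restraint bookkeeping splits intra/inter/sequential correctly", {
  rest <- data.frame(
    res_a = c(1, 1, 1, 1, 5),  atom_a = "H1'",
    res_b = c(1, 2, 20, 7, 16), atom_b = "H8",
    lower = 1.8, upper = 5, class = "weak",
    exchangeable = FALSE, pseudoatom = FALSE)
  s <- restraint_summary(rest, n_bp = 10)
  expect_equal(s$total, 5L)
  expect_equal(s$intra_residue, 1L)
  expect_equal(s$inter_residue, 4L)
  expect_equal(s$sequential, 1L)          # 1-2 only; 1-20 is inter-strand
  expect_equal(s$non_sequential, 3L)
  expect_equal(s$sequential + s$non_sequential, s$inter_residue)
})

test_that("restraint tables round-trip through the XPLOR dialect", {
  rest <- rbind(
    classify_noe(list(res_a = 1, atom_a = "H8", res_b = 2, atom_b = "H1'",
                      exchangeable = FALSE, class = "strong")),
    classify_noe(list(res_a = 3, atom_a = "H1", res_b = 18, atom_b = "H41",
                      exchangeable = TRUE, class = "medium")))
  path <- tempfile(fileext = ".tbl")
  write_restraint_table(rest, path)
  lines <- readLines(path)
  expect_match(lines[1], "^assign \\(resid 1 and name H8\\)")
  expect_match(lines[1], "2.9000 1.1000 0.0000")
  back <- read_restraint_table(path)
  back <- back[order(back$res_a), ]
  rownames(back) <- rownames(rest) <- NULL
  expect_equal(back, rest)
  expect_error(write_restraint_table(rest[0, ], tempfile()), "empty")
})
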