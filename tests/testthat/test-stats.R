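test_that("Boltzmann weights match closed-form evaluations", {
  expect_equal(boltzmann_weights(c(0, 0, 0), 298.15), rep(1 / 3, 3))
  # frozen from an independent closed-form evaluation at RT
  expect_equal(boltzmann_weights(c(0, 1, 2), 298.15),
               c(0.8203, 0.1519, 0.0281), tolerance = 2e-3)
  # RT ln 10 at 298.15 K: a 10:1 population ratio
  w <- boltzmann_weights(c(0, 1.364), 298.15)
  expect_equal(w[1] / w[2], 10, tolerance = 0.01)
})

test_that("Boltzmann weights behave correctly in the temperature limits", {
  e <- c(0, 0.5, 2, 4)
  w <- boltzmann_weights(e, 298.15)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(diff(w) < 0)) # strictly decreasing in energy
  # T -> infinity: uniform
  expect_equal(boltzmann_weights(e, 1e6), rep(0.25, 4), tolerance = 1e-3)
  # T -> 0+: all mass on the minimum
  w0 <- boltzmann_weights(e, 1)
  expect_gt(w0[1], 1 - 1e-12)
  expect_error(boltzmann_weights(numeric(0)), "empty")
  expect_error(boltzmann_weights(c(0, 1), -5), "positive")
  expect_error(boltzmann_weights(c(0, Inf)), "finite")
})

test_that("class fractions sum and split as populations should", {
  w <- c(0.5, 0.3, 0.15, 0.05)
  expect_identical(class_fraction(w, c(TRUE, TRUE, TRUE, TRUE)), 1)
  expect_identical(class_fraction(w, rep(FALSE, 4)), 0)
  expect_equal(class_fraction(w, c(1, 1, 1, 0)), 0.95)
  # additivity over disjoint classes
  a <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(class_fraction(w, a) + class_fraction(w, !a), 1)
  expect_error(class_fraction(w, c(TRUE, FALSE)), "length")
})

test_that("class_min_gap finds the lowest class member or signals absence", {
  expect_identical(class_min_gap(c(0, 2, 5.9), c(TRUE, FALSE, FALSE)), 0)
  # the printed worked case: sole alpha conformer at 5.9 kcal/mol
  expect_identical(class_min_gap(c(0, 2, 5.9), c(FALSE, FALSE, TRUE)), 5.9)
  expect_error(class_min_gap(c(0, 2), c(FALSE, FALSE)), "empty")
})

test_that("circular means handle wraparound, constants and symmetric pairs", {
  expect_identical(circular_mean(c(170, -170)), 180)
  expect_identical(circular_mean(c(-80, -80, -80)), -80)
  expect_equal(circular_mean(c(-60, -100)), -80, tolerance = 1e-9)
  expect_error(circular_mean(numeric(0)), "empty")
  # weighted variant reduces to the unweighted one with equal weights
  expect_equal(circular_mean(c(10, 50, 90), rep(2, 3)),
               circular_mean(c(10, 50, 90)))
})

test_that("the ensemble report assembles counts, flags and populations", {
  # synthetic ensemble: 4 alpha-turn helical + 1 extended conformer
  bb <- build_backbone(5, phi = -63, psi = -42)
  roles <- peptide_role_map(bb)
  helix <- bb$conformers[[1]]
  ext <- build_backbone(5, phi = 180, psi = 180)$conformers[[1]]
  confs <- c(
    purrr::map(c(0, 0.3, 0.8, 1.1), function(e) {
      conformer(helix$xyz + matrix(stats::rnorm(length(helix$xyz),
                                                sd = 1e-4), ncol = 3),
                energy = e)
    }),
    list(conformer(ext$xyz, energy = 3.0))
  )
  e <- conformer_ensemble(bb, confs)
  flags <- analyze_ensemble(e, roles)
  rep <- table1_report(e, flags)
  s <- glance(rep)
  expect_equal(s$n_window, 5)
  expect_equal(s$n_hbond_B, 4)
  expect_equal(s$n_dalpha_probe, 4)
  expect_true(s$globmin_hbond_B)
  expect_gt(s$frac_alpha, 0.9) # mimics a dominant top-4 alpha class
  expect_equal(s$min_gap_alpha, 0)
  expect_equal(nrow(tidy(rep)), 5)
  expect_equal(sum(tidy(rep)$weight), 1, tolerance = 1e-12)

  # permutation invariance of the counts
  perm <- c(3, 5, 1, 2, 4)
  e2 <- conformer_ensemble(bb, confs[perm])
  rep2 <- table1_report(e2, analyze_ensemble(e2, roles))
  expect_equal(glance(rep2)$n_hbond_B, s$n_hbond_B)
  expect_equal(glance(rep2)$frac_alpha, s$frac_alpha, tolerance = 1e-12)

  expect_error(table1_report(e, flags[1:3, ]), "one row per")
})

test_that("report files are written and are re-readable", {
  bb <- build_backbone(5, phi = -63, psi = -42)
  roles <- peptide_role_map(bb)
  cf <- bb$conformers[[1]]
  e <- conformer_ensemble(bb, list(conformer(cf$xyz, energy = 0)))
  rep <- table1_report(e, analyze_ensemble(e, roles))
  dir <- withr::local_tempdir()
  files <- write_report(rep, dir)
  expect_true(all(file.exists(files)))
  flags_back <- utils::read.delim(files[["flags"]])
  expect_equal(nrow(flags_back), 1)
  js <- jsonlite::read_json(files[["json"]])
  expect_equal(js$summary[[1]]$n_window, 1)
})
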