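test_that("backbone construction round-trips its phi/psi spec", {
  withr::with_seed(21, {
    for (k in 1:6) {
      phi <- stats::runif(1, -170, 170)
      psi <- stats::runif(1, -170, 170)
      bb <- build_backbone(5, phi = phi, psi = psi)
      vt <- virtual_torsions(bb$conformers[[1]], peptide_role_map(bb))
      expect_true(all(abs(wrap_angle(vt$phi - phi)) <= 0.5))
      expect_true(all(abs(wrap_angle(vt$psi - psi)) <= 0.5))
    }
  })
  expect_error(build_backbone(1, 0, 0))
})

test_that("the helical pentapeptide reproduces the turn-probe geometry", {
  bb <- build_backbone(5, phi = -63, psi = -42)
  roles <- peptide_role_map(bb)
  d <- measure_distance(bb$conformers[[1]], roles$calpha[1], roles$calpha[5])
  expect_gte(d, 5.5)
  expect_lte(d, 7.0)
  hb <- detect_hbonds(bb$conformers[[1]], bb, hbond_criteria(), roles)
  expect_true(any(hb$ring_size == 13))
})

test_that("decoys are seed-deterministic and rarely close a 13-ring", {
  d1 <- make_decoys(100, seed = 7)
  d2 <- make_decoys(100, seed = 7)
  expect_identical(purrr::map(d1$conformers, "xyz"),
                   purrr::map(d2$conformers, "xyz"))
  frac13 <- mean(purrr::map_lgl(d1$conformers, function(cf) {
    any(detect_hbonds(cf, d1, hbond_criteria())$ring_size == 13)
  }))
  expect_lt(frac13, 0.2)
  d3 <- make_decoys(1, seed = 1)
  expect_length(d3$conformers, 1)
  # different seeds differ
  d4 <- make_decoys(100, seed = 8)
  expect_false(identical(purrr::map(d1$conformers, "xyz"),
                         purrr::map(d4$conformers, "xyz")))
})

test_that("labelled energy sets drive the Boltzmann machinery as designed", {
  # the dominant-top-4 pattern
  es <- make_energy_set(list(c("alpha", 0), c("alpha", 0.3),
                             c("alpha", 0.8), c("alpha", 1.1),
                             c("gamma", 3.0)))
  w <- boltzmann_weights(es$rel_energy, 298.15)
  expect_gt(class_fraction(w, es$class == "alpha"), 0.9)
  # the high-lying sole alpha conformer pattern
  es2 <- make_energy_set(list(c("gamma", 0), c("alpha", 5.9)))
  expect_equal(class_min_gap(es2$rel_energy, es2$class == "alpha"), 5.9)
  # degenerate single class
  es3 <- make_energy_set(list(c("alpha", 0)))
  expect_identical(class_fraction(boltzmann_weights(es3$rel_energy),
                                  es3$class == "alpha"), 1)
  expect_error(make_energy_set(list(c("alpha", 1))), "0 member")
})

test_that("synthetic NMR series honour their construction", {
  s <- make_nmr_series(slope = -7, intercept = 6.78, sigma = 0, n = 8)
  expect_equal(nrow(s), 8)
  expect_equal(s$delta_ppm[1], 6.78)
  expect_equal(range(s$T_K), c(263, 328))
  s1 <- make_nmr_series(-3, 7, 0.002, seed = 5)
  s2 <- make_nmr_series(-3, 7, 0.002, seed = 5)
  expect_identical(s1, s2)
  expect_error(make_nmr_series(-3, 7, 0, n = 2), "at least 3")
  expect_error(make_nmr_series(-3, 7, 0, t_range = c(300, 290)), "range")
})
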