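test_that("deduplicate merges copies and keeps the lowest-energy representative", {
  g <- toy_chain()
  cf <- g$conformers[[1]]
  at <- function(theta, e) {
    out <- set_torsion(cf, g, 1, 2, 3, 4, theta)
    conformer(out$xyz, energy = e)
  }
  # two identical copies -> 1 member
  e <- deduplicate(g, list(at(180, 1.0), at(180, 1.0)))
  expect_equal(length(e), 1)
  # distinct wells -> 2 members
  e <- deduplicate(g, list(at(180, 1.0), at(65, 2.0)))
  expect_equal(length(e), 2)
  # near-coincident pair + one distinct: greedy keeps the lowest of the pair
  e <- deduplicate(g, list(at(100, 0.0), at(101, 0.0001), at(180, 3.0)))
  expect_equal(length(e), 2)
  expect_equal(e$energies[1], 0.0)
  # idempotent
  e2 <- deduplicate(g, e$conformers)
  expect_equal(length(e2), length(e))
  expect_equal(e2$energies, e$energies)
})

test_that("the energy window is boundary-inclusive and nested", {
  g <- toy_chain()
  cf <- g$conformers[[1]]
  confs <- purrr::map(c(0, 2, 5.9, 6.0, 6.1), function(e) {
    conformer(cf$xyz, energy = e)
  })
  e <- conformer_ensemble(g, confs)
  expect_equal(length(energy_window(e, 6.0)), 4) # 6.0 retained, 6.1 not
  expect_equal(length(energy_window(e, 0.001)), 1)
  # a member at exactly 5.9 above the minimum stays inside a 6.0 window
  expect_true(5.9 %in% energy_window(e, 6.0)$rel_energies)
  # nesting: w1 <= w2 => window(w1) subset of window(w2)
  for (w in list(c(0.5, 2), c(2, 5.9), c(5.9, 6), c(3, 100))) {
    s1 <- energy_window(e, w[1])$energies
    s2 <- energy_window(e, w[2])$energies
    expect_true(all(s1 %in% s2))
  }
  expect_error(energy_window(e, -1), "positive")
})

test_that("the MC driver recovers all minima of the three-well potential", {
  g <- toy_chain()
  e <- mc_search(g, search_config(n_starts = 50, seed = 1, batch_size = 10),
                 backend_torsion(three_well))
  found <- sort(vapply(e$conformers, function(cf) {
    dihedral_angle(cf$xyz, 1, 2, 3, 4)
  }, numeric(1)))
  oracle <- sort(grid_scan_minima(three_well))
  expect_equal(length(found), length(oracle))
  expect_equal(found, oracle, tolerance = 0.02)
  # energies match the potential at its minima
  expect_equal(e$energies, three_well(found)[order(three_well(found))],
               tolerance = 1e-6)
})

test_that("the search is deterministic per seed and handles n_starts = 1", {
  g <- toy_chain()
  be <- backend_torsion(three_well)
  cfg <- search_config(n_starts = 40, seed = 9, batch_size = 8)
  e1 <- mc_search(g, cfg, be)
  e2 <- mc_search(g, cfg, be)
  expect_identical(purrr::map(e1$conformers, "xyz"),
                   purrr::map(e2$conformers, "xyz"))
  expect_identical(e1$energies, e2$energies)
  # different seed, different trajectory (pool sizes or geometries differ)
  e3 <- mc_search(g, search_config(n_starts = 40, seed = 10,
                                   batch_size = 8), be)
  expect_false(identical(purrr::map(e1$conformers, "xyz"),
                         purrr::map(e3$conformers, "xyz")))
  e_single <- mc_search(g, search_config(n_starts = 1, seed = 1), be)
  expect_equal(length(e_single), 1)
})

test_that("ensembles sort by energy with zero-based relative energies", {
  g <- toy_chain()
  cf <- g$conformers[[1]]
  e <- conformer_ensemble(g, list(conformer(cf$xyz, energy = 3),
                                  conformer(cf$xyz, energy = 1)))
  expect_equal(e$energies, c(1, 3))
  expect_equal(e$rel_energies, c(0, 2))
  expect_error(conformer_ensemble(g, list(conformer(cf$xyz))), "finite")
  tb <- tibble::as_tibble(e)
  expect_equal(tb$rel_energy, c(0, 2))
})

test_that("ensemble SDF round-trips conformers and energies", {
  g <- toy_chain()
  cf <- g$conformers[[1]]
  e <- conformer_ensemble(g, list(
    conformer(cf$xyz, energy = -2.5, converged = TRUE),
    conformer(set_torsion(cf, g, 1, 2, 3, 4, 60)$xyz, energy = 0.75,
              converged = TRUE)
  ))
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_ensemble_sdf(e, tmp)
  e2 <- read_ensemble_sdf(tmp)
  expect_equal(length(e2), 2)
  expect_equal(e2$energies, e$energies)
  expect_equal(e2$conformers[[1]]$xyz, e$conformers[[1]]$xyz,
               tolerance = 1e-3)
})
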