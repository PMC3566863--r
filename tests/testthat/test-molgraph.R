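test_that("the scaffold SMILES loads and validates by formula and mass", {
  g <- fixture_graph("1a")
  comp <- graph_composition(g)
  expect_identical(hill_formula(comp), "C27H29N5O5")
  expect_equal(monoisotopic_mass(comp), 503.2169, tolerance = 5e-4)
  # (3S,6S,12aS): three stereocentres, all S
  expect_equal(nrow(g$stereo), 3)
  expect_true(all(g$stereo$descriptor == "S"))
  # the 6R epimer differs in exactly one descriptor
  g_b <- fixture_graph("1b")
  expect_equal(sort(table(g_b$stereo$descriptor), decreasing = TRUE),
               sort(table(c("S", "S", "R")), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("trivial SMILES loads and malformed SMILES fails cleanly", {
  g <- load_structure(smiles = "CC")
  expect_equal(sum(g$atoms$element != "H"), 2)
  expect_equal(sum(g$atoms$element == "H"), 6)
  expect_error(load_structure(smiles = "C("), "parse")
  expect_error(load_structure(), "exactly one")
  expect_error(load_structure(smiles = "C", sdf = "x.sdf"), "exactly one")
})

test_that("hydrogen-bond typing finds the expected donors and acceptors", {
  g <- fixture_graph("1a")
  ty <- hbond_typing(g)
  # indole N-H, carbamate N-H, methylamide N-H
  expect_equal(nrow(ty$donors), 3)
  expect_true(all(g$atoms$element[ty$donors$donor] == "N"))
  expect_true(all(g$atoms$element[ty$donors$h] == "H"))
  # both DKP carbonyl O, methylamide O, both Cbz O
  expect_equal(nrow(ty$acceptors), 5)
  expect_equal(sum(ty$acceptors$kind == "carbonyl_O"), 4)
  expect_equal(sum(ty$acceptors$kind == "other_O"), 1)

  ty0 <- hbond_typing(methane_graph())
  expect_equal(nrow(ty0$donors), 0)
  expect_equal(nrow(ty0$acceptors), 0)

  tyf <- hbond_typing(formamide_graph())
  expect_equal(nrow(tyf$donors), 2) # one N-H entry per hydrogen
  expect_equal(length(unique(tyf$donors$donor)), 1)
  expect_equal(tyf$acceptors$kind, "carbonyl_O")
})

test_that("pseudo-cycle ring sizes give the C7/C13 taxonomy", {
  g <- fixture_graph("1a")
  roles <- fixture_roles("1a")
  expect_identical(pseudo_ring_size(g, roles$donor_h, roles$acceptor_pos3),
                   7L)
  expect_identical(pseudo_ring_size(g, roles$donor_h, roles$acceptor_pos1),
                   13L)
  # an amide's own H -> O contact closes a 4-ring (H, N, C, O)
  fa <- formamide_graph()
  expect_identical(pseudo_ring_size(fa, 5L, 2L), 4L)
  expect_error(pseudo_ring_size(g, roles$donor_n, roles$acceptor_pos1),
               "not a hydrogen")
})

test_that("ring size is at least 3 whenever donor H and acceptor are 2+ bonds apart", {
  g <- fixture_graph("1a")
  ty <- hbond_typing(g)
  for (i in seq_len(nrow(ty$donors))) {
    for (j in seq_len(nrow(ty$acceptors))) {
      rs <- pseudo_ring_size(g, ty$donors$h[i], ty$acceptors$id[j])
      expect_gte(rs, 3L)
    }
  }
})

test_that("write -> load round-trips the graph class and stereo labels", {
  g <- fixture_graph("1a")
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_structure(g, tmp)
  g2 <- load_structure(sdf = tmp)
  expect_true(graphs_isomorphic(g, g2))
  expect_identical(g2$stereo, g$stereo)
  # coordinates survive at the V2000 precision
  expect_equal(g2$conformers[[1]]$xyz, g$conformers[[1]]$xyz,
               tolerance = 1e-3)
})

test_that("synthetic graphs (no SDF template) also round-trip through SDF", {
  bb <- build_backbone(3, phi = -75, psi = 65)
  tmp <- withr::local_tempfile(fileext = ".sdf")
  bb$conformers[[1]]$energy <- 1.25
  write_structure(bb, tmp)
  g2 <- load_structure(sdf = tmp)
  expect_true(graphs_isomorphic(bb, g2))
  expect_equal(g2$conformers[[1]]$energy, 1.25)
})
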