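test_that("an ideal alpha-helical pentapeptide closes the 13-ring H-bond", {
  bb <- build_backbone(5, phi = -63, psi = -42)
  roles <- peptide_role_map(bb)
  cf <- bb$conformers[[1]]
  hb <- detect_hbonds(cf, bb, hbond_criteria(), roles)
  expect_true(any(hb$ring_size == 13 & hb$label == "5->1"))
  fl <- flag_turns(cf, bb, hbond_criteria(), roles)
  expect_true(fl$has_hbond_B)
  expect_lt(fl$dalpha, 7)
  expect_gt(fl$dalpha, 5.5) # Calpha(i)-Calpha(i+4) of an ideal helix
  expect_true(fl$dalpha_probe)
})

test_that("an ideal inverse-gamma tripeptide closes exactly one 7-ring", {
  bb <- build_backbone(3, phi = c(180, -75, 180), psi = c(180, 65, 180))
  cf <- bb$conformers[[1]]
  hb <- detect_hbonds(cf, bb, hbond_criteria())
  expect_equal(nrow(hb), 1)
  expect_equal(hb$ring_size, 7L)
  # oracle: direct distance/angle computation on the constructed geometry
  h3 <- which(bb$atoms$label == "H3")
  o1 <- which(bb$atoms$label == "O1")
  n3 <- which(bb$atoms$label == "N3")
  expect_equal(hb$dist_ha, measure_distance(cf, h3, o1), tolerance = 1e-12)
  expect_lte(hb$dist_ha, 2.5)
  v1 <- cf$xyz[n3, ] - cf$xyz[h3, ]
  v2 <- cf$xyz[o1, ] - cf$xyz[h3, ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(hb$angle_dha, ang, tolerance = 1e-9)
  expect_gte(ang, 120)
})

test_that("a stretched all-trans backbone has no intramolecular H-bond", {
  bb <- build_backbone(5, phi = 180, psi = 180)
  hb <- detect_hbonds(bb$conformers[[1]], bb, hbond_criteria())
  expect_equal(nrow(hb), 0)
  roles <- peptide_role_map(bb)
  fl <- flag_turns(bb$conformers[[1]], bb, hbond_criteria(), roles)
  expect_false(fl$has_hbond_A)
  expect_false(fl$has_hbond_B)
  expect_gt(fl$dalpha, 7)
  expect_false(fl$dalpha_probe)
})

test_that("reported contacts always satisfy the criteria they were found under", {
  crit <- hbond_criteria(max_ha_dist = 2.3, min_dha_angle = 130)
  decoys <- make_decoys(40, seed = 3)
  for (cf in decoys$conformers[1:40]) {
    hb <- detect_hbonds(cf, decoys, crit)
    if (nrow(hb)) {
      expect_true(all(hb$dist_ha <= crit$max_ha_dist))
      expect_true(all(hb$angle_dha >= crit$min_dha_angle))
      expect_true(all(hb$ring_size >= crit$min_ring_size))
    }
  }
})

test_that("heavy-atom mode works without hydrogen geometry", {
  bb <- build_backbone(5, phi = -63, psi = -42)
  roles <- peptide_role_map(bb)
  hb <- detect_hbonds(bb$conformers[[1]], bb,
                      hbond_criteria(heavy_atom_mode = TRUE), roles)
  expect_true(any(hb$ring_size == 13))
  expect_true(all(is.na(hb$dist_ha)))
})

test_that("virtual torsions round-trip the constructed phi/psi", {
  cases <- list(c(-63, -42), c(-75, 65), c(-120, 130), c(55, 40))
  for (ps in cases) {
    bb <- build_backbone(5, phi = ps[1], psi = ps[2])
    vt <- virtual_torsions(bb$conformers[[1]], peptide_role_map(bb))
    expect_equal(vt$phi, rep(ps[1], 3), tolerance = 0.5)
    expect_equal(vt$psi, rep(ps[2], 3), tolerance = 0.5)
  }
})

test_that("planar zigzag backbones give torsions of 0 or 180 only", {
  bb <- build_backbone(4, phi = 180, psi = 180)
  vt <- virtual_torsions(bb$conformers[[1]], local({
    # build a 4-residue role map by hand from labels
    lab <- bb$atoms$label
    idx <- function(x) which(lab == x)
    role_map(
      donor_n = idx("N4"), donor_h = idx("H4"),
      acceptor_pos1 = idx("O1"), acceptor_pos3 = idx("O2"),
      calpha = c(idx("CA1"), idx("CA2"), idx("CA3"), idx("CA4"), idx("N4")),
      backbone = stats::setNames(purrr::map(1:4, function(i) {
        c(idx(paste0("N", i)), idx(paste0("CA", i)), idx(paste0("C", i)))
      }), as.character(1:4))
    )
  }))
  vals <- abs(wrap_angle(c(vt$phi[1:2], vt$psi[1:2])))
  expect_true(all(pmin(vals, abs(vals - 180)) < 1e-6))
})

test_that("d-alpha is invariant under rigid motion of the conformer", {
  bb <- build_backbone(5, phi = -63, psi = -42)
  roles <- peptide_role_map(bb)
  cf <- bb$conformers[[1]]
  moved <- random_rigid_motion(cf, seed = 11)
  expect_equal(
    measure_distance(cf, roles$calpha[1], roles$calpha[5]),
    measure_distance(moved, roles$calpha[1], roles$calpha[5]),
    tolerance = 1e-9
  )
})

test_that("a 13-ring flag implies a 13-atom pseudo-cycle in the graph", {
  g <- fixture_graph("1a")
  roles <- fixture_roles("1a")
  # force a geometry-independent check of the topological invariant
  expect_identical(pseudo_ring_size(g, roles$donor_h, roles$acceptor_pos1),
                   13L)
  bb <- build_backbone(5, phi = -63, psi = -42)
  pr <- peptide_role_map(bb)
  fl <- flag_turns(bb$conformers[[1]], bb, hbond_criteria(), pr)
  if (fl$has_hbond_B) {
    expect_identical(pseudo_ring_size(bb, pr$donor_h, pr$acceptor_pos1), 13L)
  }
})
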