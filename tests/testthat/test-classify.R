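test_that("the published torsion averages compose the B-aL-X designation", {
  expect_identical(classify_region(-81.5, 64.5), "B")
  expect_identical(classify_region(146.3, 36.9), "aL")
  expect_identical(classify_region(120.5, -29.3), "X")
  d <- turn_designation(rbind(c(-81.5, 64.5), c(146.3, 36.9),
                              c(120.5, -29.3)))
  expect_identical(as.character(d), "B-aL-X")
})

test_that("region centres classify as expected and compose designations", {
  expect_identical(classify_region(-65, -40), "A")
  d <- turn_designation(rbind(c(-65, -40), c(-65, -40), c(-65, -40)))
  expect_identical(as.character(d), "A-A-A")
  # any pair outside all rectangles contributes an X
  d2 <- turn_designation(rbind(c(-65, -40), c(0, -150), c(-65, -40)))
  expect_match(as.character(d2), "X")
  expect_error(turn_designation(rbind(c(0, 0), c(1, 1))), "three")
})

test_that("region classification is total over the wrapped domain", {
  m <- region_map()
  labs <- c(m$regions$label, m$fallback)
  withr::with_seed(5, {
    phi <- c(stats::runif(400, -180, 180), -180, 180, 0, -30, 30, 45)
    psi <- c(stats::runif(400, -180, 180), 180, -180, 45, -10, 120, 0)
    for (i in seq_along(phi)) {
      lab <- classify_region(phi[i], psi[i], m)
      expect_length(lab, 1)
      expect_true(lab %in% labs)
    }
  })
})

test_that("boundaries are closed-low / open-high (with 180 closed)", {
  # psi = 45 is the closed lower edge of B, open upper edge of A
  expect_identical(classify_region(-100, 45), "B")
  expect_identical(classify_region(-100, 44.999), "A")
  # phi upper bound of aL is 180 and closed; psi = 180 closed for B
  expect_identical(classify_region(180, 50), "aL")
  expect_identical(classify_region(-100, 180), "B")
})

test_that("mirrored helical centres map A to aL", {
  m <- region_map()
  a <- m$regions[m$regions$label == "A", ]
  centre <- c((a$phi_min + a$phi_max) / 2, (a$psi_min + a$psi_max) / 2)
  expect_identical(classify_region(centre[1], centre[2], m), "A")
  expect_identical(classify_region(-centre[1], -centre[2], m), "aL")
})

test_that("gamma-turn windows reproduce the published averages and mirror", {
  expect_identical(classify_gamma(-80.1, 79.6), "inverse")
  expect_identical(classify_gamma(80, -70), "classic")
  expect_identical(classify_gamma(0, 0), "none")
  withr::with_seed(8, {
    phi <- stats::runif(300, -180, 180)
    psi <- stats::runif(300, -180, 180)
    for (i in seq_along(phi)) {
      fwd <- classify_gamma(phi[i], psi[i])
      rev <- classify_gamma(-phi[i], -psi[i])
      expect_identical(fwd == "inverse", rev == "classic")
      expect_identical(fwd == "classic", rev == "inverse")
    }
  })
})

test_that("region maps round-trip through YAML", {
  m <- region_map()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_region_map(m, tmp)
  m2 <- read_region_map(tmp)
  expect_equal(m2$regions, m$regions)
  expect_identical(classify_region(-81.5, 64.5, m2), "B")
})
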