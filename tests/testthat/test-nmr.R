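test_that("temperature coefficients are exact on noiseless lines", {
  s <- make_nmr_series(slope = -7.0, intercept = 6.78, sigma = 0)
  expect_equal(temp_coefficient(s), -7.0, tolerance = 1e-10)
  flat <- make_nmr_series(slope = 0, intercept = 7.1, sigma = 0)
  expect_equal(temp_coefficient(flat), 0, tolerance = 1e-12)
  expect_error(temp_coefficient(s[1:2, ]), "at least 3")
  bad <- s
  bad$T_K <- rep(300, nrow(bad))
  expect_error(temp_coefficient(bad), "increasing")
})

test_that("slopes are recovered within 0.3 ppb/K from noisy series", {
  s <- make_nmr_series(slope = -2.3, intercept = 5.53, sigma = 0.002,
                       n = 8, seed = 42)
  expect_lt(abs(temp_coefficient(s) - (-2.3)), 0.3)
  s2 <- make_nmr_series(slope = -7.0, intercept = 6.78, sigma = 0.002,
                        n = 8, seed = 43)
  expect_lt(abs(temp_coefficient(s2) - (-7.0)), 0.3)
})

test_that("slope estimation is unbiased over replicates", {
  errs <- vapply(1:200, function(k) {
    s <- make_nmr_series(slope = -5, intercept = 6.5, sigma = 0.002,
                         n = 8, seed = k)
    temp_coefficient(s) + 5
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.1)
})

test_that("NH states classify as the published coefficients do", {
  expect_identical(classify_nh_state(7.0), "equilibrium_bonded")
  expect_identical(classify_nh_state(-7.0), "equilibrium_bonded")
  expect_identical(classify_nh_state(2.3), "non_bonded")
  expect_identical(classify_nh_state(3.5), "indeterminate")
  expect_error(classify_nh_state(7, solvent = "DMSO"), "CDCl3")
})

test_that("classification is monotone in the coefficient magnitude", {
  states <- vapply(seq(0, 12, by = 0.25), classify_nh_state, character(1))
  rank <- c(non_bonded = 1, indeterminate = 2, equilibrium_bonded = 3)
  expect_true(all(diff(rank[states]) >= 0))
})

test_that("titration deltas reproduce the published shifts", {
  expect_equal(titration_delta(
    tibble::tibble(pct_dmso = c(0, 30), delta_ppm = c(6.78, 7.02))
  ), 0.24)
  expect_equal(titration_delta(
    tibble::tibble(pct_dmso = c(0, 30), delta_ppm = c(5.53, 6.35))
  ), 0.82)
  expect_equal(titration_delta(
    tibble::tibble(pct_dmso = c(0, 10, 30), delta_ppm = c(6, 6, 6))
  ), 0)
  expect_error(titration_delta(
    tibble::tibble(pct_dmso = c(5, 30), delta_ppm = c(6, 7))
  ), "0%")
})

test_that("titration delta depends only on the endpoints", {
  base <- tibble::tibble(pct_dmso = c(0, 30), delta_ppm = c(6.78, 7.02))
  wiggly <- tibble::tibble(pct_dmso = c(0, 5, 12, 21, 30),
                           delta_ppm = c(6.78, 6.95, 6.70, 7.30, 7.02))
  expect_identical(titration_delta(base), titration_delta(wiggly))
})

test_that("exposure classes split at the 0.5 ppm boundary", {
  expect_identical(classify_exposure(0.24), "shielded")
  expect_identical(classify_exposure(0.82), "exposed")
  expect_identical(classify_exposure(0.5), "exposed")
  expect_identical(classify_exposure(-0.3), "shielded")
})

test_that("the evidence table reproduces the published interpretation", {
  ref <- nmr_reference()
  temp <- dplyr::bind_rows(
    make_nmr_series(-7.0, 6.78, 0, label = "NHMe"),
    make_nmr_series(-2.3, 5.53, 0, label = "NHCbz")
  )
  titr <- tibble::tibble(
    label = rep(c("NHMe", "NHCbz"), each = 2),
    pct_dmso = c(0, 30, 0, 30),
    delta_ppm = c(6.78, 7.02, 5.53, 6.35)
  )
  ev <- nmr_evidence(temp, titr)
  me <- ev[ev$label == "NHMe", ]
  cbz <- ev[ev$label == "NHCbz", ]
  expect_identical(me$nh_state, "equilibrium_bonded")
  expect_identical(me$exposure, "shielded")
  expect_identical(cbz$nh_state, "non_bonded")
  expect_identical(cbz$exposure, "exposed")
  expect_equal(abs(me$temp_coef_ppb_K), ref$abs_temp_coef_ppb_K[1],
               tolerance = 1e-9)
})
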