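# Synthetic-data generator: determinism, noise structure, contrast series.

test_that("zero noise and zero resolution return exact model values", {
  ins <- instrument_spec(0.001, 0.4, 50, dq_over_q = 0)
  cv <- generate_curve("power_law", c(alpha2 = 1e-9, decay = 4,
                                      background = 0.01),
                       ins, noise_spec(0))
  expect_equal(cv$intensity, 1e-9 * cv$q^-4 + 0.01, tolerance = 1e-14)
  expect_null(cv$sigma_q)
})

test_that("same seed reproduces the curve; different seeds do not", {
  a <- generate_curve("flexible_cylinder_powerlaw", fiber_truth(),
                      instrument_d11(60), noise_spec(0.02, seed = 10))
  b <- generate_curve("flexible_cylinder_powerlaw", fiber_truth(),
                      instrument_d11(60), noise_spec(0.02, seed = 10))
  c <- generate_curve("flexible_cylinder_powerlaw", fiber_truth(),
                      instrument_d11(60), noise_spec(0.02, seed = 11))
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("noise scale and floor propagate into stored uncertainties", {
  ins <- instrument_spec(0.001, 0.4, 50, dq_over_q = 0)
  cv <- generate_curve("power_law", c(alpha2 = 1e-9, decay = 4,
                                      background = 0.01),
                       ins, noise_spec(0.05, floor_sigma = 0.02, seed = 1))
  i0 <- 1e-9 * cv$q^-4 + 0.01
  expect_equal(cv$sigma_i, pmax(0.05 * i0, 0.02), tolerance = 1e-12)
})

test_that("the generating truth travels in the metadata", {
  cv <- generate_curve("flexible_cylinder_powerlaw", fiber_truth(),
                       instrument_d11(60), noise_spec(0.02, seed = 1))
  expect_equal(cv$metadata$truth$model, "flexible_cylinder_powerlaw")
  expect_equal(cv$metadata$truth$params$kuhn, 318)
  expect_equal(cv$metadata$dq_over_q, 0.09)
})

test_that("contrast series: zero contrast at the match point", {
  chitin <- chitin_composition()
  mp <- match_point(chitin)$f_d2o
  ser <- generate_contrast_series(
    chitin, fractions = c(0, mp, 1), forward_scale = 10,
    instrument = instrument_d11(40), noise = noise_spec(0),
    background = 0.05)
  at_match <- ser$curves[[2]]
  expect_equal(at_match$intensity, rep(0.05, length(at_match$q)),
               tolerance = 1e-10)
})

test_that("contrast series: scale invariance of the match-point estimate", {
  chitin <- chitin_composition()
  s1 <- generate_contrast_series(chitin, forward_scale = 1,
                                 instrument = instrument_d11(40),
                                 noise = noise_spec(0))
  s2 <- generate_contrast_series(chitin, forward_scale = 2,
                                 instrument = instrument_d11(40),
                                 noise = noise_spec(0))
  for (i in seq_along(s1$curves)) {
    expect_equal(s2$curves[[i]]$intensity, 2 * s1$curves[[i]]$intensity,
                 tolerance = 1e-12)
  }
  expect_equal(match_point_from_series(s1)$f_d2o,
               match_point_from_series(s2)$f_d2o, tolerance = 1e-10)
})

test_that("series noise is reproducible under a master seed, independent across curves", {
  chitin <- chitin_composition()
  mk <- function() generate_contrast_series(
    chitin, forward_scale = 10, instrument = instrument_d11(40),
    noise = noise_spec(0.02, seed = 100))
  s1 <- mk(); s2 <- mk()
  for (i in seq_along(s1$curves)) {
    expect_identical(s1$curves[[i]]$intensity, s2$curves[[i]]$intensity)
  }
  # different curves get different noise realizations
  r1 <- (s1$curves[[1]]$intensity /
           s1$curves[[1]]$sigma_i)
  r2 <- (s1$curves[[2]]$intensity / s1$curves[[2]]$sigma_i)
  expect_false(isTRUE(all.equal(r1, r2)))
})

test_that("instrument presets carry the documented ranges", {
  d11 <- instrument_d11()
  expect_equal(c(d11$q_min, d11$q_max), c(0.0013, 0.4102))
  expect_equal(d11$dq_over_q, 0.09)
  bt5 <- instrument_bt5()
  expect_equal(c(bt5$q_min, bt5$q_max), c(5e-5, 1e-3))
  expect_error(instrument_spec(0.1, 0.01, 50), "q_max")
  expect_error(instrument_spec(0.01, 0.1, 5), "n_points")
})
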