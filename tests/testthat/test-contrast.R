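# Scattering-length densities, contrasts and match points.

test_that("solvent SLD endpoints match hand-computed water values", {
  # sum of b over the formula divided by the molecular volume:
  # H2O at 0.997 g/mL -> -0.558e-6 A^-2, D2O at 1.105 g/mL -> 6.361e-6
  expect_equal(solvent_sld(0), -0.56, tolerance = 0.01 / 0.56)
  expect_equal(solvent_sld(1), 6.36, tolerance = 0.03 / 6.36)
  expect_equal(solvent_sld(0.5),
               (solvent_sld(0) + solvent_sld(1)) / 2)
  expect_equal(solvent_sld("50%"), solvent_sld(0.5))
})

test_that("composition SLD: GlcNAc unit, exchange, and self-consistency", {
  chitin <- chitin_composition()
  # brute-force sum of tabulated b over C8H13NO5 / (M / rho N_A) = 1.909
  expect_equal(composition_sld(chitin, 0), 1.909, tolerance = 1e-3)
  # no exchangeable sites -> independent of solvent
  dry <- molecular_composition("C8O5N", density = 1.4)
  expect_equal(composition_sld(dry, 0), composition_sld(dry, 1))
  # water treated as a solute reproduces the solvent line closely
  # (exactly at f = 0; within the D2O-density idealization at f = 1)
  w <- molecular_composition("H2O", labile_h = 2, density = 0.997)
  f <- seq(0, 1, by = 0.25)
  expect_lt(max(abs(composition_sld(w, f) - solvent_sld(f))), 0.03)
  expect_equal(composition_sld(w, 0), solvent_sld(0))
})

test_that("composition SLD is affine in f_d2o with the labile-H slope", {
  chitin <- chitin_composition()
  f <- c(0, 0.3, 0.62, 1)
  s <- composition_sld(chitin, f, exchange_fraction = 0.8)
  co <- coef(lm(s ~ f))
  # slope = 10 * exchange * n_labile * (b_D - b_H) / V
  expect_equal(unname(co[2]),
               10 * 0.8 * 3 * (6.671 + 3.739) / chitin$volume_A3,
               tolerance = 1e-10)
  expect_equal(max(abs(s - (co[1] + co[2] * f))), 0, tolerance = 1e-12)
})

test_that("closed-form match point behaves as an intensive quantity", {
  chitin <- chitin_composition()
  mp <- match_point(chitin)
  expect_true(mp$reachable)
  expect_equal(mp$f_d2o, 0.446, tolerance = 0.005 / 0.446)
  # uniform rescaling of the formula leaves the match point unchanged
  double <- molecular_composition("C16H26N2O10", labile_h = 6,
                                  density = 1.5)
  expect_equal(match_point(double)$f_d2o, mp$f_d2o, tolerance = 1e-12)
  # a composition identical to H2O matches pure H2O
  w <- molecular_composition("H2O", labile_h = 2, density = 0.997)
  expect_equal(match_point(w)$f_d2o, 0, tolerance = 1e-10)
})

test_that("match point rises with deuteration until unreachable", {
  mps <- vapply(c(0, 0.25, 0.5), function(d) {
    comp <- molecular_composition("C8H13NO5", labile_h = 3,
                                  deuteration = d, density = 1.5)
    match_point(comp)$f_d2o
  }, numeric(1))
  expect_true(all(diff(mps) > 0))
  # perdeuterated, no exchangeable H: SLD above pure D2O -> flagged
  per <- molecular_composition("C8D13NO5", density = 1.5)
  mp <- match_point(per)
  expect_gt(mp$f_d2o, 1)
  expect_false(mp$reachable)
})

test_that("parallel SLD lines raise a no-match-point error", {
  # choose the density so the labile-H slope equals the solvent slope
  slope_solv <- solvent_sld(1) - solvent_sld(0)
  v_target <- 10 * 2 * (6.671 + 3.739) / slope_solv
  rho <- (2 * 1.008 + 15.999) * 1e24 / (v_target * 6.02214076e23)
  comp <- molecular_composition("H2O", labile_h = 2, density = rho)
  expect_error(match_point(comp), "parallel")
})

test_that("series estimator recovers the minimum of an exact quadratic", {
  q <- seq(0.03, 0.4, length.out = 50)
  f <- c(0, 0.2, 0.42, 0.66, 0.8, 1)
  curves <- lapply(f, function(fi) {
    scattering_curve(q, rep(2 * (fi - 0.47)^2 + 0.1, length(q)),
                     sigma_i = rep(0.01, length(q)),
                     metadata = list(f_d2o = fi))
  })
  mp <- match_point_from_series(curves)
  expect_equal(mp$f_d2o, 0.47, tolerance = 1e-10)
})

test_that("series estimator rejects degenerate input", {
  q <- seq(0.03, 0.4, length.out = 20)
  mk <- function(fi, val) scattering_curve(q, rep(val, 20), rep(0.01, 20),
                                           metadata = list(f_d2o = fi))
  expect_error(match_point_from_series(list(mk(0, 1), mk(0.5, 2))),
               "at least 3")
  flat <- lapply(c(0, 0.3, 0.6, 1), mk, val = 1)
  expect_error(match_point_from_series(flat), "no interior minimum")
  # downward-opening parabola
  bad <- lapply(c(0, 0.3, 0.6, 1), function(fi) mk(fi, 1 - (fi - 0.5)^2))
  expect_error(match_point_from_series(bad), "no interior minimum")
})

test_that("series estimator agrees with the closed form on simulated data", {
  chitin <- chitin_composition()
  ser <- generate_contrast_series(
    chitin, forward_scale = 10, instrument = instrument_d11(80),
    noise = noise_spec(0.02, seed = 5), background = 0.05)
  mp <- match_point_from_series(ser)
  expect_equal(mp$f_d2o, match_point(chitin)$f_d2o, tolerance = 0.02)
})

test_that("composition validation catches inconsistent bookkeeping", {
  expect_error(molecular_composition("C8H13NO5", labile_h = 14,
                                     density = 1.5), "labile_h")
  expect_error(molecular_composition("C8H13NO5", labile_h = 3,
                                     density = 0), "density")
  expect_error(molecular_composition("C8H13NO5", labile_h = 3,
                                     deuteration = 1.2, density = 1.5),
               "deuteration")
  expect_error(parse_formula("Xy3"), "tabulated")
  expect_equal(parse_formula("C8H13NO5"),
               c(C = 8L, H = 13L, N = 1L, O = 5L),
               ignore_attr = TRUE)
  expect_error(composition_sld(chitin_composition(), "47"), "%")
})
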