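# Weighted nonlinear least-squares engine and the fiber/aggregate
# protocols.

test_that("noiseless Guinier data are recovered to high precision", {
  ins <- instrument_spec(0.005, 0.05, 60, dq_over_q = 0)
  cv <- generate_curve("guinier", c(G = 100, Rg = 50, background = 0),
                       ins, noise_spec(0))
  f <- fit_curve(cv, "guinier", fit_config(fixed = c(background = 0)))
  expect_lt(rel_err(f$estimates[["G"]], 100), 1e-6)
  expect_lt(rel_err(f$estimates[["Rg"]], 50), 1e-6)
})

test_that("uniform weights equal sigma weights when sigma is constant", {
  ins <- instrument_spec(0.005, 0.05, 50, dq_over_q = 0)
  cv <- generate_curve("guinier", c(G = 100, Rg = 50, background = 0.5),
                       ins, noise_spec(0, floor_sigma = 0.3, seed = 2))
  f1 <- fit_curve(cv, "guinier", fit_config(weighting = "sigma"))
  f2 <- fit_curve(cv, "guinier", fit_config(weighting = "uniform"))
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("estimates are equivariant under joint rescaling of I and sigma", {
  ins <- instrument_spec(0.005, 0.05, 50, dq_over_q = 0)
  cv <- generate_curve("guinier", c(G = 100, Rg = 50, background = 0.5),
                       ins, noise_spec(0.02, seed = 3))
  k <- 1000
  cv2 <- scattering_curve(cv$q, k * cv$intensity, k * cv$sigma_i,
                          metadata = cv$metadata)
  f1 <- fit_curve(cv, "guinier", fit_config())
  f2 <- fit_curve(cv2, "guinier", fit_config())
  expect_equal(f2$estimates[["G"]] / f1$estimates[["G"]], k,
               tolerance = 1e-4)
  expect_equal(f2$estimates[["Rg"]], f1$estimates[["Rg"]],
               tolerance = 1e-5)
  expect_equal(f2$chisq_red, f1$chisq_red, tolerance = 1e-6)
})

test_that("fiber protocol: noiseless round trip is exact", {
  q <- exp(seq(log(0.0013), log(0.4102), length.out = 100))
  i0 <- eval_flexible_cylinder(q, fiber_truth())
  cv <- scattering_curve(q, i0, 0.01 * i0)  # exact model, 1% weights
  f <- fit_chitin_reference(cv, config = fit_config(seed = 1))
  expect_lt(rel_err(f$estimates[["radius"]], 16), 1e-4)
  expect_lt(rel_err(f$estimates[["kuhn"]], 318), 1e-3)
  expect_lt(f$chisq_red, 1e-6)
  expect_equal(f$estimates[["contour"]], 5000)
  expect_true("contour" %in% f$fixed)
})

test_that("fiber protocol recovers the decay exponent of sharp interfaces", {
  cv <- generate_curve("flexible_cylinder_powerlaw", fiber_truth(),
                       instrument_d11(120), noise_spec(0.02, seed = 8))
  f <- fit_chitin_reference(cv, config = fit_config(seed = 1))
  expect_lt(abs(f$estimates[["decay"]] - 4), 0.1)
})

test_that("non-convergence is flagged, not thrown", {
  ins <- instrument_spec(0.005, 0.05, 40, dq_over_q = 0)
  cv <- generate_curve("guinier", c(G = 100, Rg = 50, background = 0),
                       ins, noise_spec(0.05, seed = 4))
  f <- suppressWarnings(
    fit_curve(cv, "guinier",
              fit_config(start = c(G = 1e5, Rg = 500, background = 10),
                         max_iter = 1)))
  expect_s3_class(f, "sans_fit")
  expect_false(f$converged)
})

test_that("a degenerate parameterization yields NA uncertainties", {
  ins <- instrument_spec(0.005, 0.05, 40, dq_over_q = 0)
  cv <- generate_curve(function(q, p) p[["a"]] * exp(-q * 10),
                       list(a = 1), ins, noise_spec(0.01, seed = 5))
  # b and c enter only through their sum: singular information matrix
  f <- fit_curve(cv, function(q, p) (p[["b"]] + p[["c"]]) * exp(-q * 10),
                 fit_config(start = c(b = 0.5, c = 0.5)))
  expect_true(all(is.na(f$se)))
})

test_that("two-stage unified fit recovers a two-level aggregate", {
  bp <- aggregate_truth()
  cv <- generate_curve("beaucage2", bp, instrument_d11(150),
                       noise_spec(0.03, seed = 1))
  f <- fit_beaucage_two_stage(cv, config = fit_config(seed = 1))
  expect_true(f$converged)
  expect_lt(rel_err(f$estimates[["Rg1"]], 1800), 0.10)
  expect_lt(rel_err(f$estimates[["Rg2"]], 125), 0.10)
  expect_lt(abs(f$estimates[["D1"]] - 2.6), 0.15)
  expect_lt(abs(f$estimates[["D2"]] - 2.6), 0.15)
  # the Rg bound of the protocol is recorded and respected
  rg_cap <- pi / min(cv$q)
  expect_lte(f$estimates[["Rg1"]], rg_cap)
  expect_lte(f$estimates[["Rg2"]], rg_cap)
  expect_true(any(grepl("pi/q_min", f$constraints)))
})

test_that("two-stage fit never worsens the stage-1 concatenated chi-square", {
  bp <- aggregate_truth()
  cv <- generate_curve("beaucage2", bp, instrument_d11(120),
                       noise_spec(0.03, seed = 6))
  f <- fit_beaucage_two_stage(cv, config = fit_config(seed = 2))
  st <- c(G1 = f$stages$low$estimates[["G1"]],
          Rg1 = min(f$stages$low$estimates[["Rg1"]], pi / min(cv$q)),
          B1 = f$stages$low$estimates[["B1"]],
          D1 = f$stages$low$estimates[["D1"]],
          G2 = f$stages$high$estimates[["G1"]],
          Rg2 = f$stages$high$estimates[["Rg1"]],
          B2 = f$stages$high$estimates[["B1"]],
          D2 = f$stages$high$estimates[["D1"]],
          background = f$stages$high$estimates[["background"]])
  reg <- sanstools:::get_sans_model("beaucage2")
  m <- smear_gaussian(function(qq) reg$eval(qq, st), cv$q, f$dq_over_q)
  chisq_start <- sum(((cv$intensity - m) / cv$sigma_i)^2)
  expect_lte(f$chisq, chisq_start + 1e-6)
})

test_that("an out-of-window Rg is pinned at the pi/q_min bound and flagged", {
  rg_cap <- pi / 0.0013
  bp <- aggregate_truth(Rg1 = 3500, G1 = 5000)   # beyond the window
  cv <- generate_curve("beaucage2", bp, instrument_d11(120),
                       noise_spec(0.03, seed = 7))
  f <- fit_beaucage_two_stage(cv, config = fit_config(seed = 2))
  expect_lte(f$estimates[["Rg1"]], rg_cap * (1 + 1e-8))
  expect_gt(f$estimates[["Rg1"]], 0.999 * rg_cap)
  expect_true("Rg1" %in% f$at_bound)
  expect_true(any(grepl("at bound: Rg1", f$constraints)))
})

test_that("fitting one-level data with two levels collapses a level", {
  cv <- generate_curve("beaucage1",
                       c(G1 = 100, Rg1 = 120, B1 = 1e-4, D1 = 2.8,
                         background = 0.01),
                       instrument_d11(120), noise_spec(0.02, seed = 9))
  f <- fit_beaucage_two_stage(cv, config = fit_config(seed = 2))
  # one level reproduces the truth, the other (spurious) level collapses:
  # Guinier scale consistent with zero within ~2 sigma, or Porod scale
  # numerically zero
  e <- f$estimates; se <- f$se
  real_lvl <- which.min(abs(c(e[["Rg1"]], e[["Rg2"]]) - 120))
  spur <- if (real_lvl == 1) c("G2", "B2") else c("G1", "B1")
  expect_lt(rel_err(e[[c("Rg1", "Rg2")[real_lvl]]], 120), 0.10)
  g_sp <- e[[spur[1]]]
  collapsed <- g_sp < 2 * max(se[[spur[1]]], 0, na.rm = TRUE) + 0.02 * 100 ||
    e[[spur[2]]] < 1e-8
  expect_true(collapsed)
})

test_that("configuration errors are caught early", {
  q <- c(0.01, 0.02, 0.03, 0.04)
  cv <- scattering_curve(q, 10 * exp(-q^2 * 40^2 / 3), rep(0.1, 4))
  expect_error(fit_curve(cv, "beaucage1", fit_config()), "more data points")
  expect_error(fit_curve(cv, "guinier", fit_config(fixed = c(zz = 1))),
               "unknown fixed")
  expect_error(fit_curve(cv, "nope", fit_config()), "unknown model")
})
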