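# Synthetic-data generator: instrument-like curves from any of the package
# models, with multiplicative Gaussian counting noise, and full
# contrast-variation series whose integrated-intensity minimum encodes a
# composition's match point.

#' Instrument specification for synthetic curves
#'
#' @param q_min,q_max q-range, 1/A.
#' @param n_points Number of grid points (>= 10).
#' @param spacing `"log"` (default) or `"linear"`.
#' @param dq_over_q Relative Gaussian q-resolution applied when generating
#'   (0 disables smearing).
#' @return Object of class `"instrument_spec"`.
#' @export
instrument_spec <- function(q_min, q_max, n_points = 120,
                            spacing = c("log", "linear"), dq_over_q = 0) {
  spacing <- match.arg(spacing)
  stopifnot(q_min > 0, q_max > q_min, n_points >= 10, dq_over_q >= 0)
  structure(list(q_min = q_min, q_max = q_max,
                 n_points = as.integer(n_points), spacing = spacing,
                 dq_over_q = dq_over_q),
            class = "instrument_spec")
}

#' Pinhole-SANS preset (D11-like)
#'
#' q-range 0.0013-0.4102 1/A with a 9% relative wavelength spread, the
#' configuration typical of a long pinhole SANS instrument.
#'
#' @param n_points Number of grid points.
#' @param dq_over_q Relative resolution width.
#' @return An [instrument_spec()].
#' @export
instrument_d11 <- function(n_points = 120, dq_over_q = 0.09) {
  instrument_spec(0.0013, 0.4102, n_points, "log", dq_over_q)
}

#' USANS preset (BT5-like)
#'
#' q-range 5e-5 to 1e-3 1/A, 6% wavelength spread (slit-smearing of USANS
#' instruments is not modelled; the preset only fixes the grid).
#'
#' @param n_points Number of grid points.
#' @param dq_over_q Relative resolution width.
#' @return An [instrument_spec()].
#' @export
instrument_bt5 <- function(n_points = 30, dq_over_q = 0.06) {
  instrument_spec(5e-5, 1e-3, n_points, "log", dq_over_q)
}

#' Noise specification for synthetic curves
#'
#' Multiplicative Gaussian noise emulating counting statistics after data
#' reduction: \eqn{\sigma_k = \max(\mathrm{rel}\cdot I_k, \mathrm{floor})}.
#'
#' @param relative_sigma Fractional noise level (default 0.02).
#' @param floor_sigma Absolute noise floor, 1/cm.
#' @param seed Integer seed; the same seed reproduces the same curve.
#' @return Object of class `"noise_spec"`.
#' @export
noise_spec <- function(relative_sigma = 0.02, floor_sigma = 0, seed = NULL) {
  stopifnot(relative_sigma >= 0, floor_sigma >= 0)
  structure(list(relative_sigma = relative_sigma, floor_sigma = floor_sigma,
                 seed = seed),
            class = "noise_spec")
}

resolve_model_fun <- function(model, params = NULL) {
  if (is.function(model)) {
    if (is.null(params)) return(model)
    return(function(q) model(q, params))
  }
  stopifnot(is.character(model), length(model) == 1L)
  if (inherits(params, "flexcyl_params")) {
    return(function(q) eval_flexible_cylinder(q, params))
  }
  if (inherits(params, "beaucage_params")) {
    return(function(q) eval_beaucage(q, params))
  }
  if (inherits(params, "ellipsoid_chain_params")) {
    return(function(q) eval_ellipsoid_chain(q, params))
  }
  reg <- get_sans_model(model)
  p <- unlist(params)
  missing <- setdiff(reg$par_names, names(p))
  if (length(missing)) {
    stop("model '", model, "' needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  function(q) reg$eval(q, p)
}

#' Generate a synthetic scattering curve
#'
#' Evaluates a model on the instrument's q-grid, applies Gaussian
#' resolution smearing if the instrument declares a relative q-resolution,
#' and adds seeded Gaussian noise with
#' \eqn{\sigma = \max(\mathrm{rel}\cdot I, \mathrm{floor})}. The generating
#' truth (model key and parameters) is stored in the curve metadata so
#' recovery studies can compare against it.
#'
#' @param model Model key (see [sans_model_keys()]) or a function; with a
#'   parameter object ([flexcyl_params()], [beaucage_params()],
#'   [ellipsoid_chain_params()]) or named vector in `params`.
#' @param params Model parameters.
#' @param instrument An [instrument_spec()].
#' @param noise A [noise_spec()].
#' @param label Optional sample label.
#' @param f_d2o Optional D2O fraction stored in the metadata.
#' @return A [scattering_curve()].
#' @examples
#' p <- flexcyl_params(alpha1 = 1, radius = 16, kuhn = 318, contour = 5000)
#' sc <- generate_curve("flexible_cylinder_powerlaw", p,
#'                      instrument_d11(n_points = 50),
#'                      noise_spec(0.02, seed = 1))
#' @export
generate_curve <- function(model, params, instrument = instrument_d11(),
                           noise = noise_spec(), label = NULL,
                           f_d2o = NULL) {
  stopifnot(inherits(instrument, "instrument_spec"),
            inherits(noise, "noise_spec"))
  q <- if (instrument$spacing == "log") {
    exp(seq(log(instrument$q_min), log(instrument$q_max),
            length.out = instrument$n_points))
  } else {
    seq(instrument$q_min, instrument$q_max,
        length.out = instrument$n_points)
  }
  f <- resolve_model_fun(model, params)
  i0 <- if (instrument$dq_over_q > 0) {
    smear_gaussian(f, q, instrument$dq_over_q)
  } else {
    f(q)
  }
  sigma <- pmax(noise$relative_sigma * abs(i0), noise$floor_sigma)
  noisy <- if (all(sigma == 0)) {
    i0
  } else {
    eps <- if (is.null(noise$seed)) {
      rnorm(length(q), 0, sigma)
    } else {
      withr::with_seed(noise$seed, rnorm(length(q), 0, sigma))
    }
    i0 + eps
  }
  meta <- list(
    label = label, f_d2o = f_d2o,
    dq_over_q = instrument$dq_over_q,
    truth = list(model = if (is.character(model)) model else "function",
                 params = params),
    noise = unclass(noise), instrument = unclass(instrument)
  )
  scattering_curve(q, noisy,
                   sigma_i = pmax(sigma, 1e-12 * max(abs(i0), 1)),
                   sigma_q = if (instrument$dq_over_q > 0)
                     instrument$dq_over_q * q,
                   metadata = meta)
}

#' Generate a contrast-variation series
#'
#' Simulates the match-point experiment: one particle shape measured at a
#' set of D2O fractions. At each fraction the (fixed) normalized shape
#' function is scaled by the squared contrast between the solute
#' composition and the solvent, so the series' integrated intensity is an
#' exact quadratic in the D2O fraction with its minimum at the
#' composition's match point. H/D-exchange-induced shape changes are not
#' modelled.
#'
#' @param solute A [molecular_composition()].
#' @param fractions D2O volume fractions; the default is a typical
#'   six-point series (0, 20, 42, 66, 80, 100%).
#' @param forward_scale Scale of the shape term at unit contrast, 1/cm per
#'   (1e-6 A^-2)^2.
#' @param instrument An [instrument_spec()].
#' @param noise A [noise_spec()]; curve `i` uses `seed + i - 1` so
#'   realizations are independent but reproducible under one master seed.
#' @param shape_params Shape of the scatterer: a [flexcyl_params()]
#'   (default: a rigid nanofiber, R = 16 A, b = 318 A, L = 5000 A) or any
#'   parameter object accepted by [generate_curve()] together with
#'   `shape_model`.
#' @param shape_model Model key for `shape_params`.
#' @param background Flat background added at every contrast, 1/cm.
#' @param exchange_fraction Labile-H exchange fraction for the solute SLD.
#' @return Object of class `"contrast_series"`: a list with `curves`,
#'   `fractions`, and the generating `truth` (including the closed-form
#'   match point).
#' @export
generate_contrast_series <- function(solute,
                                     fractions = c(0, 0.2, 0.42, 0.66,
                                                   0.8, 1),
                                     forward_scale = 1,
                                     instrument = instrument_d11(),
                                     noise = noise_spec(),
                                     shape_params = NULL,
                                     shape_model = "flexible_cylinder_powerlaw",
                                     background = 0,
                                     exchange_fraction = 1) {
  stopifnot(inherits(solute, "molecular_composition"))
  fractions <- vapply(fractions, as_fraction, numeric(1))
  if (is.null(shape_params)) {
    shape_params <- flexcyl_params(alpha1 = 1, radius = 16, kuhn = 318,
                                   contour = 5000)
  }
  shape_fun <- resolve_model_fun(shape_model, shape_params)
  contrasts <- composition_sld(solute, fractions,
                               exchange_fraction = exchange_fraction) -
    solvent_sld(fractions)
  curves <- lapply(seq_along(fractions), function(i) {
    fi <- fractions[i]
    model_i <- function(q) {
      forward_scale * contrasts[i]^2 * shape_fun(q) + background
    }
    ns <- noise
    if (!is.null(ns$seed)) ns$seed <- ns$seed + i - 1L
    generate_curve(model_i, params = NULL, instrument = instrument,
                   noise = ns,
                   label = sprintf("contrast_%02.0f_pct_d2o", 100 * fi),
                   f_d2o = fi)
  })
  mp <- match_point(solute, exchange_fraction = exchange_fraction)
  structure(
    list(curves = curves, fractions = fractions,
         truth = list(match_point = mp$f_d2o, contrasts = contrasts,
                      forward_scale = forward_scale,
                      background = background)),
    class = "contrast_series"
  )
}

#' @export
print.contrast_series <- function(x, ...) {
  cat(sprintf("Contrast-variation series: %d curves at f_D2O = %s\n",
              length(x$curves),
              paste(format(x$fractions), collapse = ", ")))
  cat(sprintf("  generating match point: %.3f\n", x$truth$match_point))
  invisible(x)
}
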