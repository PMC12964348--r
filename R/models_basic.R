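erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Power-law scattering term
#'
#' \eqn{I(q) = \alpha_2 q^{-D} + c}. With decay exponent D near 4 this is
#' Porod scattering from sharp, solvent-impenetrable interfaces; lower
#' exponents indicate fractal or diffuse structure.
#'
#' @param q Scattering vector, 1/A (positive).
#' @param alpha2 Power-law scale.
#' @param decay_D Decay exponent.
#' @param background_c Flat background, 1/cm.
#' @return Intensities, same length as `q`.
#' @examples
#' eval_power_law(0.1, alpha2 = 1, decay_D = 4)   # 1e4
#' @export
eval_power_law <- function(q, alpha2, decay_D, background_c = 0) {
  stopifnot(all(q > 0))
  alpha2 * q^(-decay_D) + background_c
}

#' Parameters of the multi-level Beaucage unified model
#'
#' One structural level contributes a Guinier term (scale `G`, radius of
#' gyration `Rg`) and a power-law term (Porod constant `B`, decay exponent
#' `D`) with an error-function crossover. Levels are ordered from the
#' largest structure (level 1) down; the power-law term of level `i` is cut
#' off at high q by the Rg of level `i+1` (taken as 0 for the last level).
#'
#' @param G Guinier scales, 1/cm (one per level, >= 0).
#' @param Rg Radii of gyration, Angstrom (strictly decreasing across levels).
#' @param B Porod constants (>= 0).
#' @param D Decay exponents, in (0, 4.5].
#' @param background Flat background, 1/cm.
#' @return Object of class `"beaucage_params"`.
#' @examples
#' beaucage_params(G = c(100, 5), Rg = c(1800, 125), B = c(1e-6, 1e-4),
#'                 D = c(2.6, 2.6))
#' @export
beaucage_params <- function(G, Rg, B, D, background = 0) {
  n <- length(G)
  stopifnot(n >= 1L, length(Rg) == n, length(B) == n, length(D) == n)
  if (any(G < 0) || any(B < 0)) stop("G and B must be >= 0", call. = FALSE)
  if (any(Rg <= 0)) stop("Rg must be positive", call. = FALSE)
  if (n > 1L && any(diff(Rg) >= 0)) {
    stop("Rg must be strictly decreasing across levels (largest first)",
         call. = FALSE)
  }
  if (any(D <= 0 | D > 4.5)) stop("D must lie in (0, 4.5]", call. = FALSE)
  structure(list(G = G, Rg = Rg, B = B, D = D, background = background,
                 n_levels = n),
            class = "beaucage_params")
}

#' Evaluate the Beaucage unified scattering model
#'
#' \deqn{I(q) = c + \sum_{i=1}^N \left[G_i e^{-q^2 R_{g,i}^2/3}
#'   + B_i e^{-q^2 R_{g,i+1}^2/3} (1/q_i^*)^{D_i}\right],\quad
#'   q_i^* = q\,[\mathrm{erf}(q R_{g,i}/\sqrt 6)]^{-3}}
#' with \eqn{R_{g,N+1} = 0}. The power term is evaluated as
#' \eqn{[\mathrm{erf}(qR_{g,i}/\sqrt6)]^{3D_i} q^{-D_i}}, which is
#' numerically stable as \eqn{q \to 0} (it vanishes like \eqn{q^{2D_i}}).
#'
#' @param q Scattering vector, 1/A (positive).
#' @param params A [beaucage_params()].
#' @return Intensities, 1/cm.
#' @export
eval_beaucage <- function(q, params) {
  stopifnot(inherits(params, "beaucage_params"), all(q > 0))
  rg_next <- c(params$Rg[-1], 0)
  out <- rep(params$background, length(q))
  for (i in seq_len(params$n_levels)) {
    guinier <- params$G[i] * exp(-q^2 * params$Rg[i]^2 / 3)
    erfq <- erf(q * params$Rg[i] / sqrt(6))
    porod <- params$B[i] * exp(-q^2 * rg_next[i]^2 / 3) *
      erfq^(3 * params$D[i]) * q^(-params$D[i])
    out <- out + guinier + porod
  }
  out
}

#' Beaucage-consistent Porod constant
#'
#' The Porod constant that joins a level's power-law regime smoothly onto
#' its Guinier regime,
#' \deqn{B = \frac{G D}{R_g^D}\left[\frac{6D^2}{(2+D)(2+2D)}\right]^{D/2}
#'   \Gamma(D/2),}
#' useful as a starting value or for constructing self-consistent
#' synthetic levels. `G` and `B` remain independent fitting parameters.
#'
#' @param G Guinier scale, 1/cm.
#' @param Rg Radius of gyration, Angstrom.
#' @param D Decay exponent.
#' @return Porod constant B.
#' @export
beaucage_consistent_B <- function(G, Rg, D) {
  (G * D / Rg^D) * (6 * D^2 / ((2 + D) * (2 + 2 * D)))^(D / 2) *
    gamma(D / 2)
}

#' Gaussian resolution smearing
#'
#' Convolves a model curve with a Gaussian resolution function of width
#' \eqn{\sigma_q = (\Delta q/q)\, q}, the dominant effect of a relative
#' wavelength spread on a pinhole SANS instrument. The convolution is done
#' by Gauss-Legendre quadrature over +/- `n_sigma` standard deviations; the
#' model is evaluated on the shifted nodes, so no information is lost at the
#' edges of the data grid when `model` is a function.
#'
#' @param model Either a function `model(q)` returning intensities, or a
#'   numeric vector of model values aligned with `q` (then interpolated
#'   log-log with end-slope extrapolation).
#' @param q Scattering vector at which smeared intensities are wanted.
#' @param dq_over_q Relative resolution width (e.g. 0.09 for a 9%
#'   wavelength spread); 0 returns the model values unchanged.
#' @param n_quad Number of quadrature nodes.
#' @param n_sigma Truncation of the Gaussian, in standard deviations.
#' @return Smeared intensities at `q`.
#' @export
smear_gaussian <- function(model, q, dq_over_q, n_quad = 25, n_sigma = 4) {
  stopifnot(dq_over_q >= 0, all(q > 0))
  f <- if (is.function(model)) {
    model
  } else {
    values <- as.numeric(model)
    stopifnot(length(values) == length(q))
    loglog_interpolant(q, values)
  }
  if (dq_over_q == 0) return(f(q))
  if (n_sigma * dq_over_q >= 1) {
    n_sigma <- 0.99 / dq_over_q  # keep all nodes at positive q
  }
  gl <- pracma::gaussLegendre(n_quad, -n_sigma, n_sigma)
  w <- gl$w * dnorm(gl$x)
  w <- w / sum(w)
  qq <- outer(q, 1 + dq_over_q * gl$x)  # node j: q * (1 + dq/q * x_j)
  iv <- matrix(f(as.vector(qq)), nrow = length(q))
  as.vector(iv %*% w)
}

# Interpolate tabulated model values; log-log inside the grid with linear
# (power-law) continuation of the end slopes, which matches how SAS curves
# behave at their extremes. Falls back to linear interpolation if any value
# is non-positive.
loglog_interpolant <- function(q, values) {
  if (all(values > 0)) {
    lq <- log(q); lv <- log(values)
    n <- length(q)
    slope_lo <- (lv[2] - lv[1]) / (lq[2] - lq[1])
    slope_hi <- (lv[n] - lv[n - 1]) / (lq[n] - lq[n - 1])
    fa <- approxfun(lq, lv)
    function(x) {
      lx <- log(x)
      y <- fa(lx)
      lo <- lx < lq[1]; hi <- lx > lq[n]
      y[lo] <- lv[1] + slope_lo * (lx[lo] - lq[1])
      y[hi] <- lv[n] + slope_hi * (lx[hi] - lq[n])
      exp(y)
    }
  } else {
    fa <- approxfun(q, values, rule = 2)
    function(x) fa(x)
  }
}
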