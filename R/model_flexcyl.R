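# Wormlike-chain ("flexible cylinder") form factor with excluded-volume
# corrections, following the method-3 parameterization of Pedersen &
# Schurtenberger for semiflexible chains, combined with a circular
# cross-section factor. All q in 1/A, lengths in A.

# Excluded-volume expansion of Rg^2 for a chain of n = L/b Kuhn segments.
wlc_alpha2 <- function(n) (1 + (n / 3.12)^2 + (n / 8.67)^3)^(0.176 / 3)

wlc_rg2_long <- function(L, b) wlc_alpha2(L / b) * L * b / 6

# Benoit-Doty finite-length factor; series below n = 0.05 to avoid
# catastrophic cancellation (bracket -> n/2 - n^2/5 in the rod limit).
wlc_rg2_short <- function(L, b) {
  n <- L / b
  fac <- if (n < 0.05) {
    n / 2 - n^2 / 5
  } else {
    1 - 1.5 / n + 1.5 / n^2 - 0.75 / n^3 * (1 - exp(-2 * n))
  }
  wlc_rg2_long(L, b) * fac
}

# Debye coil function of u = q^2 Rg^2.
s_debye <- function(u) {
  out <- numeric(length(u))
  small <- u < 1e-3
  out[small] <- 1 - u[small] / 3 + u[small]^2 / 12
  ub <- u[!small]
  out[!small] <- 2 * (exp(-ub) + ub - 1) / ub^2
  out
}

# Crossover weight between the coil (Debye) and the excluded-volume
# power-law regime, as a function of x = q Rg. The tanh switch tends to a
# small positive constant as x -> 0 while the power-law sum diverges like
# x^(-3/nu), so the weight is clamped to zero below x = 1 (where the
# power-law branch has no meaning); the jump this introduces is O(1e-6).
wlc_w <- function(x) {
  w <- 0.5 * (1 + tanh((x - 1.523) / 0.1477))
  w[x < 1] <- 0
  w
}

# Excluded-volume chain scattering function: Debye at low qRg blended into
# C1 (qRg)^(-1/nu) + C2 (qRg)^(-2/nu) + C3 (qRg)^(-3/nu), nu = 0.585.
wlc_sexv_raw <- function(qq, rg) {
  qr <- qq * rg
  w <- wlc_w(qr)
  t1 <- qr^(-1 / 0.585)
  (1 - w) * s_debye(qr^2) +
    w * (1.22 * t1 + 0.4288 * t1^2 - 1.651 * t1^3)
}

# The C1..C3 interpolant is not monotone near qRg ~ 2 (a known artifact of
# the parameterization). We replace it by its running minimum in q,
# evaluated on a dense internal grid so the envelope does not depend on the
# caller's q-grid. Continuous, and identical to the raw function wherever
# that is decreasing.
wlc_sexv <- function(qq, rg) {
  qrmax <- max(qq) * rg
  grid <- exp(seq(log(0.01), log(max(qrmax, 0.02)), length.out = 400)) / rg
  qall <- sort(unique(c(qq, grid)))
  senv <- cummin(wlc_sexv_raw(qall, rg))
  senv[match(qq, qall)]
}

# Low-q part for long chains: excluded-volume chain plus the
# local-stiffness correction term (weight C = 3.06 n^-0.44 for n > 10).
wlc_long_low <- function(qq, L, b, rg2, c_corr) {
  u <- qq^2 * rg2
  corr <- ifelse(u < 1e-4,
                 7 / 15 + 8 * u / 15,
                 4 / 15 + 7 / (15 * u) -
                   (11 / 15 + 7 / (15 * u)) * exp(-2 * u))
  wlc_sexv(qq, sqrt(rg2)) + c_corr * (b / L) * corr
}

# Join a two-term power law a1 x^-p1 + a2 x^-p2 (+ pi/(qL)) to a low-q
# function with continuity of value and slope at the crossover.
wlc_join_coeffs <- function(slow_fun, qc, b, L, p1, p2) {
  del <- 1.001
  s1 <- slow_fun(qc)
  ds <- (slow_fun(qc * del) - s1) / (qc * (del - 1))
  xc <- qc * b
  amat <- matrix(c(xc^-p1, xc^-p2,
                   -(p1 / qc) * xc^-p1, -(p2 / qc) * xc^-p2),
                 2, 2, byrow = TRUE)
  solve(amat, c(s1 - pi / (qc * L), ds + pi / (qc^2 * L)))
}

wlc_long <- function(q, L, b) {
  n <- L / b
  rg2 <- wlc_rg2_long(L, b)
  c_corr <- if (n > 10) 3.06 * n^(-0.44) else 1
  qc <- 3.1 / b
  p1 <- 4.12; p2 <- 4.42
  ab <- wlc_join_coeffs(function(qq) wlc_long_low(qq, L, b, rg2, c_corr),
                        qc, b, L, p1, p2)
  out <- numeric(length(q))
  lo <- q * b <= 3.1
  if (any(lo)) out[lo] <- wlc_long_low(q[lo], L, b, rg2, c_corr)
  if (any(!lo)) {
    x <- q[!lo] * b
    out[!lo] <- ab[1] * x^-p1 + ab[2] * x^-p2 + pi / (q[!lo] * L)
  }
  out / (1 + c_corr * (b / L) * 7 / 15)   # normalize S(0) = 1
}

# Exact orientation-averaged form factor of a thin rigid rod of length L,
# as a function of u = qL.
p_rod <- function(u) {
  out <- numeric(length(u))
  small <- u < 1e-3
  out[small] <- 1 - u[small]^2 / 36
  ub <- u[!small]
  si <- vapply(ub, pracma::Si, numeric(1))
  out[!small] <- 2 * si / ub - 4 * sin(ub / 2)^2 / ub^2
  out
}

# Short chains (L <= 4b) are nearly rigid: blend the exact rod form factor
# with a Debye/power-law construct (p1 = 5.36, p2 = 5.62), weight
# (4 - n)/3 clamped to [0, 1]; pure rod for b >= L.
wlc_short <- function(q, L, b) {
  n <- L / b
  lam <- min(max((4 - n) / 3, 0), 1)
  rod <- p_rod(q * L)
  if (lam >= 1) return(rod)
  rg2s <- wlc_rg2_short(L, b)
  rgs <- sqrt(rg2s)
  qcb <- max(1.9 * b / rgs, 3)
  qc <- qcb / b
  p1 <- 5.36; p2 <- 5.62
  sdeb <- function(qq) s_debye(qq^2 * rg2s)
  ab <- wlc_join_coeffs(sdeb, qc, b, L, p1, p2)
  x <- q * b
  ps <- ifelse(x <= qcb, sdeb(q),
               ab[1] * x^-p1 + ab[2] * x^-p2 + pi / (q * L))
  lam * rod + (1 - lam) * ps
}

#' Wormlike-chain scattering function
#'
#' Form factor of a semiflexible chain of contour length `contour` and Kuhn
#' length `kuhn`, normalized to 1 at q = 0. For chains longer than four
#' Kuhn segments the method-3 parameterization with excluded-volume
#' corrections is used (Debye/power-law interpolation at low q with a
#' local-stiffness correction, joined to a two-term power law plus the
#' \eqn{\pi/(qL)} rod term at \eqn{qb = 3.1} with value and slope
#' continuity). Shorter chains blend towards the exact rigid-rod form
#' factor, which is reached for `kuhn >= contour`.
#'
#' @param q Scattering vector, 1/A (positive).
#' @param contour Contour length L, Angstrom.
#' @param kuhn Kuhn length b (twice the persistence length), Angstrom.
#' @return Dimensionless form factor values.
#' @export
wlc_form_factor <- function(q, contour, kuhn) {
  stopifnot(all(q > 0), contour > 0, kuhn > 0)
  if (contour / kuhn > 4) wlc_long(q, contour, kuhn)
  else wlc_short(q, contour, kuhn)
}

#' Parameters of the flexible-cylinder + power-law model
#'
#' \deqn{I(q) = \alpha_1 P_{flex}(q; R, L_C, b_{Kuhn}) + \alpha_2 q^{-D} + c}
#' where \eqn{P_{flex}} is the wormlike-chain function times the circular
#' cross-section factor \eqn{[2 J_1(qR)/(qR)]^2}, normalized to 1 at q = 0.
#' The power-law term captures Porod scattering from large, sharp
#' interfaces (fiber bundles) below the q-range of the chain signal.
#'
#' @param alpha1 Scale of the flexible-cylinder term, 1/cm.
#' @param radius Cross-section radius R, Angstrom.
#' @param kuhn Kuhn length, Angstrom.
#' @param contour Contour length, Angstrom.
#' @param alpha2 Power-law scale (>= 0).
#' @param decay Power-law decay exponent, in \[1, 5\].
#' @param background Flat background c, 1/cm.
#' @return Object of class `"flexcyl_params"`.
#' @examples
#' flexcyl_params(alpha1 = 1, radius = 16, kuhn = 318, contour = 5000)
#' @export
flexcyl_params <- function(alpha1, radius, kuhn, contour, alpha2 = 0,
                           decay = 4, background = 0) {
  stopifnot(alpha1 >= 0, radius > 0, kuhn > 0, contour > 0, alpha2 >= 0)
  if (alpha2 > 0 && (decay < 1 || decay > 5)) {
    stop("decay must lie in [1, 5]", call. = FALSE)
  }
  structure(list(alpha1 = alpha1, radius = radius, kuhn = kuhn,
                 contour = contour, alpha2 = alpha2, decay = decay,
                 background = background),
            class = "flexcyl_params")
}

# Circular cross-section factor [2 J1(x)/x]^2, x = qR.
p_cross_section <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 4
  xb <- x[!small]
  out[!small] <- (2 * besselJ(xb, 1) / xb)^2
  out
}

#' Evaluate the flexible-cylinder + power-law model
#'
#' @param q Scattering vector, 1/A (positive).
#' @param params A [flexcyl_params()].
#' @return Intensities, 1/cm.
#' @examples
#' p <- flexcyl_params(alpha1 = 1, radius = 16, kuhn = 318, contour = 5000)
#' eval_flexible_cylinder(c(0.01, 0.1), p)
#' @export
eval_flexible_cylinder <- function(q, params) {
  stopifnot(inherits(params, "flexcyl_params"), all(q > 0))
  p <- params
  s <- wlc_form_factor(q, p$contour, p$kuhn) * p_cross_section(q * p$radius)
  pw <- if (p$alpha2 > 0) p$alpha2 * q^(-p$decay) else 0
  p$alpha1 * s + pw + p$background
}
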