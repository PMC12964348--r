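#' Parameters of the random-walk ellipsoid-chain model
#'
#' Describes an elongated, flexible multi-domain particle as `n_subunits`
#' ellipsoids whose centers perform a random walk with fixed step length.
#' In the decoupling approximation the orientation-averaged intensity is
#' \deqn{I(q) \propto \sum_i V_i^2 \langle F_i^2\rangle +
#'   \sum_{i \ne j} V_i V_j \langle F_i\rangle\langle F_j\rangle
#'   \left[\frac{\sin qd}{qd}\right]^{|i-j|}}
#' with \eqn{d} the center-to-center step and \eqn{F_i} the normalized
#' ellipsoid amplitude; the \eqn{sinc^{|i-j|}} factor is the random-walk
#' average of the inter-subunit phase. Normalized so that
#' \eqn{I(0) = scale + background}.
#'
#' @param n_subunits Number of subunits (>= 1).
#' @param semi_axes Ellipsoid semi-axes in Angstrom: a length-3 vector
#'   shared by all subunits, or an `n_subunits x 3` matrix.
#' @param step_length Center-to-center distance of consecutive subunits, A.
#' @param scale Forward intensity, 1/cm.
#' @param background Flat background, 1/cm.
#' @return Object of class `"ellipsoid_chain_params"`.
#' @examples
#' ellipsoid_chain_params(5, semi_axes = c(12, 12, 20), step_length = 35)
#' @export
ellipsoid_chain_params <- function(n_subunits, semi_axes, step_length,
                                   scale = 1, background = 0) {
  stopifnot(n_subunits >= 1, step_length > 0, scale >= 0)
  if (is.matrix(semi_axes)) {
    stopifnot(nrow(semi_axes) == n_subunits, ncol(semi_axes) == 3)
  } else {
    stopifnot(length(semi_axes) == 3)
    semi_axes <- matrix(rep(semi_axes, each = n_subunits), ncol = 3)
  }
  if (any(semi_axes <= 0)) stop("semi-axes must be positive", call. = FALSE)
  structure(list(n_subunits = as.integer(n_subunits), semi_axes = semi_axes,
                 step_length = step_length, scale = scale,
                 background = background),
            class = "ellipsoid_chain_params")
}

# Normalized ellipsoid amplitude 3 j1(x)/x = 3 (sin x - x cos x)/x^3.
ellipsoid_amp <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 10
  xb <- x[!small]
  out[!small] <- 3 * (sin(xb) - xb * cos(xb)) / xb^3
  out
}

# Orientation averages <F> and <F^2> for one ellipsoid with semi-axes
# (a, b, c), by Gauss-Legendre quadrature over cos(theta) in [0,1] and
# phi in [0, pi/2] (orthorhombic symmetry).
ellipsoid_orientation_avg <- function(q, axes, n_theta = 64, n_phi = 16) {
  glt <- pracma::gaussLegendre(n_theta, 0, 1)
  glp <- pracma::gaussLegendre(n_phi, 0, pi / 2)
  ct <- glt$x
  st <- sqrt(pmax(1 - ct^2, 0))
  # effective radius for each orientation node
  r_eff <- sqrt(outer(st^2, cos(glp$x)^2) * axes[1]^2 +
                outer(st^2, sin(glp$x)^2) * axes[2]^2 +
                matrix(ct^2, n_theta, n_phi) * axes[3]^2)
  w <- outer(glt$w, glp$w)
  w <- as.vector(w) / sum(w)
  x <- outer(q, as.vector(r_eff))           # n_q x n_nodes
  fx <- matrix(ellipsoid_amp(as.vector(x)), nrow = length(q))
  list(mean = as.vector(fx %*% w), mean_sq = as.vector(fx^2 %*% w))
}

#' Evaluate the random-walk ellipsoid-chain model
#'
#' @param q Scattering vector, 1/A (positive).
#' @param params An [ellipsoid_chain_params()].
#' @param n_theta,n_phi Gauss-Legendre node counts for the orientation
#'   average.
#' @return Intensities, 1/cm.
#' @export
eval_ellipsoid_chain <- function(q, params, n_theta = 64, n_phi = 16) {
  stopifnot(inherits(params, "ellipsoid_chain_params"), all(q > 0))
  p <- params
  n <- p$n_subunits
  vol <- 4 / 3 * pi * apply(p$semi_axes, 1, prod)
  # orientation averages per distinct subunit shape
  shape_key <- apply(p$semi_axes, 1, paste, collapse = "_")
  uniq <- !duplicated(shape_key)
  avg <- vector("list", n)
  for (i in which(uniq)) {
    avg[[i]] <- ellipsoid_orientation_avg(q, p$semi_axes[i, ], n_theta, n_phi)
  }
  for (i in which(!uniq)) avg[[i]] <- avg[[match(shape_key[i], shape_key)]]
  self_term <- Reduce(`+`, lapply(seq_len(n), function(i) {
    vol[i]^2 * avg[[i]]$mean_sq
  }))
  x <- q * p$step_length
  sinc <- ifelse(abs(x) < 1e-8, 1, sin(x) / x)
  cross_term <- 0
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        cross_term <- cross_term + 2 * vol[i] * vol[j] *
          avg[[i]]$mean * avg[[j]]$mean * sinc^(j - i)
      }
    }
  }
  inorm <- (self_term + cross_term) / sum(vol)^2
  p$scale * inorm + p$background
}
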