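#' Molecular composition for scattering-length-density work
#'
#' Bundles the elemental composition of a molecule (or polymer repeat unit)
#' with the bookkeeping needed for neutron contrast calculations: how many
#' of its hydrogens are labile (solvent-exchangeable N-H/O-H), what fraction
#' of the non-labile hydrogens are biosynthetically deuterated, and the mass
#' density from which the molecular volume is derived
#' (\eqn{V = M/(\rho N_A)}).
#'
#' @param formula Elemental formula string (see [parse_formula()]) or a named
#'   count vector. Hydrogen entered as `"H"` counts all hydrogens; labile
#'   ones are singled out via `labile_h`.
#' @param labile_h Number of solvent-exchangeable hydrogens per formula unit.
#' @param deuteration Fraction of *non-labile* hydrogens replaced by
#'   deuterium (0-1, or `"75%"`).
#' @param density Mass density in g/mL; must be positive.
#' @param label Optional sample label.
#' @return Object of class `"molecular_composition"` with fields `counts`,
#'   `labile_h`, `deuteration`, `density`, `molar_mass` (g/mol) and
#'   `volume_A3` (molecular volume in cubic Angstrom).
#' @examples
#' # anhydro-GlcNAc repeat unit of chitin (3 exchangeable H: N-H, O3-H, O6-H)
#' chitin <- molecular_composition("C8H13NO5", labile_h = 3, density = 1.5)
#' chitin$volume_A3
#' @export
molecular_composition <- function(formula, labile_h = 0, deuteration = 0,
                                  density, label = NULL) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("element counts must be named", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.neutron_b_coh))
  if (length(unknown)) {
    stop("no tabulated scattering length for: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0)) stop("element counts must be >= 0", call. = FALSE)
  deuteration <- as_fraction(deuteration, "deuteration")
  if (deuteration < 0 || deuteration > 1) {
    stop("deuteration must lie in [0, 1]", call. = FALSE)
  }
  n_h <- if ("H" %in% names(counts)) unname(counts[["H"]]) else 0
  if (labile_h < 0 || labile_h > n_h) {
    stop("labile_h must lie between 0 and the total H count (", n_h, ")",
         call. = FALSE)
  }
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("density must be a single positive number (g/mL)", call. = FALSE)
  }
  molar_mass <- sum(counts * .atomic_mass[names(counts)])
  volume_A3 <- molar_mass / (density * .N_AVOGADRO) * 1e24
  structure(
    list(counts = counts, labile_h = labile_h, deuteration = deuteration,
         density = density, molar_mass = molar_mass, volume_A3 = volume_A3,
         label = label),
    class = "molecular_composition"
  )
}

#' @export
print.molecular_composition <- function(x, ...) {
  f <- paste0(names(x$counts), ifelse(x$counts > 1, x$counts, ""),
              collapse = "")
  cat("Molecular composition", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat("  formula     :", f, sprintf("(M = %.2f g/mol)\n", x$molar_mass))
  cat(sprintf("  density     : %.3f g/mL  (V = %.1f A^3)\n",
              x$density, x$volume_A3))
  cat(sprintf("  labile H    : %d of %d H\n", x$labile_h,
              if ("H" %in% names(x$counts)) x$counts[["H"]] else 0L))
  cat(sprintf("  deuteration : %.0f%% of non-labile H\n", 100 * x$deuteration))
  invisible(x)
}

#' Solvent specification for an H2O/D2O mixture
#'
#' @param f_d2o Volume fraction of D2O (0-1, or `"47%"`).
#' @param exchange_fraction Fraction of labile hydrogens on the solute that
#'   actually exchange with the solvent (default 1, full exchange).
#' @return Object of class `"solvent_spec"`.
#' @examples
#' solvent_spec("47%")
#' @export
solvent_spec <- function(f_d2o, exchange_fraction = 1) {
  f_d2o <- as_fraction(f_d2o, "f_d2o")
  exchange_fraction <- as_fraction(exchange_fraction, "exchange_fraction")
  if (any(f_d2o < 0 | f_d2o > 1)) stop("f_d2o must lie in [0, 1]",
                                       call. = FALSE)
  if (exchange_fraction < 0 || exchange_fraction > 1) {
    stop("exchange_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(f_d2o = f_d2o, exchange_fraction = exchange_fraction),
            class = "solvent_spec")
}

# SLD of a fixed formula/density, in 1e-6 A^-2. b in fm, V in A^3:
# sld[1e-6 A^-2] = 10 * sum(b)/V.
sld_from_counts <- function(counts, density) {
  m <- sum(counts * .atomic_mass[names(counts)])
  v <- m / (density * .N_AVOGADRO) * 1e24
  10 * sum(counts * .neutron_b_coh[names(counts)]) / v
}

#' Scattering-length density of an H2O/D2O mixture
#'
#' Linear in the D2O volume fraction between the pure-water endpoints, which
#' are computed from tabulated coherent scattering lengths and the densities
#' of light and heavy water (0.997 and 1.105 g/mL).
#'
#' @param solvent A [solvent_spec()], or a numeric vector of D2O fractions.
#' @return SLD in units of \eqn{10^{-6} \mathrm{\AA}^{-2}}, vectorized over
#'   the fraction.
#' @examples
#' solvent_sld(c(0, 0.5, 1))
#' @export
solvent_sld <- function(solvent) {
  f <- if (inherits(solvent, "solvent_spec")) solvent$f_d2o else
    as_fraction(solvent, "f_d2o")
  sld_h <- sld_from_counts(.WATER_H$counts, .WATER_H$density)
  sld_d <- sld_from_counts(.WATER_D$counts, .WATER_D$density)
  (1 - f) * sld_h + f * sld_d
}

#' Scattering-length density of a molecular composition in solvent
#'
#' Sums tabulated coherent scattering lengths over the formula unit.
#' Non-labile hydrogens carry the deuteration fraction of the composition;
#' labile hydrogens carry a solvent-weighted scattering length, with a
#' fraction `exchange_fraction * f_d2o` counted as deuterium. The molecular
#' volume comes from the mass density, so the SLD is affine in the D2O
#' fraction with slope
#' \eqn{10\,x\,n_\mathrm{lab}(b_D - b_H)/V} (x = exchange fraction).
#'
#' @param comp A [molecular_composition()].
#' @param solvent A [solvent_spec()] or numeric D2O fraction(s).
#' @param exchange_fraction Overrides the solvent's exchange fraction if
#'   given.
#' @return SLD in \eqn{10^{-6} \mathrm{\AA}^{-2}}, vectorized over the D2O
#'   fraction.
#' @examples
#' chitin <- molecular_composition("C8H13NO5", labile_h = 3, density = 1.5)
#' composition_sld(chitin, 0)     # fully protiated chitin in H2O
#' @export
composition_sld <- function(comp, solvent, exchange_fraction = NULL) {
  stopifnot(inherits(comp, "molecular_composition"))
  if (inherits(solvent, "solvent_spec")) {
    f <- solvent$f_d2o
    ex <- if (is.null(exchange_fraction)) solvent$exchange_fraction else
      as_fraction(exchange_fraction, "exchange_fraction")
  } else {
    f <- as_fraction(solvent, "f_d2o")
    ex <- if (is.null(exchange_fraction)) 1 else
      as_fraction(exchange_fraction, "exchange_fraction")
  }
  if (!is.finite(comp$volume_A3) || comp$volume_A3 <= 0) {
    stop("molecular volume undefined (non-positive density?)", call. = FALSE)
  }
  b_h <- .neutron_b_coh[["H"]]
  b_d <- .neutron_b_coh[["D"]]
  counts <- comp$counts
  n_h <- if ("H" %in% names(counts)) unname(counts[["H"]]) else 0
  n_lab <- comp$labile_h
  n_fix <- n_h - n_lab
  other <- counts[setdiff(names(counts), "H")]
  b_other <- sum(other * .neutron_b_coh[names(other)])
  b_nonlab <- n_fix * ((1 - comp$deuteration) * b_h + comp$deuteration * b_d)
  b_lab <- n_lab * (b_h + ex * f * (b_d - b_h))
  10 * (b_other + b_nonlab + b_lab) / comp$volume_A3
}

#' Closed-form contrast match point
#'
#' Both the composition SLD and the solvent SLD are affine functions of the
#' D2O volume fraction, so the match point -- the fraction at which the two
#' are equal and the composition is rendered invisible to neutrons -- has a
#' closed form. The solution may fall outside \[0, 1\]; it is then reported
#' as-is and flagged unreachable.
#'
#' @param comp A [molecular_composition()].
#' @param exchange_fraction Fraction of labile hydrogens that exchange
#'   (default 1).
#' @return Object of class `"sans_match_point"` with fields `f_d2o`,
#'   `percent`, `reachable`, `sld_at_match` and `method = "closed_form"`.
#' @examples
#' chitin <- molecular_composition("C8H13NO5", labile_h = 3, density = 1.5)
#' match_point(chitin)   # ~44% D2O at 1.5 g/mL, full exchange
#' @export
match_point <- function(comp, exchange_fraction = 1) {
  stopifnot(inherits(comp, "molecular_composition"))
  ex <- as_fraction(exchange_fraction, "exchange_fraction")
  c0 <- composition_sld(comp, 0, exchange_fraction = ex)
  c1 <- composition_sld(comp, 1, exchange_fraction = ex)
  s0 <- solvent_sld(0)
  s1 <- solvent_sld(1)
  dslope <- (s1 - s0) - (c1 - c0)
  scale <- max(abs(c(s1 - s0, c1 - c0, 1e-12)))
  if (abs(dslope) < 1e-10 * scale) {
    stop("no match point: composition and solvent SLD lines are parallel",
         call. = FALSE)
  }
  f <- (c0 - s0) / dslope
  structure(
    list(f_d2o = f, percent = 100 * f, reachable = (f >= 0 && f <= 1),
         sld_at_match = s0 + f * (s1 - s0), exchange_fraction = ex,
         method = "closed_form"),
    class = "sans_match_point"
  )
}

#' @export
print.sans_match_point <- function(x, ...) {
  cat(sprintf("Contrast match point: %.1f%% D2O  (%s)\n", x$percent,
              x$method))
  if (!is.null(x$sld_at_match)) {
    cat(sprintf("  SLD at match : %.3f x 1e-6 A^-2\n", x$sld_at_match))
  }
  if (!x$reachable) cat("  NOTE: outside [0, 100]% -- not reachable\n")
  invisible(x)
}

#' Match point from a measured contrast-variation series
#'
#' Implements the integrated-intensity estimator: each curve in the series
#' is integrated over a q-window with the trapezoid rule on its native grid
#' (default 0.03-0.4 1/A), the integrated intensity is regressed on the D2O
#' fraction with a second-degree polynomial, and the match point is the
#' abscissa of the parabola's minimum. Because the scattered intensity is
#' proportional to the squared contrast, which is an exact quadratic in the
#' D2O fraction, the estimator is unbiased for an ideal series.
#'
#' @param series A `"contrast_series"` (see [generate_contrast_series()]) or
#'   a list of [scattering_curve()] objects whose `metadata$f_d2o` is set.
#' @param q_window Length-2 numeric, integration window in 1/A.
#' @return `"sans_match_point"` object with the fitted polynomial
#'   coefficients and the integrated intensities attached.
#' @export
match_point_from_series <- function(series, q_window = c(0.03, 0.4)) {
  curves <- if (inherits(series, "contrast_series")) series$curves else series
  if (!is.list(curves)) stop("'series' must be a list of curves",
                             call. = FALSE)
  f <- vapply(curves, function(cv) {
    fv <- cv$metadata$f_d2o
    if (is.null(fv)) NA_real_ else as_fraction(fv, "f_d2o")
  }, numeric(1))
  if (anyNA(f)) stop("every curve needs metadata$f_d2o", call. = FALSE)
  if (length(unique(f)) < 3L) {
    stop("need at least 3 distinct D2O fractions for a quadratic fit",
         call. = FALSE)
  }
  stopifnot(is.numeric(q_window), length(q_window) == 2L,
            q_window[1] < q_window[2])
  integ <- vapply(curves, function(cv) {
    keep <- cv$q >= q_window[1] & cv$q <= q_window[2]
    if (sum(keep) < 2L) {
      stop("q_window [", q_window[1], ", ", q_window[2],
           "] not covered by curve '", cv$metadata$label %||% "?", "'",
           call. = FALSE)
    }
    pracma::trapz(cv$q[keep], cv$intensity[keep])
  }, numeric(1))
  fit <- lm(integ ~ f + I(f^2))
  a <- unname(coef(fit))
  if (anyNA(a) || !is.finite(a[3]) || a[3] <= 0) {
    stop("no interior minimum: quadratic coefficient is not positive",
         call. = FALSE)
  }
  fmin <- -a[2] / (2 * a[3])
  structure(
    list(f_d2o = fmin, percent = 100 * fmin,
         reachable = (fmin >= 0 && fmin <= 1), sld_at_match = NULL,
         coefficients = a, integrated = data.frame(f_d2o = f, integral = integ),
         q_window = q_window, method = "integrated_series"),
    class = "sans_match_point"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
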