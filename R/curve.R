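#' Reduced SAS dataset
#'
#' Container for a reduced small-angle scattering curve: a strictly
#' increasing positive q-grid, absolute intensities, one-standard-deviation
#' uncertainties, and optionally a per-point q-resolution. Free-form
#' metadata (sample label, D2O fraction, instrument, provenance flags)
#' travels with the curve.
#'
#' @param q Scattering vector, 1/Angstrom. Positive; sorted if needed (with
#'   a warning).
#' @param intensity Intensity, 1/cm; same length as `q`.
#' @param sigma_i Uncertainty on the intensity, 1/cm; strictly positive.
#'   If `NULL`, 1% of `|intensity|` is used and flagged in the metadata.
#' @param sigma_q Optional q-resolution (sigma), 1/Angstrom.
#' @param metadata Named list.
#' @return Object of class `"scattering_curve"`.
#' @examples
#' sc <- scattering_curve(q = c(0.01, 0.02, 0.05),
#'                        intensity = c(10, 5, 1), sigma_i = c(1, 0.5, 0.1))
#' sc
#' @export
scattering_curve <- function(q, intensity, sigma_i = NULL, sigma_q = NULL,
                             metadata = list()) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  n <- length(q)
  if (n < 1L || length(intensity) != n) {
    stop("q and intensity must be non-empty and of equal length",
         call. = FALSE)
  }
  if (!all(is.finite(q)) || !all(is.finite(intensity))) {
    stop("q and intensity must be finite", call. = FALSE)
  }
  if (any(q <= 0)) stop("q must be strictly positive", call. = FALSE)
  if (is.null(sigma_i)) {
    sigma_i <- pmax(0.01 * abs(intensity), 1e-12)
    metadata$sigma_synthesized <- TRUE
  }
  sigma_i <- as.numeric(sigma_i)
  if (length(sigma_i) != n || any(!is.finite(sigma_i)) || any(sigma_i <= 0)) {
    stop("sigma_i must be finite, positive and match q in length",
         call. = FALSE)
  }
  if (!is.null(sigma_q)) {
    sigma_q <- as.numeric(sigma_q)
    if (length(sigma_q) != n || any(!is.finite(sigma_q)) || any(sigma_q < 0)) {
      stop("sigma_q must be finite, non-negative and match q in length",
           call. = FALSE)
    }
  }
  if (is.unsorted(q, strictly = TRUE)) {
    warning("q not strictly increasing; sorting the curve", call. = FALSE)
    o <- order(q)
    q <- q[o]; intensity <- intensity[o]; sigma_i <- sigma_i[o]
    if (!is.null(sigma_q)) sigma_q <- sigma_q[o]
    if (any(diff(q) == 0)) stop("duplicated q values", call. = FALSE)
  }
  structure(
    list(q = q, intensity = intensity, sigma_i = sigma_i, sigma_q = sigma_q,
         metadata = metadata),
    class = "scattering_curve"
  )
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("Scattering curve: %d points, q = %.4g .. %.4g 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  if (!is.null(x$metadata$label)) cat("  label:", x$metadata$label, "\n")
  if (!is.null(x$metadata$f_d2o)) {
    cat(sprintf("  f_D2O: %.2f\n", as_fraction(x$metadata$f_d2o)))
  }
  if (isTRUE(x$metadata$sigma_synthesized)) {
    cat("  note : sigma_i synthesized (1% of I)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity, sigma_i = x$sigma_i)
  if (!is.null(x$sigma_q)) d$sigma_q <- x$sigma_q
  d
}

#' @export
length.scattering_curve <- function(x) length(x$q)

#' Restrict a curve to a q-range
#'
#' @param curve A [scattering_curve()].
#' @param q_range Length-2 numeric `c(qmin, qmax)`; `NA` entries leave that
#'   side open.
#' @return A [scattering_curve()] with only the points inside the range.
#' @export
subset_q <- function(curve, q_range) {
  stopifnot(inherits(curve, "scattering_curve"), length(q_range) == 2L)
  lo <- if (is.na(q_range[1])) -Inf else q_range[1]
  hi <- if (is.na(q_range[2])) Inf else q_range[2]
  keep <- curve$q >= lo & curve$q <= hi
  if (!any(keep)) stop("q_range excludes all points", call. = FALSE)
  scattering_curve(curve$q[keep], curve$intensity[keep],
                   curve$sigma_i[keep],
                   if (!is.null(curve$sigma_q)) curve$sigma_q[keep],
                   curve$metadata)
}
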