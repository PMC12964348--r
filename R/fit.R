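# Weighted nonlinear least-squares fitting of scattering models, with the
# constraint handling used for fiber systems: box bounds (notably
# Rg <= pi/q_min), fixed parameters (notably the contour length), seeded
# multi-start, and log-scale optimization of strictly positive shape
# parameters for conditioning across decades.

.LOG_LO <- log(1e-12)
.LOG_HI <- log(1e12)
.LIN_HI <- 1e12

#' Fitting configuration
#'
#' @param start Named numeric vector of starting values (overrides the
#'   model's data-driven heuristics, per parameter).
#' @param lower,upper Named numeric vectors of box bounds (partial; merged
#'   into the model defaults).
#' @param fixed Named numeric vector of parameters to hold fixed.
#' @param weighting `"sigma"` (weights \eqn{1/\sigma^2}, default) or
#'   `"uniform"`.
#' @param q_range Optional `c(qmin, qmax)` sub-range to fit.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param ftol Relative convergence tolerance on the sum of squares.
#' @param n_starts Number of multi-start repetitions (first start
#'   unperturbed; the rest perturbed around it).
#' @param seed Integer seed for the multi-start perturbations.
#' @param dq_over_q Relative q-resolution used to smear the model during
#'   fitting; `NULL` takes the value recorded in the curve's metadata
#'   (0 if absent).
#' @return Object of class `"fit_config"`.
#' @export
fit_config <- function(start = NULL, lower = NULL, upper = NULL,
                       fixed = NULL, weighting = c("sigma", "uniform"),
                       q_range = NULL, max_iter = 200, ftol = 1e-12,
                       n_starts = 1, seed = NULL, dq_over_q = NULL) {
  weighting <- match.arg(weighting)
  if (!is.null(q_range)) stopifnot(length(q_range) == 2L)
  structure(list(start = start, lower = lower, upper = upper, fixed = fixed,
                 weighting = weighting, q_range = q_range,
                 max_iter = max_iter, ftol = ftol, n_starts = n_starts,
                 seed = seed, dq_over_q = dq_over_q),
            class = "fit_config")
}

# ---- model registry ---------------------------------------------------

eval_beaucage_raw <- function(q, G, Rg, B, D, background) {
  # constructor-free evaluation so the optimizer may visit transient states
  n <- length(G)
  rg_next <- c(Rg[-1], 0)
  out <- rep(background, length(q))
  for (i in seq_len(n)) {
    erfq <- erf(q * Rg[i] / sqrt(6))
    out <- out + G[i] * exp(-q^2 * Rg[i]^2 / 3) +
      B[i] * exp(-q^2 * rg_next[i]^2 / 3) * erfq^(3 * D[i]) * q^(-D[i])
  }
  out
}

guinier_heuristic <- function(curve) {
  n <- length(curve$q)
  k <- max(5L, n %/% 4L)
  idx <- seq_len(min(k, n))
  ok <- curve$intensity[idx] > 0
  if (sum(ok) >= 3) {
    f <- lm(log(curve$intensity[idx][ok]) ~ I(curve$q[idx][ok]^2))
    sl <- coef(f)[2]
    if (is.finite(sl) && sl < 0) {
      return(c(G = unname(exp(coef(f)[1])), Rg = sqrt(-3 * unname(sl))))
    }
  }
  c(G = max(curve$intensity[1], 1e-3), Rg = 1 / (3 * min(curve$q)))
}

powerlaw_heuristic <- function(curve) {
  ok <- curve$intensity > 0
  if (sum(ok) >= 3) {
    f <- lm(log(curve$intensity[ok]) ~ log(curve$q[ok]))
    d <- min(max(-unname(coef(f)[2]), 0.5), 4.4)
    a <- exp(unname(coef(f)[1]))
  } else {
    d <- 2.5
    a <- max(median(curve$intensity), 1e-6)
  }
  c(alpha2 = a, decay = d)
}

beaucage_level_start <- function(curve) {
  g <- guinier_heuristic(curve)
  p <- powerlaw_heuristic(curve)
  rg <- min(g[["Rg"]], pi / min(curve$q))
  b_start <- max(median(curve$intensity * curve$q^p[["decay"]]) * 0.5, 1e-10)
  c(G = g[["G"]], Rg = rg, B = b_start,
    D = min(max(p[["decay"]], 1), 4.4))
}

get_sans_model <- function(model, data = NULL) {
  if (is.function(model)) {
    return(list(key = "custom", eval = model, par_names = NULL,
                positive = character(), lower = NULL, upper = NULL,
                start = function(curve) NULL))
  }
  switch(
    model,
    power_law = list(
      key = model,
      eval = function(q, p) eval_power_law(q, p[["alpha2"]], p[["decay"]],
                                           p[["background"]]),
      par_names = c("alpha2", "decay", "background"),
      positive = character(),
      lower = c(alpha2 = 0, decay = 0.5, background = 0),
      upper = c(alpha2 = .LIN_HI, decay = 6, background = .LIN_HI),
      start = function(curve) {
        p <- powerlaw_heuristic(curve)
        c(alpha2 = p[["alpha2"]], decay = p[["decay"]],
          background = 0.5 * max(min(curve$intensity), 1e-8))
      }
    ),
    guinier = list(
      key = model,
      eval = function(q, p) p[["G"]] * exp(-q^2 * p[["Rg"]]^2 / 3) +
        p[["background"]],
      par_names = c("G", "Rg", "background"),
      positive = "Rg",
      lower = c(G = 0, Rg = 1e-3, background = 0),
      upper = c(G = .LIN_HI, Rg = 1e7, background = .LIN_HI),
      start = function(curve) {
        g <- guinier_heuristic(curve)
        c(G = g[["G"]], Rg = g[["Rg"]],
          background = 0.5 * max(min(curve$intensity), 1e-8))
      }
    ),
    beaucage1 = list(
      key = model,
      eval = function(q, p) eval_beaucage_raw(q, p[["G1"]], p[["Rg1"]],
                                              p[["B1"]], p[["D1"]],
                                              p[["background"]]),
      par_names = c("G1", "Rg1", "B1", "D1", "background"),
      positive = "Rg1",
      lower = c(G1 = 0, Rg1 = 1e-3, B1 = 0, D1 = 0.5, background = 0),
      upper = c(G1 = .LIN_HI, Rg1 = 1e7, B1 = .LIN_HI, D1 = 4.5,
                background = .LIN_HI),
      start = function(curve) {
        s <- beaucage_level_start(curve)
        c(G1 = s[["G"]], Rg1 = s[["Rg"]], B1 = s[["B"]], D1 = s[["D"]],
          background = 0.5 * max(min(curve$intensity), 1e-8))
      }
    ),
    beaucage2 = list(
      key = model,
      eval = function(q, p) eval_beaucage_raw(
        q, c(p[["G1"]], p[["G2"]]), c(p[["Rg1"]], p[["Rg2"]]),
        c(p[["B1"]], p[["B2"]]), c(p[["D1"]], p[["D2"]]), p[["background"]]),
      par_names = c("G1", "Rg1", "B1", "D1", "G2", "Rg2", "B2", "D2",
                    "background"),
      positive = c("Rg1", "Rg2"),
      lower = c(G1 = 0, Rg1 = 1e-3, B1 = 0, D1 = 0.5, G2 = 0, Rg2 = 1e-3,
                B2 = 0, D2 = 0.2, background = 0),
      upper = c(G1 = .LIN_HI, Rg1 = 1e7, B1 = .LIN_HI, D1 = 4.5,
                G2 = .LIN_HI, Rg2 = 1e7, B2 = .LIN_HI, D2 = 4.5,
                background = .LIN_HI),
      start = function(curve) {
        qs <- sqrt(min(curve$q) * max(curve$q))
        lo <- beaucage_level_start(subset_q(curve, c(NA, qs)))
        hi <- beaucage_level_start(subset_q(curve, c(qs, NA)))
        rg2 <- min(hi[["Rg"]], lo[["Rg"]] / 5)
        c(G1 = lo[["G"]], Rg1 = lo[["Rg"]], B1 = lo[["B"]], D1 = lo[["D"]],
          G2 = hi[["G"]], Rg2 = rg2, B2 = hi[["B"]], D2 = hi[["D"]],
          background = 0.5 * max(min(curve$intensity), 1e-8))
      }
    ),
    flexible_cylinder_powerlaw = list(
      key = model,
      eval = function(q, p) {
        s <- wlc_form_factor(q, p[["contour"]], p[["kuhn"]]) *
          p_cross_section(q * p[["radius"]])
        p[["alpha1"]] * s + p[["alpha2"]] * q^(-p[["decay"]]) +
          p[["background"]]
      },
      par_names = c("alpha1", "radius", "kuhn", "contour", "alpha2",
                    "decay", "background"),
      positive = c("radius", "kuhn", "contour"),
      lower = c(alpha1 = 0, radius = 1, kuhn = 5, contour = 10, alpha2 = 0,
                decay = 1, background = 0),
      upper = c(alpha1 = .LIN_HI, radius = 500, kuhn = 1e5, contour = 1e7,
                alpha2 = .LIN_HI, decay = 5, background = .LIN_HI),
      start = function(curve) {
        q <- curve$q; I <- curve$intensity
        c0 <- 0.5 * max(min(I), 1e-8)
        a2 <- max((I[1] - c0) * q[1]^4 * 0.5, 1e-12)
        r0 <- 20; k0 <- 150; l0 <- 5000
        mid <- which.min(abs(q - 0.02))
        # scale the chain term so it passes through the mid-q data
        pq <- wlc_form_factor(q[mid], l0, k0) *
          p_cross_section(q[mid] * r0)
        flex_mid <- max(I[mid] - a2 * q[mid]^-4 - c0, 0.2 * I[mid])
        a1 <- max(flex_mid / max(pq, 1e-6), 1e-8)
        c(alpha1 = a1, radius = r0, kuhn = k0, contour = l0,
          alpha2 = a2, decay = 4, background = c0)
      }
    ),
    stop("unknown model key: '", model, "'", call. = FALSE)
  )
}

#' List the built-in fittable model keys
#' @return Character vector of model keys accepted by [fit_curve()] and the
#'   CLI.
#' @export
sans_model_keys <- function() {
  c("power_law", "guinier", "beaucage1", "beaucage2",
    "flexible_cylinder_powerlaw")
}

# ---- transformed-parameter machinery ----------------------------------

to_internal <- function(p, positive) {
  out <- ifelse(names(p) %in% positive, log(pmax(p, 1e-300)), p)
  names(out) <- names(p)
  out
}
from_internal <- function(th, positive) {
  out <- ifelse(names(th) %in% positive, exp(th), th)
  names(out) <- names(th)
  out
}

jacobian_fd <- function(fn, par) {
  r0 <- fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- 1e-6 * (abs(par[j]) + 1e-6)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

# ---- main fitting routine ---------------------------------------------

#' Fit a scattering model to a reduced curve
#'
#' Minimizes \eqn{\sum_k [(I_k - I_{model}(q_k))/\sigma_k]^2} by
#' Levenberg-Marquardt least squares with box bounds. Strictly positive
#' shape parameters (radii, Kuhn length, Rg) are optimized on a log scale;
#' scale parameters stay linear so they may collapse to zero. Parameter
#' uncertainties are one standard deviation, from the covariance
#' \eqn{(J^T J)^{-1} \chi^2_{red}} at the optimum. Non-convergence is
#' reported in the result status, not thrown; a singular covariance yields
#' `NA` uncertainties.
#'
#' @param data A [scattering_curve()].
#' @param model A model key (see [sans_model_keys()]) or a function
#'   `model(q, pars)` taking a named parameter vector (then `config$start`
#'   must name every parameter).
#' @param config A [fit_config()].
#' @return Object of class `"sans_fit"`: estimates, 1-sigma uncertainties,
#'   reduced chi-square, covariance, convergence status and a log of active
#'   constraints.
#' @export
fit_curve <- function(data, model, config = fit_config()) {
  stopifnot(inherits(data, "scattering_curve"))
  if (!inherits(config, "fit_config")) stop("config must be a fit_config()",
                                            call. = FALSE)
  if (!is.null(config$q_range)) data <- subset_q(data, config$q_range)
  reg <- get_sans_model(model, data)
  par_names <- reg$par_names %||% names(config$start)
  if (is.null(par_names)) {
    stop("custom models need named starting values in config$start",
         call. = FALSE)
  }
  start <- setNames(rep(NA_real_, length(par_names)), par_names)
  auto <- reg$start(data)
  if (!is.null(auto)) start[names(auto)] <- auto
  if (!is.null(config$start)) start[names(config$start)] <- config$start
  if (anyNA(start)) {
    stop("no starting value for: ",
         paste(par_names[is.na(start)], collapse = ", "), call. = FALSE)
  }
  lower <- setNames(rep(-Inf, length(par_names)), par_names)
  upper <- setNames(rep(Inf, length(par_names)), par_names)
  if (!is.null(reg$lower)) lower[names(reg$lower)] <- reg$lower
  if (!is.null(reg$upper)) upper[names(reg$upper)] <- reg$upper
  if (!is.null(config$lower)) lower[names(config$lower)] <- config$lower
  if (!is.null(config$upper)) upper[names(config$upper)] <- config$upper
  fixed <- config$fixed
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), par_names)
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    start[names(fixed)] <- fixed
  }
  free <- setdiff(par_names, names(fixed))
  n <- length(data$q)
  if (n <= length(free)) {
    stop("need more data points (", n, ") than free parameters (",
         length(free), ")", call. = FALSE)
  }
  start[free] <- pmin(pmax(start[free], lower[free]), upper[free])

  sigma <- if (config$weighting == "uniform") rep(1, n) else data$sigma_i
  dq <- config$dq_over_q %||% data$metadata$dq_over_q %||% 0
  eval_full <- function(pars) {
    if (dq > 0) {
      smear_gaussian(function(qq) reg$eval(qq, pars), data$q, dq)
    } else {
      reg$eval(data$q, pars)
    }
  }

  positive <- intersect(reg$positive %||% character(), free)
  th0 <- to_internal(start[free], positive)
  th_lo <- to_internal(pmax(lower[free],
                            ifelse(names(start[free]) %in% positive,
                                   1e-12, -Inf)), positive)
  th_hi <- to_internal(pmin(upper[free],
                            ifelse(names(start[free]) %in% positive,
                                   1e12, Inf)), positive)

  resid_fn <- function(th) {
    pars <- start
    pars[free] <- from_internal(setNames(th, free), positive)
    r <- (data$intensity - eval_full(pars)) / sigma
    r[!is.finite(r)] <- 1e8
    r
  }

  run_one <- function(th_start) {
    tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(th_start, th_lo), th_hi),
        lower = th_lo, upper = th_hi, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = config$max_iter, ftol = config$ftol, ptol = 1e-12)),
      error = function(e) NULL)
  }

  starts <- list(th0)
  if (config$n_starts > 1) {
    perturbed <- withr::with_seed(config$seed %||% 1L, {
      lapply(seq_len(config$n_starts - 1L), function(i) {
        th <- th0 + rnorm(length(th0), 0, 0.4)
        pmin(pmax(th, th_lo), th_hi)
      })
    })
    starts <- c(starts, perturbed)
  }
  fits <- Filter(Negate(is.null), lapply(starts, run_one))
  if (!length(fits)) {
    stop("all optimizer starts failed for model '", reg$key, "'",
         call. = FALSE)
  }
  best <- fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]

  th_hat <- setNames(best$par, free)
  est <- start
  est[free] <- from_internal(th_hat, positive)
  chisq <- best$deviance
  dof <- n - length(free)
  chisq_red <- chisq / dof

  J <- jacobian_fd(resid_fn, th_hat)
  # column-scale before inverting: scale parameters can differ from shape
  # parameters by many orders of magnitude
  cn <- sqrt(colSums(J^2))
  cn[cn == 0 | !is.finite(cn)] <- 1
  cov_th <- tryCatch({
    cs <- solve(crossprod(sweep(J, 2, cn, "/")))
    sweep(sweep(cs, 2, cn, "/"), 1, cn, "/") * chisq_red
  }, error = function(e) NULL)
  se <- setNames(rep(NA_real_, length(par_names)), par_names)
  cov_par <- NULL
  if (!is.null(cov_th) && all(is.finite(cov_th))) {
    scale_d <- ifelse(free %in% positive, est[free], 1)  # delta method
    cov_par <- diag(scale_d, nrow = length(free)) %*% cov_th %*%
      diag(scale_d, nrow = length(free))
    dimnames(cov_par) <- list(free, free)
    dvar <- diag(cov_par)
    se[free] <- ifelse(dvar >= 0, sqrt(dvar), NA_real_)
  }

  # an active lower bound is hit exactly (scale parameters collapsing to
  # 0); upper bounds (protocol caps) are detected with a small slack
  at_bound <- free[(th_hat - th_lo[free]) < 1e-12 * (1 + abs(th_lo[free])) |
                   (th_hi[free] - th_hat) < 1e-4 * (1 + abs(th_hi[free]))]
  constraints <- character()
  if (!is.null(fixed)) {
    constraints <- c(constraints,
                     paste0("fixed: ", names(fixed), " = ", fixed))
  }
  if (length(at_bound)) {
    constraints <- c(constraints,
                     paste0("at bound: ", at_bound, " = ",
                            signif(est[at_bound], 6)))
  }
  converged <- best$info %in% 1:4
  structure(
    list(model = reg$key, estimates = est, se = se,
         fixed = names(fixed) %||% character(),
         chisq = chisq, chisq_red = chisq_red, dof = dof,
         n_points = n, n_free = length(free),
         covariance = cov_par, converged = converged,
         status = best$info, message = best$message,
         at_bound = at_bound, constraints = constraints,
         weighting = config$weighting, dq_over_q = dq,
         n_starts = config$n_starts, seed = config$seed),
    class = "sans_fit"
  )
}

#' @export
print.sans_fit <- function(x, ...) {
  cat(sprintf("Model '%s' fit: %d points, %d free parameters\n",
              x$model, x$n_points, x$n_free))
  cat(sprintf("  reduced chi-square: %.4g   (converged: %s)\n",
              x$chisq_red, x$converged))
  tab <- data.frame(
    estimate = signif(x$estimates, 6),
    uncertainty = signif(x$se, 3),
    note = ifelse(names(x$estimates) %in% x$fixed, "fixed",
                  ifelse(names(x$estimates) %in% x$at_bound, "at bound", ""))
  )
  print(tab)
  invisible(x)
}

#' @export
coef.sans_fit <- function(object, ...) object$estimates

#' Flat key-value report of a fit
#'
#' Serializes a [fit_curve()] result to a flat named list (estimates,
#' uncertainties, reduced chi-square, constraint log), convenient for text
#' or JSON reports laid out like published fit-parameter tables.
#'
#' @param fit A `"sans_fit"`.
#' @return Named list of scalars plus a `constraints` character vector.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "sans_fit"))
  out <- list(model = fit$model)
  for (nm in names(fit$estimates)) {
    out[[nm]] <- unname(fit$estimates[[nm]])
    out[[paste0(nm, "_sd")]] <- unname(fit$se[[nm]])
  }
  out$chisq_red <- fit$chisq_red
  out$n_points <- fit$n_points
  out$n_free <- fit$n_free
  out$converged <- fit$converged
  out$constraints <- fit$constraints
  out
}

# ---- protocol-level fits ----------------------------------------------

#' Two-stage fit of the two-level Beaucage unified model
#'
#' Stage 1 fits a single-level unified model separately on the low-q and
#' high-q halves of the curve (split at the geometric mean of the q-range
#' unless overridden) to obtain starting values; stage 2 fits the combined
#' two-level model from those starts. Both radii of gyration are bounded
#' above by \eqn{\pi/q_{min}} so that no reported size lies outside the
#' measured window; a fitted Rg pinned at that bound is flagged in the
#' result. If a stage-1 sub-fit fails, heuristic Guinier/power-law starting
#' values are used instead and a warning is recorded in the result log.
#'
#' @param data A [scattering_curve()]; should span a wide q-range
#'   (qmax/qmin of 30 or more) so two levels can be separated.
#' @param n_levels Number of levels (currently 1 or 2; 1 falls through to a
#'   plain [fit_curve()]).
#' @param config A [fit_config()]; `n_starts` below 5 is raised to 5 for
#'   the combined stage.
#' @param q_split Optional split point for stage 1, 1/A.
#' @return A `"sans_fit"` for the combined model, with stage-1 fits in
#'   `$stages` and any stage-1 fallback recorded in `$warnings`.
#' @export
fit_beaucage_two_stage <- function(data, n_levels = 2, config = fit_config(),
                                   q_split = NULL) {
  stopifnot(inherits(data, "scattering_curve"))
  if (!is.null(config$q_range)) {
    data <- subset_q(data, config$q_range)
    config$q_range <- NULL
  }
  if (n_levels == 1) return(fit_curve(data, "beaucage1", config))
  if (n_levels != 2) stop("only 1 or 2 levels are supported", call. = FALSE)
  qmin <- min(data$q); qmax <- max(data$q)
  if (qmax / qmin < 30) {
    warning("q-range spans less than 1.5 decades; levels may not separate",
            call. = FALSE)
  }
  rg_cap <- pi / qmin
  qs <- q_split %||% sqrt(qmin * qmax)
  warnings_log <- character()

  stage_fit <- function(range, label) {
    sub <- subset_q(data, range)
    cfg <- fit_config(weighting = config$weighting,
                      upper = c(Rg1 = rg_cap),
                      max_iter = config$max_iter, ftol = config$ftol,
                      n_starts = 1, dq_over_q = config$dq_over_q)
    tryCatch(fit_curve(sub, "beaucage1", cfg), error = function(e) {
      warnings_log <<- c(warnings_log,
                         paste0("stage-1 ", label, " fit failed (",
                                conditionMessage(e),
                                "); using heuristic starts"))
      s <- beaucage_level_start(sub)
      list(estimates = c(G1 = s[["G"]], Rg1 = min(s[["Rg"]], rg_cap),
                         B1 = s[["B"]], D1 = s[["D"]],
                         background = 0.5 * max(min(sub$intensity), 1e-8)))
    })
  }
  lo <- stage_fit(c(NA, qs), "low-q")
  hi <- stage_fit(c(qs, NA), "high-q")

  rg1_start <- min(lo$estimates[["Rg1"]], rg_cap)
  rg2_start <- min(hi$estimates[["Rg1"]], rg_cap)
  if (rg2_start >= rg1_start) rg2_start <- rg1_start / 10
  start <- c(G1 = lo$estimates[["G1"]], Rg1 = rg1_start,
             B1 = lo$estimates[["B1"]], D1 = lo$estimates[["D1"]],
             G2 = hi$estimates[["G1"]], Rg2 = rg2_start,
             B2 = hi$estimates[["B1"]], D2 = hi$estimates[["D1"]],
             background = hi$estimates[["background"]])
  if (!is.null(config$start)) start[names(config$start)] <- config$start
  cfg2 <- config
  cfg2$start <- start
  cfg2$upper <- c(c(Rg1 = rg_cap, Rg2 = rg_cap), config$upper)
  cfg2$upper <- cfg2$upper[!duplicated(names(cfg2$upper))]
  cfg2$n_starts <- max(config$n_starts, 5)
  fit <- fit_curve(data, "beaucage2", cfg2)

  # report levels ordered largest-Rg first
  if (fit$estimates[["Rg2"]] > fit$estimates[["Rg1"]]) {
    swap <- function(v) {
      v[c("G1", "Rg1", "B1", "D1", "G2", "Rg2", "B2", "D2")] <-
        v[c("G2", "Rg2", "B2", "D2", "G1", "Rg1", "B1", "D1")]
      v
    }
    fit$estimates <- swap(fit$estimates)
    fit$se <- swap(fit$se)
    map <- c(G1 = "G2", Rg1 = "Rg2", B1 = "B2", D1 = "D2",
             G2 = "G1", Rg2 = "Rg1", B2 = "B1", D2 = "D1")
    fit$at_bound <- unname(ifelse(fit$at_bound %in% names(map),
                                  map[fit$at_bound], fit$at_bound))
    fit$constraints <- c(
      fit$constraints[!grepl("^at bound", fit$constraints)],
      if (length(fit$at_bound)) {
        paste0("at bound: ", fit$at_bound, " = ",
               signif(fit$estimates[fit$at_bound], 6))
      })
  }
  fit$constraints <- unique(c(fit$constraints,
                              sprintf("Rg <= pi/q_min = %.4g A", rg_cap)))
  fit$stages <- list(low = lo, high = hi, q_split = qs)
  fit$warnings <- warnings_log
  fit
}

#' Reference fit for semiflexible nanofiber curves
#'
#' Fits the flexible-cylinder + power-law model with the contour length
#' held fixed (default 5000 A, about \eqn{2\pi/q_{min}} for a typical
#' pinhole SANS q-range: fibers longer than the measurement window cannot
#' be sized and are fixed just above it). Free parameters: scale, radius,
#' Kuhn length, power-law scale and decay exponent, flat background.
#'
#' The fit runs in two phases: the Kuhn length is first held at its
#' starting value while the well-conditioned parameters (scales, radius,
#' decay exponent, background) settle, then everything is released from the
#' phase-1 optimum (the Kuhn direction is strongly coupled to the power-law
#' term, and a joint cold start regularly lands in a spurious basin). The
#' Kuhn length is bounded above by `contour/4.2`: the protocol addresses
#' semiflexible fibers with many Kuhn segments per contour, and the bound
#' keeps the fit inside that regime.
#'
#' @param data A [scattering_curve()] covering roughly 0.0013-0.41 1/A.
#' @param contour Fixed contour length, Angstrom.
#' @param config A [fit_config()]; `n_starts` below 3 is raised to 3 for
#'   phase 2.
#' @return A `"sans_fit"`.
#' @export
fit_chitin_reference <- function(data, contour = 5000,
                                 config = fit_config()) {
  stopifnot(inherits(data, "scattering_curve"))
  config$fixed <- c(config$fixed, c(contour = contour))
  config$fixed <- config$fixed[!duplicated(names(config$fixed))]
  kuhn_cap <- contour / 4.2
  config$upper <- c(config$upper,
                    c(kuhn = kuhn_cap))[!duplicated(names(
                      c(config$upper, c(kuhn = kuhn_cap))))]
  kuhn0 <- min(unname(config$start["kuhn"] %|na|% 150), kuhn_cap)
  cfg1 <- config
  cfg1$fixed <- c(config$fixed, c(kuhn = kuhn0))
  cfg1$n_starts <- 1
  phase1 <- tryCatch(fit_curve(data, "flexible_cylinder_powerlaw", cfg1),
                     error = function(e) NULL)
  cfg2 <- config
  if (!is.null(phase1)) {
    st <- phase1$estimates[setdiff(names(phase1$estimates),
                                   names(config$fixed))]
    st["kuhn"] <- kuhn0
    cfg2$start <- c(config$start,
                    st[setdiff(names(st), names(config$start))])
  }
  cfg2$n_starts <- max(config$n_starts, 3)
  fit <- fit_curve(data, "flexible_cylinder_powerlaw", cfg2)
  fit$constraints <- unique(c(fit$constraints,
                              sprintf("kuhn <= contour/4.2 = %.4g A",
                                      kuhn_cap)))
  fit
}

`%|na|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a
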