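# Multi-load-case parameter identification by bounded least squares, staged
# as passive-then-active: the decoupled passive/active structure of all four
# models lets the passive parameters be identified from the six passive load
# cases and the active parameters from the active uniaxial-along-fiber curve
# alone.

# fitted parameter names per model and stage
fit_param_names <- function(model, stage = c("passive", "active")) {
  stage <- match.arg(stage)
  if (model == "ase") {
    if (stage == "passive") c("G1", "G2", "D1", "D2", "lambda_star")
    else c("sigma_max", "a", "lambda_opta")
  } else {
    if (stage == "passive") c("alpha", "beta", "gamma", "omega0")
    else c("Popt", "lambda_opt", "lambda_min")
  }
}

# physiological default box constraints
default_fit_bounds <- function(names) {
  lower <- c(G1 = 1e-4, G2 = 1e-4, D1 = 1e-4, D2 = 1e-4, lambda_star = 1.05,
             sigma_max = 1e-4, a = 1e-4, lambda_opta = 1.0,
             alpha = 1e-4, beta = 1e-4, gamma = 1e-4, omega0 = 0.01,
             Popt = 1e-4, lambda_opt = 1.0, lambda_min = 0.3)
  upper <- c(G1 = 1e3, G2 = 1e3, D1 = 1e3, D2 = 1e2, lambda_star = 2.0,
             sigma_max = 1e3, a = 1e4, lambda_opta = 1.6,
             alpha = 50, beta = 50, gamma = 1e4, omega0 = 0.99,
             Popt = 1e4, lambda_opt = 1.6, lambda_min = 0.9)
  list(lower = lower[names], upper = upper[names])
}

set_fit_params <- function(params, names, x) {
  for (i in seq_along(names)) params[[names[i]]] <- x[i]
  params
}

#' Stacked residuals of a model against a set of curves
#'
#' Concatenates `model response - sample` over all samples of all curves.
#' Active curves are evaluated at tetanus (time activation 1), matching the
#' isometric tetanic conditions of the experimental active data.
#' Constitutive failures at trial parameters are mapped to large finite
#' penalties so a bounded optimizer stays in-domain.
#'
#' @param params A `muscle_params` object (the trial parameter set).
#' @param curves List of [experimental_curve()] objects.
#' @return Numeric residual vector (kPa).
#' @export
residuals_curves <- function(params, curves) {
  if (inherits(curves, "experimental_curve")) curves <- list(curves)
  if (!length(curves)) stop("no curves supplied", call. = FALSE)
  unlist(lapply(curves, function(cu) {
    act <- if (cu$state[1] == "active") muscle_activation("tetanic") else {
      muscle_activation("passive")
    }
    vapply(seq_len(nrow(cu)), function(i) {
      val <- tryCatch(
        nominal_response(params, cu$loadcase[1], cu$x[i], act),
        error = function(e) NA_real_
      )
      if (!is.finite(val)) 1e6 else val - cu$P_kPa[i]
    }, numeric(1))
  }), use.names = FALSE)
}

run_lm_fit <- function(params, curves, names, x0, lower, upper, control,
                       restarts = 4L) {
  fn <- function(x) residuals_curves(set_fit_params(params, names, x), curves)
  one <- function(x) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = x, lower = lower, upper = upper, fn = fn,
                         control = control),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(list(ok = FALSE, message = conditionMessage(res), par = x,
                  niter = 0L, deviance = sum(fn(x)^2)))
    }
    list(ok = res$info %in% 1:4, message = res$message, par = res$par,
         niter = res$niter, deviance = res$deviance)
  }
  best <- one(x0)
  # local least-squares solvers can stall in flat valleys of the exponential
  # stress laws; deterministic jittered restarts escape them. The restart
  # target is a residual norm far below any physical stress scale.
  target <- 1e-8 * max(1, sqrt(sum(unlist(
    lapply(curves, function(cu) cu$P_kPa)
  )^2)))
  attempt <- 0L
  while (sqrt(best$deviance) > target && attempt < restarts) {
    attempt <- attempt + 1L
    set.seed(1000L + attempt)
    base <- if (attempt %% 2L == 1L) x0 else best$par
    x_try <- pmin(pmax(base * exp(stats::runif(length(x0), -log(2), log(2))),
                       lower), upper)
    cand <- one(x_try)
    if (cand$deviance < best$deviance) best <- cand
  }
  best
}

# column norms of the numeric Jacobian of the residuals; parameters whose
# column is numerically zero do not influence any supplied curve
jacobian_column_norms <- function(params, curves, names, x) {
  r0 <- residuals_curves(set_fit_params(params, names, x), curves)
  vapply(seq_along(names), function(j) {
    h <- 1e-5 * max(abs(x[j]), 1e-3)
    xp <- x
    xp[j] <- xp[j] + h
    xm <- x
    xm[j] <- xm[j] - h
    rp <- residuals_curves(set_fit_params(params, names, xp), curves)
    rm <- residuals_curves(set_fit_params(params, names, xm), curves)
    sqrt(sum(((rp - rm) / (2 * h))^2))
  }, numeric(1))
}

finish_fit <- function(params, curves, names, lm, unidentifiable) {
  params <- set_fit_params(params, names, lm$par)
  structure(list(
    model = params$model,
    params = params,
    estimates = stats::setNames(lm$par, names),
    residual_norm = sqrt(lm$deviance),
    per_curve_errors = lapply(curves, error_measures, params = params),
    converged = lm$ok,
    n_evals = lm$niter,
    message = lm$message,
    unidentifiable = unidentifiable
  ), class = "fit_result")
}

#' Fit the passive parameters of a model to passive curves
#'
#' Bounded Levenberg-Marquardt least squares over the passive parameters
#' only (ASE: `G1`, `G2`, `D1`, `D2`, `lambda_star`; generalized
#' active-strain family: `alpha`, `beta`, `gamma`, `omega0`). The
#' incompressibility parameters are held fixed. For the ASE model the
#' along-fiber passive parameters are pre-fitted on the uniaxial
#' along-fiber curve (independent of the shear moduli) before the joint
#' fit, and jittered restarts guard against local minima. Parameters whose
#' residual
#' Jacobian column vanishes on the supplied curves (e.g. the ASE shear
#' moduli when only uniaxial-along-fiber data is given) are reported in the
#' result's `unidentifiable` field and a warning is raised.
#'
#' @param curves List of passive [experimental_curve()] objects.
#' @param params Starting `muscle_params` object; its current values seed
#'   the optimizer unless `x0` is given.
#' @param x0 Optional named start values for the fitted parameters.
#' @param bounds Optional list with `lower`, `upper` named vectors.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @param restarts Maximum number of deterministic jittered restarts used
#'   to escape local minima when the residual has not reached the noiseless
#'   target.
#' @return A `fit_result`: fitted `params`, `estimates`, `residual_norm`
#'   (kPa), `per_curve_errors`, `converged`, `n_evals`, `unidentifiable`.
#' @export
fit_passive <- function(curves, params, x0 = NULL, bounds = NULL,
                        control = minpack.lm::nls.lm.control(maxiter = 200),
                        restarts = 4L) {
  if (inherits(curves, "experimental_curve")) curves <- list(curves)
  if (any(vapply(curves, function(cu) cu$state[1], "") != "passive")) {
    stop("fit_passive expects passive curves only", call. = FALSE)
  }
  modes <- unique(vapply(curves, function(cu) cu$loadcase[1], ""))
  if (length(modes) < 2L) {
    warning("passive fit from a single load mode is generally not identifiable",
            call. = FALSE)
  }
  names <- fit_param_names(params$model, "passive")
  if (is.null(bounds)) bounds <- default_fit_bounds(names)
  start <- vapply(names, function(nm) params[[nm]], numeric(1))
  if (!is.null(x0)) start[names(x0)] <- x0
  start <- pmin(pmax(start, bounds$lower), bounds$upper)
  # the ASE uniaxial-along-fiber response is independent of the shear
  # moduli, so the along-fiber passive parameters can be pre-fitted on that
  # curve alone; seeding the joint fit this way sidesteps a local minimum
  # of the five-parameter problem
  if (params$model == "ase") {
    utcaf <- Filter(function(cu) cu$loadcase[1] == "UTCAF", curves)
    fiber <- intersect(c("D1", "D2", "lambda_star"), names)
    if (length(utcaf) && length(fiber) == 3L &&
        all(fiber %in% names(bounds$lower))) {
      pre <- run_lm_fit(set_fit_params(params, names, start), utcaf, fiber,
                        start[fiber], bounds$lower[fiber],
                        bounds$upper[fiber], control, restarts)
      start[fiber] <- pre$par
    }
  }
  norms <- jacobian_column_norms(params, curves, names, start)
  # a parameter is unidentifiable when its residual sensitivity is
  # negligible against the most sensitive parameter (relative threshold:
  # finite-difference roundoff of the residuals sits orders of magnitude
  # below it)
  bad <- which(norms < 1e-6 * max(norms, 1))
  unident <- names[bad]
  if (length(unident)) {
    warning(sprintf("parameter(s) not identifiable from the supplied curves: %s",
                    paste(unident, collapse = ", ")), call. = FALSE)
  }
  lm <- run_lm_fit(params, curves, names, start, bounds$lower, bounds$upper,
                   control, restarts)
  finish_fit(params, curves, names, lm, unident)
}

#' Fit the active parameters to an active uniaxial-along-fiber curve
#'
#' Fits the active parameters (ASE: `sigma_max`, `a`, `lambda_opta`;
#' generalized active-strain family: `Popt`, `lambda_opt`, `lambda_min`) at
#' tetanus with the passive parameters held fixed, typically at the values
#' returned by [fit_passive()]. For the ASE model only the product
#' `sigma_max * a` is identifiable from stress data; the split is stabilized
#' by the box constraints.
#'
#' @param curve An active UTCAF [experimental_curve()].
#' @inheritParams fit_passive
#' @return A `fit_result`.
#' @export
fit_active <- function(curve, params, x0 = NULL, bounds = NULL,
                       control = minpack.lm::nls.lm.control(maxiter = 200),
                       restarts = 4L) {
  if (!inherits(curve, "experimental_curve") || curve$state[1] != "active" ||
      curve$loadcase[1] != "UTCAF") {
    stop("fit_active expects a single active UTCAF curve", call. = FALSE)
  }
  names <- fit_param_names(params$model, "active")
  if (is.null(bounds)) bounds <- default_fit_bounds(names)
  start <- vapply(names, function(nm) params[[nm]], numeric(1))
  if (!is.null(x0)) start[names(x0)] <- x0
  start <- pmin(pmax(start, bounds$lower), bounds$upper)
  lm <- run_lm_fit(params, list(curve), names, start, bounds$lower,
                   bounds$upper, control, restarts)
  finish_fit(params, list(curve), names, lm, character(0))
}

#' Per-curve goodness-of-fit measures
#'
#' Root-mean-square error (kPa), RMSE normalized by the data range, and the
#' maximum absolute deviation of the model response from the samples.
#'
#' @param curve An [experimental_curve()].
#' @param params A `muscle_params` object.
#' @return Named numeric vector `rmse`, `nrmse`, `max_abs_dev`.
#' @export
error_measures <- function(curve, params) {
  r <- residuals_curves(params, list(curve))
  rng <- diff(range(curve$P_kPa))
  rmse <- sqrt(mean(r^2))
  c(rmse = rmse,
    nrmse = if (rng > 0) rmse / rng else NA_real_,
    max_abs_dev = max(abs(r)))
}
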