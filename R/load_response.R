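# Homogeneous-deformation drivers: analytic fully incompressible nominal
# stress-stretch responses, nearly incompressible counterparts with relaxed
# traction-free faces, stress-free stretch under free contraction, and the
# isometric tetanic stress.

# reported stress component and traction-free face per load case; the
# traction-free assignments follow standard uniaxial / planar-tension
# testing with the fiber axis along e3. SAF reports the pressure-independent
# shear component P32.
LOADCASE_COMPONENTS <- list(
  UTCAF = list(report = c(3L, 3L), free = 1L),
  UTCTF = list(report = c(1L, 1L), free = 2L),
  SAF   = list(report = c(3L, 2L), free = NA_integer_),
  PSAF  = list(report = c(3L, 3L), free = 1L),
  PSTF  = list(report = c(1L, 1L), free = 3L),
  PSTIF = list(report = c(1L, 1L), free = 2L)
)

#' Nominal stress response of a homogeneous load case
#'
#' First Piola-Kirchhoff stress component reported for the load case under
#' the fully incompressible formulation, with the reaction pressure
#' determined by the traction-free face (`P11 = 0` for UTCAF and PSAF,
#' `P22 = 0` for UTCTF and PSTIF, `P33 = 0` for PSTF; the SAF shear
#' component `P32` is pressure-independent).
#'
#' @param params A `muscle_params` object.
#' @param mode One of [LOAD_CASES].
#' @param magnitude Stretch (shear amount for `SAF`).
#' @param act A [muscle_activation()].
#' @return Nominal stress in kPa.
#' @export
nominal_response <- function(params, mode, magnitude,
                             act = muscle_activation("passive")) {
  mode <- match.arg(mode, LOAD_CASES)
  comp <- LOADCASE_COMPONENTS[[mode]]
  st <- loadcase_deformation(mode, magnitude)
  r <- muscle_stress(params, st, act, incompressible = TRUE)
  S <- r$S
  if (!is.na(comp$free)) {
    Cinv <- solve(st$C)
    Finvt <- t(solve(st$F))
    i <- comp$free
    p <- (st$F %*% S)[i, i] / Finvt[i, i]
    P <- st$F %*% (S - p * Cinv)
  } else {
    P <- st$F %*% S
  }
  P[comp$report[1L], comp$report[2L]]
}

#' Sweep a nominal stress response over a deformation grid
#'
#' @inheritParams nominal_response
#' @param grid Strictly increasing numeric vector of stretches (shear
#'   amounts for `SAF`).
#' @return A `data.frame` (class `response_curve`) with columns `loadcase`,
#'   `state`, `model`, `x`, `P_kPa`.
#' @export
response_sweep <- function(params, mode, grid,
                           act = muscle_activation("passive")) {
  mode <- match.arg(mode, LOAD_CASES)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  P <- vapply(grid, function(x) nominal_response(params, mode, x, act),
              numeric(1))
  structure(data.frame(
    loadcase = mode,
    state = if (act$state == "passive") "passive" else "active",
    model = params$model,
    x = grid,
    P_kPa = P,
    stringsAsFactors = FALSE
  ), class = c("response_curve", "data.frame"))
}

#' Nearly incompressible nominal response with relaxed lateral faces
#'
#' Evaluates the nearly incompressible model (volumetric terms active) with
#' the prescribed stretch of the load case and the remaining lateral
#' stretches determined so that the nominal traction on the free faces
#' vanishes, as they would in a displacement-driven experiment. For `SAF`
#' the deformation is fully prescribed and the stress is evaluated directly.
#' As the incompressibility parameter grows, the result approaches the
#' fully incompressible [nominal_response()].
#'
#' @inheritParams nominal_response
#' @return Nominal stress in kPa.
#' @export
nominal_response_compressible <- function(params, mode, magnitude,
                                          act = muscle_activation("passive")) {
  mode <- match.arg(mode, LOAD_CASES)
  lam <- magnitude
  if (mode == "SAF") {
    st <- loadcase_deformation("SAF", lam)
    return(muscle_stress(params, st, act)$P[3, 2])
  }
  # free diagonal entries and their isochoric starting values
  setup <- switch(mode,
    UTCAF = list(fixed = c(NA, NA, lam), free = c(1L, 2L), tied = TRUE,
                 x0 = lam^(-1 / 2)),
    UTCTF = list(fixed = c(lam, NA, NA), free = c(2L, 3L), tied = TRUE,
                 x0 = lam^(-1 / 2)),
    PSAF = list(fixed = c(NA, 1, lam), free = 1L, tied = FALSE, x0 = 1 / lam),
    PSTF = list(fixed = c(lam, 1, NA), free = 3L, tied = FALSE, x0 = 1 / lam),
    PSTIF = list(fixed = c(lam, NA, 1), free = 2L, tied = FALSE, x0 = 1 / lam)
  )
  build_F <- function(x) {
    d <- setup$fixed
    if (setup$tied) d[setup$free] <- x else d[setup$free] <- x
    diag(d)
  }
  resid <- function(x) {
    st <- deformation_state(build_F(if (setup$tied) rep(x[1], 2) else x))
    P <- muscle_stress(params, st, act)$P
    idx <- if (setup$tied) setup$free[1L] else setup$free
    vapply(idx, function(i) P[i, i], numeric(1))
  }
  x <- if (setup$tied) setup$x0[1] else setup$x0
  n <- length(x)
  for (iter in 1:80) {
    r <- resid(x)
    if (max(abs(r)) < 1e-9) break
    Jm <- matrix(0, n, n)
    hx <- 1e-7 * pmax(abs(x), 1)
    for (j in seq_len(n)) {
      xp <- x
      xm <- x
      xp[j] <- xp[j] + hx[j]
      xm[j] <- xm[j] - hx[j]
      Jm[, j] <- (resid(xp) - resid(xm)) / (2 * hx[j])
    }
    step <- solve(Jm, r)
    # damped update keeping stretches positive
    fac <- 1
    repeat {
      xn <- x - fac * step
      if (all(xn > 0.05)) break
      fac <- fac / 2
    }
    x <- xn
  }
  st <- deformation_state(build_F(if (setup$tied) rep(x[1], 2) else x))
  P <- muscle_stress(params, st, act)$P
  comp <- LOADCASE_COMPONENTS[[mode]]$report
  P[comp[1L], comp[2L]]
}

#' Stress-free stretch under free contraction
#'
#' Fiber stretch at which the fully incompressible uniaxial-along-fiber
#' (UTCAF) nominal stress vanishes under the given activation -- the
#' homogeneous analogue of the free contraction of a unit cube, whose static
#' equilibrium without external load is the stress-free state.
#'
#' @param params A `muscle_params` object.
#' @param act A [muscle_activation()]; tetanic by default.
#' @param lower Lower end of the root bracket.
#' @param tol Root tolerance.
#' @return The stretch in (`lower`, 1] at which the response crosses zero.
#' @export
stress_free_stretch <- function(params, act = muscle_activation("tetanic"),
                                lower = NULL, tol = 1e-8) {
  f <- function(lam) nominal_response(params, "UTCAF", lam, act)
  if (resolve_ft(act, params) == 0) return(1)
  if (is.null(lower)) {
    lmin <- if (params$model == "ase") 0.4 * params$lambda_opta else {
      params$lambda_min
    }
    lower <- max(lmin + 1e-3, 0.45)
  }
  upper <- 1 - 1e-9
  if (f(lower) * f(upper) > 0) {
    stop(sprintf(
      "no sign change of the UTCAF response in [%.4g, 1): f(lo) = %.4g, f(hi) = %.4g",
      lower, f(lower), f(upper)
    ), call. = FALSE)
  }
  stats::uniroot(f, c(lower, upper), tol = tol)$root
}

#' Isometric stress at held reference length
#'
#' Fully incompressible UTCAF nominal fiber stress at stretch 1 under the
#' given activation: the force per reference area a muscle held at its
#' reference length develops.
#'
#' @inheritParams stress_free_stretch
#' @return Nominal stress in kPa.
#' @export
isometric_stress <- function(params, act = muscle_activation("tetanic")) {
  nominal_response(params, "UTCAF", 1, act)
}
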