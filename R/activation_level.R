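# Activation-parameter computation: explicit Lambert-W solution (GASA),
# implicit Newton solution (ASA), and the closed-form expression with its
# stretch derivative (GASAM), together with the uniaxial passive generalized
# invariants they require.

#' Generalized invariants of incompressible uniaxial fiber-aligned loading
#'
#' Closed forms for the passive generalized invariants under the
#' incompressible uniaxial deformation \eqn{C = \mathrm{diag}(1/\lambda,
#' 1/\lambda, \lambda^2)} (fibers along the third axis):
#' \deqn{\tilde I_p = \frac{\omega_0}{3}\left(\frac{2}{\lambda} +
#' \lambda^2\right) + (1 - \omega_0) \lambda^2, \qquad
#' \tilde J_p = \frac{\omega_0}{3}\left(2\lambda + \frac{1}{\lambda^2}\right)
#' + \frac{1 - \omega_0}{\lambda^2}}
#' together with the stretch derivative of \eqn{\tilde I_p}.
#'
#' @param lambda Fiber stretch, > 0 (vectorized).
#' @param omega0 Matrix weighting factor in (0, 1].
#' @return List with `Itilde_p`, `Jtilde_p`, `Itilde_p_prime`.
#' @export
uniaxial_passive_invariants <- function(lambda, omega0) {
  if (any(lambda <= 0)) stop("stretch must be positive", call. = FALSE)
  stopifnot(omega0 > 0, omega0 <= 1)
  wp <- 1 - omega0
  list(
    Itilde_p = (omega0 / 3) * (2 / lambda + lambda^2) + wp * lambda^2,
    Jtilde_p = (omega0 / 3) * (2 * lambda + 1 / lambda^2) + wp / lambda^2,
    Itilde_p_prime = (omega0 / 3) * (-2 / lambda^2 + 2 * lambda) +
      wp * 2 * lambda
  )
}

# elastic generalized invariants of incompressible uniaxial loading after
# the multiplicative active split: Ce = diag((1-w)/lambda, (1-w)/lambda,
# lambda^2/(1-w)^2)
uniaxial_elastic_invariants <- function(lambda, omega_a, omega0) {
  wp <- 1 - omega0
  q <- 1 - omega_a
  list(
    Itilde_e = (omega0 / 3) * (2 * q / lambda + lambda^2 / q^2) +
      wp * lambda^2 / q^2,
    Jtilde_e = (omega0 / 3) * (2 * lambda / q + q^2 / lambda^2) +
      wp * q^2 / lambda^2,
    dIe = (omega0 / 3) * (-2 / lambda + 2 * lambda^2 / q^3) +
      wp * 2 * lambda^2 / q^3,
    dJe = (omega0 / 3) * (2 * lambda / q^2 - 2 * q / lambda^2) -
      wp * 2 * q / lambda^2
  )
}

# integral of the active force-stretch dependency from lambda_min to lambda,
# split at the kink of the piecewise definition
fxi_integral <- function(lambda, lambda_opt, lambda_min) {
  if (lambda <= lambda_min) return(0)
  stats::integrate(f_xi, lower = lambda_min, upper = lambda,
                   lambda_opt = lambda_opt, lambda_min = lambda_min,
                   rel.tol = 1e-12, abs.tol = 1e-10)$value
}

#' Explicit activation parameter of the GASA model (Lambert W)
#'
#' Solves the uniaxial calibration condition -- the frozen-activation
#' nominal fiber stress must equal the passive plus active nominal stress --
#' in closed form on the principal branch \eqn{W_0} of the Lambert W
#' function:
#' \deqn{\omega_a = \frac{W_0(\chi^*)}{\alpha \lambda^2} -
#' \frac{\tilde I_p'}{2 \lambda}, \quad
#' \chi^* = \frac{\alpha}{2} \lambda \tilde I_p'
#' e^{\frac{\alpha}{2} \lambda \tilde I_p'} + P_a \frac{2 \alpha
#' \lambda}{\gamma} e^{\frac{\alpha}{2} (2 - 2 \tilde I_p +
#' \lambda \tilde I_p')}}
#'
#' @param lambda Fiber stretch, > 0.
#' @param Pa Active nominal stress (kPa), >= 0.
#' @param params A [gasa_params()] (or any generalized active-strain family
#'   parameter set supplying `alpha`, `gamma`, `omega0`).
#' @return Activation parameter in [0, 1); exactly 0 for `Pa = 0`.
#' @export
omega_gasa <- function(lambda, Pa, params) {
  stopifnot(lambda > 0)
  if (Pa < 0) stop("active nominal stress must be nonnegative", call. = FALSE)
  if (Pa == 0) return(0)
  al <- params$alpha
  inv <- uniaxial_passive_invariants(lambda, params$omega0)
  Ip <- inv$Itilde_p
  Ipp <- inv$Itilde_p_prime
  x0 <- (al / 2) * lambda * Ipp
  chi <- x0 * exp(x0) +
    Pa * (2 * al * lambda / params$gamma) *
      exp((al / 2) * (2 - 2 * Ip + lambda * Ipp))
  if (chi < -exp(-1)) {
    stop("Lambert-W argument below its domain: nonphysical activation input",
         call. = FALSE)
  }
  wa <- pracma::lambertWp(chi) / (al * lambda^2) - Ipp / (2 * lambda)
  wa <- max(wa, 0)
  if (wa >= 1) stop("activation parameter reached 1: singular activation",
                    call. = FALSE)
  wa
}

#' Implicit activation parameter of the ASA model (Newton)
#'
#' Solves the energy balance between the elastic generalized invariants of
#' the actively decomposed uniaxial deformation and the passive energy plus
#' the work of the active nominal stress,
#' \deqn{\tfrac{1}{\alpha}(e^{\alpha(\tilde I_e - 1)} - 1) +
#' \tfrac{1}{\beta}(e^{\beta(\tilde J_e - 1)} - 1) =
#' \tfrac{1}{\alpha}(e^{\alpha(\tilde I_p - 1)} - 1) +
#' \tfrac{1}{\beta}(e^{\beta(\tilde J_p - 1)} - 1) +
#' \tfrac{4}{\gamma} P_{opt} f_t \int_{\lambda_{min}}^{\lambda} f_\xi\,
#' d\tilde\lambda,}
#' by a Newton iteration seeded with the closed-form GASAM activation level,
#' with a bisection fallback.
#'
#' @param lambda Fiber stretch, > 0.
#' @param ft Time-activation level in [0, 1].
#' @param params An [asa_params()] (or compatible) parameter set.
#' @param tol Convergence tolerance on the energy residual.
#' @return Activation parameter in [0, 1); 0 for vanishing activation.
#' @export
omega_asa <- function(lambda, ft, params, tol = 1e-12) {
  stopifnot(lambda > 0, ft >= 0)
  amp <- params$Popt * ft
  if (amp == 0 || lambda <= params$lambda_min) return(0)
  al <- params$alpha
  be <- params$beta
  w0 <- params$omega0
  inv <- uniaxial_passive_invariants(lambda, w0)
  rhs <- (exp(al * (inv$Itilde_p - 1)) - 1) / al +
    (exp(be * (inv$Jtilde_p - 1)) - 1) / be +
    (4 / params$gamma) * amp *
      fxi_integral(lambda, params$lambda_opt, params$lambda_min)
  g <- function(w) {
    e <- uniaxial_elastic_invariants(lambda, w, w0)
    (exp(al * (e$Itilde_e - 1)) - 1) / al +
      (exp(be * (e$Jtilde_e - 1)) - 1) / be - rhs
  }
  gprime <- function(w) {
    e <- uniaxial_elastic_invariants(lambda, w, w0)
    exp(al * (e$Itilde_e - 1)) * e$dIe + exp(be * (e$Jtilde_e - 1)) * e$dJe
  }
  w <- omega_gasam(lambda, ft, params)$omega_a
  w <- min(max(w, 0), 0.999)
  converged <- FALSE
  for (i in 1:60) {
    gw <- g(w)
    if (abs(gw) < tol) {
      converged <- TRUE
      break
    }
    step <- gw / gprime(w)
    w_new <- w - step
    if (!is.finite(w_new) || w_new <= 0 || w_new >= 0.999999) break
    w <- w_new
  }
  if (!converged || abs(g(w)) >= tol) {
    lo <- 0
    hi <- 0.999999
    if (g(lo) > 0 || g(hi) < 0) {
      stop(sprintf(
        "no activation root in [0, 1): residuals g(0) = %.3g, g(1-) = %.3g",
        g(lo), g(hi)
      ), call. = FALSE)
    }
    w <- stats::uniroot(g, c(lo, hi), tol = 1e-14)$root
  }
  w
}

#' Explicit activation parameter of the GASAM model and its derivative
#'
#' Closed-form activation level
#' \deqn{\omega_a = \frac{\ln \phi}{\alpha \lambda^2}, \quad \phi = 1 +
#' \frac{4\alpha}{\gamma} e^{\alpha (1 - \tilde I_p)} P_{opt} f_t
#' \int_{\lambda_{min}}^{\lambda} f_\xi\, d\tilde\lambda,}
#' together with the analytic stretch derivative
#' \deqn{\frac{\partial \omega_a}{\partial \lambda} =
#' \frac{1}{\alpha\lambda^2}\left(\frac{\phi'}{\phi} - \frac{2}{\lambda}
#' \ln\phi\right), \quad \phi' = \frac{4\alpha}{\gamma}
#' e^{\alpha(1 - \tilde I_p)} P_{opt} f_t \left(f_\xi - \alpha \tilde I_p'
#' \int_{\lambda_{min}}^{\lambda} f_\xi\, d\tilde\lambda\right).}
#'
#' @param lambda Fiber stretch, > 0.
#' @param ft Time-activation level in [0, 1].
#' @param params A [gasam_params()] (or compatible) parameter set.
#' @return List with `omega_a` and `domega_dlambda`, both 0 for vanishing
#'   activation or `lambda <= lambda_min`.
#' @export
omega_gasam <- function(lambda, ft, params) {
  stopifnot(lambda > 0, ft >= 0)
  amp <- params$Popt * ft
  if (amp == 0 || lambda <= params$lambda_min) {
    return(list(omega_a = 0, domega_dlambda = 0))
  }
  al <- params$alpha
  inv <- uniaxial_passive_invariants(lambda, params$omega0)
  intf <- fxi_integral(lambda, params$lambda_opt, params$lambda_min)
  pref <- (4 * al / params$gamma) * exp(al * (1 - inv$Itilde_p)) * amp
  phi <- 1 + pref * intf
  if (phi <= 0) stop("invalid activation state: phi <= 0", call. = FALSE)
  fx <- f_xi(lambda, params$lambda_opt, params$lambda_min)
  phi_prime <- pref * (fx - al * inv$Itilde_p_prime * intf)
  wa <- log(phi) / (al * lambda^2)
  if (wa >= 1) stop("activation parameter reached 1: singular activation",
                    call. = FALSE)
  list(
    omega_a = wa,
    domega_dlambda = (phi_prime / phi - (2 / lambda) * log(phi)) /
      (al * lambda^2)
  )
}

# activation level actually used by a model at fiber stretch `lambda` and
# resolved time-activation factor `ft`; returns list(omega_a, domega_dlambda
# [GASAM only], ase_level [ASE only])
resolve_activation_level <- function(params, lambda, ft) {
  switch(params$model,
    ase = list(omega_a = NA_real_, ase_level = params$a * ft),
    gasa = {
      Pa <- active_nominal_stress(lambda, params$Popt, ft,
                                  params$lambda_opt, params$lambda_min)
      list(omega_a = omega_gasa(lambda, Pa, params))
    },
    asa = list(omega_a = omega_asa(lambda, ft, params)),
    gasam = {
      og <- omega_gasam(lambda, ft, params)
      list(omega_a = og$omega_a, domega_dlambda = og$domega_dlambda)
    }
  )
}
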