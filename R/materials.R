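# The four constitutive models: strain-energy densities, second
# Piola-Kirchhoff stresses, push-forwards, and a numerically differentiated
# elasticity tensor.
#
# All stresses are in kPa. Each model exists in two flavors:
#   * the nearly incompressible form used in simulations (default), with the
#     volumetric terms of the respective formulation, and
#   * the fully incompressible form used for analytic load-case responses
#     (volumetric terms dropped, unmodified strain measures; the reaction
#     pressure is applied by the load-response driver).

# acosh(theta) / sqrt(theta^2 - 1) with its analytic limit 1 as theta -> 1.
# The ratio multiplies every derivative of the transverse-shear invariant B2
# and is the only place the acosh singularity enters the stress.
acosh_ratio <- function(theta, tol = 1e-9) {
  eps <- theta - 1
  if (eps < tol) return(1)
  if (eps < 1e-6) return(1 - eps / 3)
  acosh(theta) / sqrt(theta^2 - 1)
}

# total Cauchy fiber stress of the ASE model: active parabola scaled by the
# activation level plus tension-only passive contribution
sigma_ftot_ase <- function(lambda_bar, level, p) {
  p$sigma_max * (lambda_bar / p$lambda_opta) * level * f_xi_a(lambda_bar, p$lambda_opta) +
    p$sigma_max * lambda_bar * f_xi_p(lambda_bar, p$D1, p$D2, p$lambda_star)
}

# fiber strain energy of the ASE model, defined through
# dPsi_ftot/dlambda_bar = sigma_ftot / lambda_bar, integrated from the
# reference stretch 1 by adaptive quadrature
psi_ftot_ase <- function(lambda_bar, level, p) {
  if (abs(lambda_bar - 1) < 1e-14) return(0)
  f <- function(lb) sigma_ftot_ase(lb, level, p) / lb
  sgn <- if (lambda_bar > 1) 1 else -1
  lo <- min(1, lambda_bar)
  hi <- max(1, lambda_bar)
  # split at the force-stretch breakpoints inside the integration range
  brk <- p$lambda_opta * c(0.6, 1.4)
  brk <- sort(c(lo, brk[brk > lo & brk < hi], p$lambda_star, 1))
  brk <- unique(pmin(pmax(brk, lo), hi))
  brk <- sort(unique(c(brk, hi)))
  tot <- 0
  for (i in seq_len(length(brk) - 1L)) {
    tot <- tot + stats::integrate(f, brk[i], brk[i + 1L],
                                  rel.tol = 1e-12, abs.tol = 1e-10)$value
  }
  sgn * tot
}

# derivative of Psi w.r.t. the (possibly isochoric) strain tensor for the
# ASE model; `Cb` is Cbar in the nearly incompressible form or C in the
# fully incompressible form
ase_dpsi_dCb <- function(Cb, M, level, p, lambda_bar) {
  I1 <- sum(diag(Cb))
  I4 <- tensor_dot(Cb, M)
  I5 <- tensor_dot(Cb %*% Cb, M)
  sI4 <- sqrt(I4)
  theta <- max((I1 * I4 - I5) / (2 * sI4), 1)
  MC <- M %*% Cb + Cb %*% M
  B1 <- I5 / I4^2 - 1
  dB1 <- MC / I4^2 - (2 * I5 / I4^3) * M
  dtheta <- (sI4 / 2) * diag(3) +
    (I1 / (2 * sI4) - theta / (2 * I4)) * M -
    (1 / (2 * sI4)) * MC
  A <- p$G1 * 2 * B1 * dB1 +
    p$G2 * 2 * acosh_ratio(theta) * dtheta +
    (sigma_ftot_ase(lambda_bar, level, p) / (2 * lambda_bar^2)) * M +
    (p$mu / 2) * diag(3)
  A
}

psi_ase <- function(p, state, level, incompressible) {
  inv <- basic_invariants(state, modified = !incompressible)
  lb <- if (incompressible) state$lambda else state$lambda_bar
  psi <- p$G1 * inv$B1^2 + p$G2 * inv$B2^2 +
    psi_ftot_ase(lb, level, p) +
    (p$mu / 2) * (inv$I1bar - 3)
  if (!incompressible) psi <- psi + (p$K / 2) * log(state$J)^2
  psi
}

stress_ase <- function(p, state, level, incompressible) {
  M <- state$frame$M
  if (incompressible) {
    A <- ase_dpsi_dCb(state$C, M, level, p, state$lambda)
    return(2 * A)
  }
  A <- ase_dpsi_dCb(state$Cbar, M, level, p, state$lambda_bar)
  Cinv <- solve(state$C)
  S_iso <- 2 * (state$J^(-2 / 3) * A -
                  (tensor_dot(A, state$Cbar) / 3) * Cinv)
  S_vol <- p$K * log(state$J) * Cinv
  S_iso + S_vol
}

# generalized active-strain family ---------------------------------------

psi_gas <- function(p, state, omega_a, incompressible) {
  gi <- generalized_invariants(state$C, p$omega0, omega_a, state$frame)
  psi <- (p$gamma / 4) *
    ((exp(p$alpha * (gi$Itilde - 1)) - 1) / p$alpha +
       (exp(p$beta * (gi$Jtilde - 1)) - 1) / p$beta)
  if (!incompressible) {
    psi <- psi + (p$gamma / (4 * p$kappa)) * (det(state$C)^(-p$kappa) - 1)
  }
  psi
}

# d(cof(C) : X)/dC for symmetric C and X
dcof_contraction <- function(C, X) {
  Cinv <- solve(C)
  det(C) * (tensor_dot(Cinv, X) * Cinv - Cinv %*% X %*% Cinv)
}

# second Piola-Kirchhoff stress of the GASA model at frozen activation level
stress_gas_frozen <- function(p, state, omega_a, incompressible) {
  gi <- generalized_invariants(state$C, p$omega0, omega_a, state$frame)
  M <- state$frame$M
  S <- (p$gamma / 2) *
    (exp(p$alpha * (gi$Itilde - 1)) * (gi$Ltilde + omega_a * M) +
       exp(p$beta * (gi$Jtilde - 1)) * dcof_contraction(state$C, gi$Ltilde))
  if (!incompressible) {
    S <- S - (p$gamma / 2) * det(state$C)^(-p$kappa) * solve(state$C)
  }
  S
}

# additional GASAM stress from the deformation dependence of the activation
# level: S_wa = (gamma/4) e^{alpha(Itilde - 1)} lambda (dwa/dlambda) M
stress_gasam_extra <- function(p, state, omega_a, domega_dlambda) {
  gi <- generalized_invariants(state$C, p$omega0, omega_a, state$frame)
  (p$gamma / 4) * exp(p$alpha * (gi$Itilde - 1)) *
    state$lambda * domega_dlambda * state$frame$M
}

# ASA --------------------------------------------------------------------

psi_asa <- function(p, state, omega_a, incompressible) {
  ad <- active_decomposition(state, omega_a, p$omega0)
  psi <- (p$gamma / 4) *
    ((exp(p$alpha * (ad$Itilde_e - 1)) - 1) / p$alpha +
       (exp(p$beta * (ad$Jtilde_e - 1)) - 1) / p$beta)
  if (!incompressible) {
    psi <- psi + (p$gamma / (4 * p$kappa)) * (det(state$C)^(-p$kappa) - 1)
  }
  psi
}

# derivative of the ASA elastic energy w.r.t. the activation parameter at
# fixed deformation (analytic, via dFa/dwa)
dpsi_asa_domega <- function(p, state, omega_a) {
  M <- state$frame$M
  Iden <- diag(3)
  Lt <- (p$omega0 / 3) * Iden + (1 - p$omega0) * M
  q <- 1 - omega_a
  Fa <- q * M + q^(-1 / 2) * (Iden - M)
  Fa_inv <- q^(-1) * M + q^(1 / 2) * (Iden - M)
  dFa <- -M + 0.5 * q^(-3 / 2) * (Iden - M)
  dFa_inv <- q^(-2) * M - 0.5 * q^(-1 / 2) * (Iden - M)
  C <- state$C
  Ce <- Fa_inv %*% C %*% Fa_inv
  Ie <- tensor_dot(Ce, Lt)
  Je <- tensor_dot(cofactor(Ce), Lt)
  dIe <- tensor_dot(C, dFa_inv %*% Lt %*% Fa_inv + Fa_inv %*% Lt %*% dFa_inv)
  X <- Fa %*% Lt %*% Fa
  dX <- dFa %*% Lt %*% Fa + Fa %*% Lt %*% dFa
  dJe <- det(C) * tensor_dot(solve(C), dX)
  (p$gamma / 4) * (exp(p$alpha * (Ie - 1)) * dIe +
                     exp(p$beta * (Je - 1)) * dJe)
}

# dwa/dlambda of the ASA model by central differences on the stretch
domega_asa_dlambda <- function(p, lambda, ft, h_rel = 1e-6) {
  h <- h_rel * lambda
  (omega_asa(lambda + h, ft, p) - omega_asa(lambda - h, ft, p)) / (2 * h)
}

stress_asa <- function(p, state, omega_a, ft, incompressible) {
  M <- state$frame$M
  Iden <- diag(3)
  Lt <- (p$omega0 / 3) * Iden + (1 - p$omega0) * M
  q <- 1 - omega_a
  Fa_inv <- q^(-1) * M + q^(1 / 2) * (Iden - M)
  Fa <- q * M + q^(-1 / 2) * (Iden - M)
  C <- state$C
  Ce <- Fa_inv %*% C %*% Fa_inv
  Ie <- tensor_dot(Ce, Lt)
  Je <- tensor_dot(cofactor(Ce), Lt)
  S <- (p$gamma / 2) *
    (exp(p$alpha * (Ie - 1)) * (Fa_inv %*% Lt %*% Fa_inv) +
       exp(p$beta * (Je - 1)) * dcof_contraction(C, Fa %*% Lt %*% Fa))
  if (!incompressible) {
    S <- S - (p$gamma / 2) * det(C)^(-p$kappa) * solve(C)
  }
  if (omega_a > 0) {
    dwadl <- domega_asa_dlambda(p, state$lambda, ft)
    S <- S + dpsi_asa_domega(p, state, omega_a) *
      (dwadl / state$lambda) * M
  }
  S
}

# public surface ----------------------------------------------------------

#' Strain-energy density of a muscle model
#'
#' @param params A `muscle_params` object ([ase_params()], [gasa_params()],
#'   [asa_params()], [gasam_params()]).
#' @param state A [deformation_state()].
#' @param act A [muscle_activation()]; default passive.
#' @param incompressible Evaluate the fully incompressible form (volumetric
#'   terms dropped, unmodified strain measures) instead of the nearly
#'   incompressible one.
#' @param omega_a Optional activation-parameter override (generalized
#'   active-strain family only). Supplying a value freezes the activation
#'   level, e.g. to differentiate the energy at fixed activation.
#' @return Strain-energy density in kPa.
#' @export
muscle_energy <- function(params, state, act = muscle_activation("passive"),
                          incompressible = FALSE, omega_a = NULL) {
  stopifnot(inherits(params, "muscle_params"),
            inherits(state, "deformation_state"))
  ft <- resolve_ft(act, params)
  if (params$model == "ase") {
    return(psi_ase(params, state, params$a * ft, incompressible))
  }
  wa <- if (!is.null(omega_a)) omega_a else {
    resolve_activation_level(params, state$lambda, ft)$omega_a
  }
  switch(params$model,
    gasa = psi_gas(params, state, wa, incompressible),
    gasam = psi_gas(params, state, wa, incompressible),
    asa = psi_asa(params, state, wa, incompressible)
  )
}

#' Second Piola-Kirchhoff stress and push-forwards of a muscle model
#'
#' Resolves the activation level with the model's own solver (Lambert W for
#' GASA, Newton for ASA, closed form for GASAM, amplitude scaling for ASE)
#' and evaluates the model's stress: the GASA stress holds the activation
#' parameter fixed, the GASAM stress adds the activation-derivative term,
#' and the ASA stress includes the corresponding term with the implicit
#' derivative approximated by central differences.
#'
#' @inheritParams muscle_energy
#' @return An object of class `stress_result`: list with `psi` (kPa), `S`,
#'   `P`, `sigma` (3x3, kPa), and `omega_a` (activation parameter used;
#'   for the ASE model the resolved activation amplitude `a * f_t`).
#' @export
muscle_stress <- function(params, state, act = muscle_activation("passive"),
                          incompressible = FALSE) {
  stopifnot(inherits(params, "muscle_params"),
            inherits(state, "deformation_state"))
  ft <- resolve_ft(act, params)
  lev <- resolve_activation_level(params, state$lambda, ft)
  S <- switch(params$model,
    ase = stress_ase(params, state, lev$ase_level, incompressible),
    gasa = stress_gas_frozen(params, state, lev$omega_a, incompressible),
    gasam = stress_gas_frozen(params, state, lev$omega_a, incompressible) +
      stress_gasam_extra(params, state, lev$omega_a, lev$domega_dlambda),
    asa = stress_asa(params, state, lev$omega_a, ft, incompressible)
  )
  S <- (S + t(S)) / 2
  pf <- push_forward(S, state)
  structure(list(
    psi = muscle_energy(params, state, act, incompressible),
    S = S, P = pf$P, sigma = pf$sigma,
    omega_a = if (params$model == "ase") lev$ase_level else lev$omega_a
  ), class = "stress_result")
}

#' Push-forward of a second Piola-Kirchhoff stress
#'
#' \eqn{P = F S} (first Piola-Kirchhoff / nominal stress) and
#' \eqn{\sigma = J^{-1} P F^T} (Cauchy stress).
#'
#' @param S Symmetric 3x3 second Piola-Kirchhoff stress (kPa).
#' @param state A [deformation_state()].
#' @return List with `P` and `sigma`.
#' @export
push_forward <- function(S, state) {
  P <- state$F %*% S
  list(P = P, sigma = (P %*% t(state$F)) / state$J)
}

#' Numerically differentiated elasticity tensor
#'
#' Fourth-order material tangent \eqn{\mathbb{C} = 2\,\partial S /
#' \partial C} (equal to \eqn{4 \partial^2 \Psi / \partial C^2} for the
#' potential-based stresses), computed by symmetric finite differences of
#' the stress with respect to the right Cauchy-Green tensor. Minor
#' symmetries are enforced by construction; the major-symmetry residual
#' (relative Frobenius norm of the antisymmetric part) is attached as
#' attribute `major_symmetry_residual`.
#'
#' @inheritParams muscle_energy
#' @param h_rel Relative finite-difference step.
#' @return A 3x3x3x3 array (kPa) satisfying \eqn{dS \approx \mathbb{C} :
#'   dC / 2}.
#' @export
elasticity_tensor <- function(params, state,
                              act = muscle_activation("passive"),
                              incompressible = FALSE, h_rel = 1e-6) {
  C <- state$C
  frame <- state$frame
  h <- h_rel * max(1, max(abs(C)))
  if (h <= .Machine$double.eps * 100) {
    stop("finite-difference step underflow", call. = FALSE)
  }
  S_of_C <- function(Cm) {
    muscle_stress(params, state_from_C(Cm, frame), act, incompressible)$S
  }
  D <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) {
    for (l in k:3) {
      dC <- matrix(0, 3, 3)
      dC[k, l] <- dC[k, l] + h
      dC[l, k] <- dC[l, k] + h
      if (k == l) dC[k, k] <- h
      G <- (S_of_C(C + dC) - S_of_C(C - dC)) / (2 * h)
      if (k == l) {
        D[, , k, k] <- G
      } else {
        D[, , k, l] <- G / 2
        D[, , l, k] <- G / 2
      }
    }
  }
  CC <- 2 * D
  # major symmetry residual
  num <- 0
  den <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    num <- num + (CC[i, j, k, l] - CC[k, l, i, j])^2
    den <- den + CC[i, j, k, l]^2
  }
  attr(CC, "major_symmetry_residual") <- sqrt(num / max(den, 1e-300))
  CC
}
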