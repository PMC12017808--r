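# Kinematics: deformation gradients for the homogeneous load cases, strain
# measures, classical and generalized invariants, and the multiplicative
# active decomposition.

#' Build a fiber frame from a reference fiber direction
#'
#' Normalizes the reference fiber direction and assembles the structural
#' tensor \eqn{M = m \otimes m} that encodes transverse isotropy.
#'
#' @param m Numeric 3-vector, reference fiber direction (need not be unit
#'   length; it is normalized).
#' @return An object of class `fiber_frame`: a list with `m` (unit 3-vector)
#'   and `M` (3x3 structural tensor, symmetric and idempotent).
#' @examples
#' f <- fiber_frame(c(0, 0, 1))
#' f$M
#' @export
fiber_frame <- function(m) {
  m <- as.numeric(m)
  if (length(m) != 3L || !all(is.finite(m))) {
    stop("fiber direction must be a finite numeric 3-vector", call. = FALSE)
  }
  nrm <- sqrt(sum(m^2))
  if (nrm <= 0) stop("fiber direction must be a nonzero vector", call. = FALSE)
  m <- m / nrm
  structure(list(m = m, M = tcrossprod(m)), class = "fiber_frame")
}

#' Default fiber frame: fibers aligned with the third coordinate axis
#' @return A `fiber_frame` with `m = (0, 0, 1)`.
#' @export
default_fiber_frame <- function() fiber_frame(c(0, 0, 1))

#' Deformation state from a deformation gradient
#'
#' Computes the derived strain measures used by every constitutive
#' evaluation: the Jacobian \eqn{J = \det F}, the right Cauchy-Green tensor
#' \eqn{C = F^T F}, its isochoric part \eqn{\bar C = J^{-2/3} C}, and the
#' fiber stretches \eqn{\lambda = \sqrt{C : M}}, \eqn{\bar\lambda =
#' \sqrt{\bar C : M}}.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param frame A [fiber_frame()]; defaults to fibers along the third axis.
#' @return An object of class `deformation_state` with fields `F`, `J`, `C`,
#'   `Cbar`, `lambda`, `lambda_bar`, and `frame`.
#' @export
deformation_state <- function(F, frame = default_fiber_frame()) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || !all(is.finite(F))) {
    stop("F must be a finite 3x3 matrix", call. = FALSE)
  }
  J <- det(F)
  if (J <= 0) stop("deformation gradient must have det F > 0", call. = FALSE)
  C <- crossprod(F)
  Cbar <- J^(-2 / 3) * C
  structure(list(
    F = F, J = J, C = C, Cbar = Cbar,
    lambda = sqrt(tensor_dot(C, frame$M)),
    lambda_bar = sqrt(tensor_dot(Cbar, frame$M)),
    frame = frame
  ), class = "deformation_state")
}

#' Load case identifiers
#'
#' The six homogeneous load cases: uniaxial tension/compression along
#' (`UTCAF`) and transverse to (`UTCTF`) the fiber direction, simple shear
#' along the fiber (`SAF`), and pure shear along (`PSAF`), transverse to
#' (`PSTF`), and transverse to isometrically constrained (`PSTIF`) fibers.
#' Fibers are aligned with the third coordinate axis throughout.
#'
#' @export
LOAD_CASES <- c("UTCAF", "UTCTF", "SAF", "PSAF", "PSTF", "PSTIF")

#' Isochoric deformation gradient of a homogeneous load case
#'
#' Returns the volume-preserving deformation gradient of the requested load
#' case. The magnitude is the stretch \eqn{\lambda_f} for all modes except
#' `SAF`, where it is the shear amount \eqn{\nu_f} (the single off-diagonal
#' entry coupling the second coordinate into the fiber direction).
#'
#' @param mode One of [LOAD_CASES].
#' @param magnitude Stretch (> 0) or, for `SAF`, the shear amount.
#' @param frame Fiber frame attached to the returned state.
#' @return A [deformation_state()] with `det F = 1`.
#' @export
loadcase_deformation <- function(mode, magnitude,
                                 frame = default_fiber_frame()) {
  mode <- match.arg(mode, LOAD_CASES)
  lam <- as.numeric(magnitude)
  if (length(lam) != 1L || !is.finite(lam)) {
    stop("magnitude must be a single finite number", call. = FALSE)
  }
  if (mode != "SAF" && lam <= 0) {
    stop("stretch magnitude must be positive", call. = FALSE)
  }
  F <- switch(mode,
    UTCAF = diag(c(lam^(-1 / 2), lam^(-1 / 2), lam)),
    UTCTF = diag(c(lam, lam^(-1 / 2), lam^(-1 / 2))),
    SAF = {
      Fm <- diag(3)
      Fm[3, 2] <- lam
      Fm
    },
    PSAF = diag(c(1 / lam, 1, lam)),
    PSTF = diag(c(lam, 1, 1 / lam)),
    PSTIF = diag(c(lam, 1 / lam, 1))
  )
  deformation_state(F, frame = frame)
}

#' Classical invariants of the isochoric right Cauchy-Green tensor
#'
#' Computes \eqn{\bar I_1 = \mathrm{tr}\,\bar C}, \eqn{\bar I_4 = \bar C : M},
#' \eqn{\bar I_5 = \bar C^2 : M}, and the along/transverse fiber shear
#' invariants \eqn{B_1 = \bar I_5 / \bar I_4^2 - 1} and \eqn{B_2 =
#' \mathrm{acosh}(\theta)} with \eqn{\theta = (\bar I_1 \bar I_4 - \bar I_5) /
#' (2 \sqrt{\bar I_4})}. Both vanish for pure stretches aligned with the
#' fiber axis.
#'
#' @param state A [deformation_state()].
#' @param modified Use the isochoric tensor `Cbar` (default) or the full `C`
#'   (used by the fully incompressible formulation, where both coincide for
#'   isochoric deformations).
#' @param theta_tol Below `1 - theta_tol` the acosh argument signals an
#'   inconsistent deformation input; within `[1 - theta_tol, 1]` it is
#'   clamped to 1 (vanishing shear).
#' @return List with `I1bar`, `I4bar`, `I5bar`, `B1`, `B2`, `theta`.
#' @export
basic_invariants <- function(state, modified = TRUE, theta_tol = 1e-9) {
  Cb <- if (modified) state$Cbar else state$C
  M <- state$frame$M
  I1 <- sum(diag(Cb))
  I4 <- tensor_dot(Cb, M)
  I5 <- tensor_dot(Cb %*% Cb, M)
  if (I4 <= 0) stop("I4 must be positive", call. = FALSE)
  theta <- (I1 * I4 - I5) / (2 * sqrt(I4))
  if (theta < 1 - theta_tol) {
    stop(sprintf(
      "acosh argument theta = %.12g < 1: inconsistent deformation input",
      theta
    ), call. = FALSE)
  }
  theta_c <- max(theta, 1)
  list(
    I1bar = I1, I4bar = I4, I5bar = I5,
    B1 = I5 / I4^2 - 1,
    B2 = acosh(theta_c),
    theta = theta_c
  )
}

#' Generalized invariants with matrix/fiber weighting and activation
#'
#' Assembles the generalized structural tensor \eqn{\tilde L = (\omega_0/3) I
#' + \omega_p M} (with \eqn{\omega_p = 1 - \omega_0}) and the generalized
#' invariants \eqn{\tilde I = \tilde I_p + \tilde I_a}, \eqn{\tilde J}. The
#' passive parts are \eqn{\tilde I_p = C : \tilde L} and \eqn{\tilde J =
#' \mathrm{cof}(C) : \tilde L}; activation augments the first invariant by
#' \eqn{\tilde I_a = \omega_a\, C : M = \omega_a \lambda^2}.
#'
#' @param C 3x3 right Cauchy-Green tensor.
#' @param omega0 Matrix weighting factor in (0, 1).
#' @param omega_a Activation parameter in [0, 1).
#' @param frame A [fiber_frame()].
#' @return List with `Ltilde`, `Itilde`, `Jtilde`, `Itilde_p`, `Itilde_a`.
#' @export
generalized_invariants <- function(C, omega0, omega_a = 0,
                                   frame = default_fiber_frame()) {
  stopifnot(omega0 > 0, omega0 < 1, omega_a >= 0, omega_a < 1)
  Lt <- (omega0 / 3) * diag(3) + (1 - omega0) * frame$M
  Ip <- tensor_dot(C, Lt)
  Ia <- omega_a * tensor_dot(C, frame$M)
  list(
    Ltilde = Lt,
    Itilde = Ip + Ia,
    Jtilde = tensor_dot(cofactor(C), Lt),
    Itilde_p = Ip,
    Itilde_a = Ia
  )
}

#' Multiplicative active decomposition of the deformation gradient
#'
#' Splits \eqn{F = F_e F_a} with the volume-preserving active part
#' \eqn{F_a = (1 - \omega_a) M + (1 - \omega_a)^{-1/2} (I - M)} and returns
#' the elastic right Cauchy-Green tensor \eqn{C_e = F_e^T F_e} together with
#' its generalized invariants.
#'
#' @param state A [deformation_state()].
#' @param omega_a Activation parameter in [0, 1).
#' @param omega0 Matrix weighting used for the elastic generalized
#'   invariants.
#' @return List with `omega_a`, `Fa`, `Fe`, `Ce`, `Itilde_e`, `Jtilde_e`.
#' @export
active_decomposition <- function(state, omega_a, omega0 = 0.5) {
  if (omega_a < 0 || omega_a >= 1) {
    stop("activation parameter must lie in [0, 1)", call. = FALSE)
  }
  M <- state$frame$M
  Fa <- (1 - omega_a) * M + (1 - omega_a)^(-1 / 2) * (diag(3) - M)
  Fa_inv <- (1 - omega_a)^(-1) * M + (1 - omega_a)^(1 / 2) * (diag(3) - M)
  Fe <- state$F %*% Fa_inv
  Ce <- crossprod(Fe)
  gi <- generalized_invariants(Ce, omega0, 0, state$frame)
  list(
    omega_a = omega_a, Fa = Fa, Fe = Fe, Ce = Ce,
    Itilde_e = gi$Itilde_p, Jtilde_e = gi$Jtilde
  )
}

# double contraction of two 3x3 tensors
tensor_dot <- function(A, B) sum(A * B)

# cofactor of an invertible 3x3 tensor, cof(C) = det(C) C^{-T}
cofactor <- function(C) det(C) * t(solve(C))

# symmetric positive-definite square root, used to rebuild a rotation-free
# deformation gradient from a right Cauchy-Green tensor
sqrtm_spd <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (any(e$values <= 0)) stop("tensor is not positive definite", call. = FALSE)
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

# deformation state with prescribed right Cauchy-Green tensor (F = sqrt(C));
# objectivity makes this choice immaterial for constitutive evaluations
state_from_C <- function(C, frame = default_fiber_frame()) {
  deformation_state(sqrtm_spd(C), frame = frame)
}
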