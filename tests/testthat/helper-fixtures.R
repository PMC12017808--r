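# Shared deterministic fixtures: random deformation states and a
# finite-difference second Piola-Kirchhoff stress used by the energy
# consistency checks.

# n random unimodular (det = 1) deformation gradients close to identity
rand_unimodular_F <- function(n, spread = 0.12, seed = 1) {
  set.seed(seed)
  out <- vector("list", n)
  k <- 0L
  while (k < n) {
    Fm <- diag(3) + spread * matrix(stats::rnorm(9), 3, 3)
    if (det(Fm) < 0.2) next
    Fm <- Fm / det(Fm)^(1 / 3)
    k <- k + 1L
    out[[k]] <- Fm
  }
  out
}

# random proper rotation
rand_rotation <- function(seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# S = 2 dPsi/dC by central differences on the independent components of C
fd_stress <- function(params, state, act, incompressible = TRUE,
                      omega_a = NULL, h_rel = 1e-5) {
  C <- state$C
  frame <- state$frame
  psi_of <- function(Cm) {
    muscle_energy(params, activemuscle:::state_from_C(Cm, frame), act,
                  incompressible = incompressible, omega_a = omega_a)
  }
  S <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in i:3) {
      h <- h_rel * max(abs(C[i, j]), 1)
      dC <- matrix(0, 3, 3)
      dC[i, j] <- h
      dC[j, i] <- h
      dpsi <- psi_of(C + dC) - psi_of(C - dC)
      if (i == j) {
        S[i, i] <- dpsi / h
      } else {
        S[i, j] <- S[j, i] <- dpsi / (2 * h)
      }
    }
  }
  S
}

rel_err <- function(x, ref) {
  max(abs(x - ref)) / max(1, max(abs(ref)))
}
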