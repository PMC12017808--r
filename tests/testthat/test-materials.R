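models <- lapply(c(ase = "ase", gasa = "gasa", asa = "asa", gasam = "gasam"),
                 reference_params)
tet <- muscle_activation("tetanic")
pas <- muscle_activation("passive")

test_that("the reference state is energy- and stress-free", {
  st <- deformation_state(diag(3))
  for (p in models) {
    expect_equal(muscle_energy(p, st), 0, tolerance = 1e-12)
    r <- muscle_stress(p, st)
    expect_equal(max(abs(r$S)), 0, tolerance = 1e-10)
    expect_equal(max(abs(r$P)), 0, tolerance = 1e-10)
    expect_s3_class(r, "stress_result")
  }
})

test_that("stress results are symmetric and push forward correctly", {
  st <- loadcase_deformation("SAF", 0.25)
  for (p in models) {
    r <- muscle_stress(p, st, tet)
    expect_equal(r$S, t(r$S), tolerance = 1e-12)
    expect_equal(r$P, st$F %*% r$S)
    expect_equal(r$sigma, (r$P %*% t(st$F)) / st$J)
    expect_equal(r$sigma, t(r$sigma), tolerance = 1e-9)
  }
})

test_that("energies and stresses are objective", {
  Q <- rand_rotation(7)
  Fm <- rand_unimodular_F(1, seed = 11)[[1]]
  st <- deformation_state(Fm)
  stQ <- deformation_state(Q %*% Fm)
  for (p in models) {
    act <- if (p$model == "ase") pas else tet
    expect_equal(muscle_energy(p, stQ, act), muscle_energy(p, st, act),
                 tolerance = 1e-10)
    r <- muscle_stress(p, st, act)
    rQ <- muscle_stress(p, stQ, act)
    expect_equal(rQ$S, r$S, tolerance = 1e-9)
    expect_equal(rQ$sigma, Q %*% r$sigma %*% t(Q), tolerance = 1e-9)
  }
})

test_that("passive energies of the active-strain family coincide pointwise", {
  for (Fm in rand_unimodular_F(5, seed = 3)) {
    st <- deformation_state(Fm)
    psis <- vapply(models[c("gasa", "asa", "gasam")], muscle_energy,
                   numeric(1), state = st)
    expect_equal(max(psis) - min(psis), 0, tolerance = 1e-12)
  }
})

test_that("without its isotropic companion term the active-stress model is
           stress-free in passive fiber compression", {
  p0 <- ase_params(G1 = 0.1, G2 = 0.05, D1 = 3.6055, D2 = 4.4883, K = 10000,
                   lambda_opta = 1.2264, lambda_star = 1.4,
                   sigma_max = 1.1450, a = 69.5471, mu = 0)
  for (lam in c(0.7, 0.85, 0.99)) {
    expect_equal(nominal_response(p0, "UTCAF", lam), 0, tolerance = 1e-10)
  }
  # the companion term restores compressive resistance
  expect_lt(nominal_response(models$ase, "UTCAF", 0.8), 0)
})

test_that("stresses are energy-consistent at spot-check states", {
  sts <- lapply(rand_unimodular_F(3, seed = 21), deformation_state)
  for (st in sts) {
    # ASE, fully incompressible and nearly incompressible (J != 1)
    expect_lt(rel_err(muscle_stress(models$ase, st, tet, TRUE)$S,
                      fd_stress(models$ase, st, tet, TRUE)), 1e-6)
    stJ <- deformation_state(1.01 * st$F)
    expect_lt(rel_err(muscle_stress(models$ase, stJ, tet)$S,
                      fd_stress(models$ase, stJ, tet,
                                incompressible = FALSE)), 1e-6)
    # GASA at frozen activation level
    wa <- muscle_stress(models$gasa, st, tet, TRUE)$omega_a
    expect_lt(rel_err(muscle_stress(models$gasa, st, tet, TRUE)$S,
                      fd_stress(models$gasa, st, tet, TRUE, omega_a = wa)),
              1e-6)
    # GASAM and ASA with the deformation-dependent activation level
    expect_lt(rel_err(muscle_stress(models$gasam, st, tet, TRUE)$S,
                      fd_stress(models$gasam, st, tet, TRUE)), 1e-6)
    expect_lt(rel_err(muscle_stress(models$asa, st, tet, TRUE)$S,
                      fd_stress(models$asa, st, tet, TRUE)), 1e-5)
  }
})

test_that("acosh ratio is continuous through its removable singularity", {
  ar <- activemuscle:::acosh_ratio
  expect_equal(ar(1), 1)
  expect_equal(ar(1 + 1e-12), 1)
  expect_equal(ar(1 + 1e-7), 1 - 1e-7 / 3, tolerance = 1e-9)
  theta <- 1 + 1e-5
  expect_equal(ar(theta), acosh(theta) / sqrt(theta^2 - 1), tolerance = 1e-6)
})

test_that("the elasticity tensor is a directional derivative of the stress", {
  st <- deformation_state(rand_unimodular_F(1, seed = 31)[[1]])
  for (nm in c("ase", "gasam")) {
    p <- models[[nm]]
    CC <- elasticity_tensor(p, st, tet, incompressible = TRUE)
    set.seed(5)
    dC <- matrix(rnorm(9), 3, 3)
    dC <- (dC + t(dC)) / 2
    t0 <- 1e-5
    Sp <- muscle_stress(p, activemuscle:::state_from_C(st$C + t0 * dC),
                        tet, TRUE)$S
    Sm <- muscle_stress(p, activemuscle:::state_from_C(st$C - t0 * dC),
                        tet, TRUE)$S
    dS_fd <- (Sp - Sm) / (2 * t0)
    dS_cc <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      dS_cc[i, j] <- sum(CC[i, j, , ] * dC) / 2
    }
    expect_lt(rel_err(dS_cc, dS_fd), 1e-4)
  }
  # potential-based passive stress: major symmetry holds numerically
  CCp <- elasticity_tensor(models$gasam, st, pas, incompressible = TRUE)
  expect_lt(attr(CCp, "major_symmetry_residual"), 1e-6)
})
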