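test_that("fiber_frame normalizes and builds the structural tensor", {
  fr <- fiber_frame(c(0, 3, 4))
  expect_equal(sum(fr$m^2), 1)
  expect_equal(fr$M, tcrossprod(fr$m))
  expect_equal(sum(diag(fr$M)), 1)
  expect_equal(fr$M %*% fr$M, fr$M)
  expect_error(fiber_frame(c(0, 0, 0)), "nonzero")
  expect_error(fiber_frame(c(1, 2)), "3-vector")
})

test_that("deformation_state computes the derived strain measures", {
  Fm <- matrix(c(1.1, 0.05, 0, 0, 0.95, 0.1, 0.02, 0, 1.05), 3, 3)
  st <- deformation_state(Fm)
  expect_equal(st$J, det(Fm))
  expect_equal(st$C, t(Fm) %*% Fm)
  expect_equal(det(st$Cbar), 1, tolerance = 1e-12)
  expect_equal(st$lambda, sqrt(sum(st$C * st$frame$M)))
  expect_equal(st$lambda_bar, st$J^(-1 / 3) * st$lambda)
  expect_error(deformation_state(-diag(3)), "det F > 0")
})

test_that("all load cases are isochoric with the documented structure", {
  for (mode in LOAD_CASES) {
    st <- loadcase_deformation(mode, if (mode == "SAF") 0.3 else 1.17)
    expect_equal(det(st$F), 1, tolerance = 1e-12)
  }
  lam <- 1.23
  expect_equal(loadcase_deformation("UTCAF", lam)$F,
               diag(c(lam^(-0.5), lam^(-0.5), lam)))
  expect_equal(loadcase_deformation("UTCTF", lam)$F,
               diag(c(lam, lam^(-0.5), lam^(-0.5))))
  Fs <- loadcase_deformation("SAF", 0.25)$F
  expect_equal(Fs[3, 2], 0.25)
  expect_equal(Fs - diag(3), matrix(c(0, 0, 0, 0, 0, 0.25, 0, 0, 0), 3, 3))
  expect_equal(loadcase_deformation("PSAF", lam)$F, diag(c(1 / lam, 1, lam)))
  expect_equal(loadcase_deformation("PSTF", lam)$F, diag(c(lam, 1, 1 / lam)))
  expect_equal(loadcase_deformation("PSTIF", lam)$F, diag(c(lam, 1 / lam, 1)))
  expect_error(loadcase_deformation("NOPE", 1.1))
  expect_error(loadcase_deformation("UTCAF", -1), "positive")
})

test_that("basic invariants vanish appropriately", {
  st <- deformation_state(diag(3))
  inv <- basic_invariants(st)
  expect_equal(inv$I1bar, 3)
  expect_equal(inv$I4bar, 1)
  expect_equal(inv$B1, 0)
  expect_equal(inv$B2, 0)
  # pure fiber-aligned stretch: both shear invariants stay zero
  inv2 <- basic_invariants(loadcase_deformation("UTCAF", 1.3))
  expect_equal(inv2$B1, 0, tolerance = 1e-12)
  expect_equal(inv2$B2, 0, tolerance = 1e-6)
  # simple shear along the fiber activates the along-fiber shear invariant
  # only
  inv3 <- basic_invariants(loadcase_deformation("SAF", 0.3))
  expect_gt(inv3$B1, 0)
  expect_equal(inv3$B2, 0, tolerance = 1e-7)
  # shear in the transverse plane activates the transverse one only
  Ft <- diag(3)
  Ft[2, 1] <- 0.3
  inv4 <- basic_invariants(deformation_state(Ft))
  expect_equal(inv4$B1, 0, tolerance = 1e-12)
  expect_gt(inv4$B2, 0)
})

test_that("generalized invariants reduce to 1 in the reference state", {
  gi <- generalized_invariants(diag(3), omega0 = 0.6388)
  expect_equal(gi$Itilde, 1)
  expect_equal(gi$Jtilde, 1)
  expect_equal(sum(diag(gi$Ltilde)), 0.6388 + (1 - 0.6388))
  # activation augments the first invariant by omega_a * lambda^2
  C <- loadcase_deformation("UTCAF", 1.2)$C
  g0 <- generalized_invariants(C, 0.6388, 0)
  g1 <- generalized_invariants(C, 0.6388, 0.3)
  expect_equal(g1$Itilde - g0$Itilde, 0.3 * 1.2^2, tolerance = 1e-12)
  expect_equal(g1$Jtilde, g0$Jtilde)
})

test_that("active decomposition is volume preserving and consistent", {
  st <- loadcase_deformation("UTCAF", 1.1)
  ad <- active_decomposition(st, omega_a = 0.4, omega0 = 0.6388)
  expect_equal(det(ad$Fa), 1, tolerance = 1e-12)
  expect_equal(ad$Fe %*% ad$Fa, st$F, tolerance = 1e-12)
  # zero activation: elastic tensor equals the total one
  ad0 <- active_decomposition(st, 0, 0.6388)
  expect_equal(ad0$Ce, st$C)
  expect_error(active_decomposition(st, 1), "\\[0, 1\\)")
})
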