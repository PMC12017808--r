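p_gasa <- reference_params("gasa")
p_asa <- reference_params("asa")
p_gasam <- reference_params("gasam")

# frozen-activation UTCAF nominal fiber stress of the generalized
# active-strain energy, with the reaction pressure from the traction-free
# lateral face -- an oracle independent of the Lambert-W solution path
frozen_utcaf_stress <- function(p, lambda, omega_a) {
  st <- loadcase_deformation("UTCAF", lambda)
  S <- activemuscle:::stress_gas_frozen(p, st, omega_a, TRUE)
  Finvt <- t(solve(st$F))
  pr <- (st$F %*% S)[1, 1] / Finvt[1, 1]
  (st$F %*% (S - pr * solve(st$C)))[3, 3]
}

test_that("uniaxial closed forms match the generalized invariants", {
  for (lam in c(0.8, 1.0, 1.25)) {
    inv <- uniaxial_passive_invariants(lam, p_gasa$omega0)
    C <- diag(c(1 / lam, 1 / lam, lam^2))
    gi <- generalized_invariants(C, p_gasa$omega0, 0)
    expect_equal(inv$Itilde_p, gi$Itilde, tolerance = 1e-14)
    expect_equal(inv$Jtilde_p, gi$Jtilde, tolerance = 1e-14)
    # derivative by central differences
    h <- 1e-6
    fd <- (uniaxial_passive_invariants(lam + h, p_gasa$omega0)$Itilde_p -
             uniaxial_passive_invariants(lam - h, p_gasa$omega0)$Itilde_p) /
      (2 * h)
    expect_equal(inv$Itilde_p_prime, fd, tolerance = 1e-8)
  }
  expect_error(uniaxial_passive_invariants(-1, 0.5), "positive")
})

test_that("force-stretch integral matches a fine Riemann sum", {
  lam <- 1.25
  grid <- seq(p_gasa$lambda_min, lam, length.out = 20001)
  v <- f_xi(grid, p_gasa$lambda_opt, p_gasa$lambda_min)
  trapz <- (sum(v) - (v[1] + v[length(v)]) / 2) * diff(grid[1:2])
  expect_equal(activemuscle:::fxi_integral(lam, p_gasa$lambda_opt,
                                           p_gasa$lambda_min),
               trapz, tolerance = 1e-7)
  expect_equal(activemuscle:::fxi_integral(0.5, p_gasa$lambda_opt,
                                           p_gasa$lambda_min), 0)
})

test_that("Lambert-W activation level satisfies the frozen-stress balance", {
  for (lam in c(0.8, 1.0, 1.15, 1.3)) {
    Pa <- active_nominal_stress(lam, p_gasa$Popt, 1, p_gasa$lambda_opt,
                                p_gasa$lambda_min)
    wa <- omega_gasa(lam, Pa, p_gasa)
    expect_gte(wa, 0)
    expect_lt(wa, 1)
    target <- frozen_utcaf_stress(p_gasa, lam, 0) + Pa
    # independent bisection on the same calibration condition
    g <- function(w) frozen_utcaf_stress(p_gasa, lam, w) - target
    w_bis <- uniroot(g, c(0, 0.99), tol = 1e-13)$root
    expect_equal(wa, w_bis, tolerance = 1e-8)
    expect_equal(frozen_utcaf_stress(p_gasa, lam, wa), target,
                 tolerance = 1e-8)
  }
})

test_that("Lambert-W activation level is zero without stress and monotone", {
  expect_equal(omega_gasa(1.1, 0, p_gasa), 0)
  was <- vapply(c(1, 5, 20, 60), function(Pa) omega_gasa(1.1, Pa, p_gasa),
                numeric(1))
  expect_true(all(diff(was) > 0))
  expect_error(omega_gasa(1.1, -1, p_gasa), "nonnegative")
})

test_that("ASA activation level satisfies its energy balance", {
  al <- p_asa$alpha
  be <- p_asa$beta
  for (lam in c(0.8, 1.0, 1.2)) {
    wa <- omega_asa(lam, 1, p_asa)
    expect_gt(wa, 0)
    expect_lt(wa, 1)
    inv <- uniaxial_passive_invariants(lam, p_asa$omega0)
    e <- activemuscle:::uniaxial_elastic_invariants(lam, wa, p_asa$omega0)
    lhs <- (exp(al * (e$Itilde_e - 1)) - 1) / al +
      (exp(be * (e$Jtilde_e - 1)) - 1) / be
    rhs <- (exp(al * (inv$Itilde_p - 1)) - 1) / al +
      (exp(be * (inv$Jtilde_p - 1)) - 1) / be +
      (4 / p_asa$gamma) * p_asa$Popt *
        activemuscle:::fxi_integral(lam, p_asa$lambda_opt, p_asa$lambda_min)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  expect_equal(omega_asa(1.1, 0, p_asa), 0)
  expect_equal(omega_asa(0.5 * p_asa$lambda_min, 1, p_asa), 0)
})

test_that("GASAM closed form matches its documented pieces", {
  for (lam in c(0.8, 1.0, 1.2)) {
    og <- omega_gasam(lam, 1, p_gasam)
    expect_gt(og$omega_a, 0)
    expect_lt(og$omega_a, 1)
    # derivative consistency by central differences
    h <- 1e-6
    fd <- (omega_gasam(lam + h, 1, p_gasam)$omega_a -
             omega_gasam(lam - h, 1, p_gasam)$omega_a) / (2 * h)
    expect_equal(og$domega_dlambda, fd, tolerance = 1e-6)
  }
  z <- omega_gasam(1.1, 0, p_gasam)
  expect_equal(z$omega_a, 0)
  expect_equal(z$domega_dlambda, 0)
  z2 <- omega_gasam(0.9 * p_gasam$lambda_min, 1, p_gasam)
  expect_equal(z2$omega_a, 0)
})

test_that("submaximal activation lowers every activation level", {
  lam <- 1.1
  Pa1 <- active_nominal_stress(lam, p_gasa$Popt, 1, p_gasa$lambda_opt,
                               p_gasa$lambda_min)
  Pa05 <- active_nominal_stress(lam, p_gasa$Popt, 0.5, p_gasa$lambda_opt,
                                p_gasa$lambda_min)
  expect_lt(omega_gasa(lam, Pa05, p_gasa), omega_gasa(lam, Pa1, p_gasa))
  expect_lt(omega_asa(lam, 0.5, p_asa), omega_asa(lam, 1, p_asa))
  expect_lt(omega_gasam(lam, 0.5, p_gasam)$omega_a,
            omega_gasam(lam, 1, p_gasam)$omega_a)
})
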