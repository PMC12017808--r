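p_ref <- reference_params("gasa")

test_that("tanh time activation clamps, saturates, and is monotone", {
  expect_equal(f_tanh(-0.1, c = 34.4017), 0)
  expect_equal(f_tanh(0, c = 34.4017), 0)
  expect_lt(abs(f_tanh(1, c = 34.4017) - 1), 1e-12)
  ts <- seq(0, 0.5, length.out = 50)
  expect_true(all(diff(f_tanh(ts, c = 34.4017)) >= 0))
  expect_equal(f_tanh(1, c = 34.4017, s = 0.5), 0.5, tolerance = 1e-10)
})

test_that("twitch superposition is normalized to a unit tetanic plateau", {
  tw <- p_ref$twitch
  expect_equal(f_twitch(0, tw), 0)
  expect_true(all(f_twitch(seq(0, 0.5, length.out = 40), tw) >= 0))
  # fused plateau oscillates around 1 after the transient
  ts <- seq(0.4, 0.4 + max(tw$Ii), length.out = 101)
  expect_equal(mean(f_twitch(ts, tw)), 1, tolerance = 1e-2)
  expect_error(f_twitch(-1, tw), "nonnegative")
  expect_error(twitch_train(c(0.5, 0.4), c(1, 1), c(0.01, 0.01),
                            c(0.004, 0.004)), "sum to 1")
})

test_that("f_xi has the documented support and maximum", {
  lo <- p_ref$lambda_opt
  lm <- p_ref$lambda_min
  expect_equal(f_xi(lo, lo, lm), 1)
  expect_equal(f_xi(lm, lo, lm), 0)
  expect_equal(f_xi(0.5 * lm, lo, lm), 0)
  grid <- seq(lm + 1e-3, 2, length.out = 400)
  v <- f_xi(grid, lo, lm)
  expect_true(all(v >= 0))
  expect_lt(max(v), 1 + 1e-8)
  expect_equal(grid[which.max(v)], lo, tolerance = 5e-3)
  # continuity at lambda_min
  expect_lt(f_xi(lm + 1e-8, lo, lm), 1e-6)
})

test_that("f_xi_a branches join continuously at 0.36", {
  la <- 1.2264
  expect_equal(f_xi_a(la, la), 1)
  for (r in c(0.6, 1.4)) {
    expect_equal(f_xi_a(r * la - 1e-10, la), 0.36, tolerance = 1e-6)
    expect_equal(f_xi_a(r * la + 1e-10, la), 0.36, tolerance = 1e-6)
  }
  # symmetric about the optimum on the central branch
  expect_equal(f_xi_a(la * 0.9, la), f_xi_a(la * 1.1, la))
})

test_that("f_xi_p is tension-only and C1 at lambda_star", {
  D1 <- 3.6055
  D2 <- 4.4883
  ls <- 1.4
  expect_equal(f_xi_p(c(0.5, 1), D1, D2, ls), c(0, 0))
  h <- 1e-6
  # value continuity
  expect_equal(f_xi_p(ls - h, D1, D2, ls), f_xi_p(ls + h, D1, D2, ls),
               tolerance = 1e-4)
  # slope continuity
  dl <- (f_xi_p(ls, D1, D2, ls) - f_xi_p(ls - h, D1, D2, ls)) / h
  dr <- (f_xi_p(ls + h, D1, D2, ls) - f_xi_p(ls, D1, D2, ls)) / h
  expect_equal(dl, dr, tolerance = 1e-4)
  # linear branch beyond lambda_star
  v <- f_xi_p(c(1.5, 1.6, 1.7), D1, D2, ls)
  expect_equal(diff(v, differences = 2), 0, tolerance = 1e-10)
})

test_that("active nominal stress peaks at Popt at the optimal stretch", {
  p <- p_ref
  expect_equal(active_nominal_stress(p$lambda_opt, p$Popt, 1,
                                     p$lambda_opt, p$lambda_min), p$Popt)
  expect_equal(active_nominal_stress(p$lambda_opt, p$Popt, 0,
                                     p$lambda_opt, p$lambda_min), 0)
  expect_equal(active_nominal_stress(p$lambda_min, p$Popt, 1,
                                     p$lambda_opt, p$lambda_min), 0)
  expect_equal(active_nominal_stress(p$lambda_opt, p$Popt, 0.05,
                                     p$lambda_opt, p$lambda_min),
               0.05 * p$Popt)
})

test_that("activation schedules round-trip with step interpolation", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("0.0 0.0", "0.1 0.5", "0.2 1.0"), path)
  s <- read_activation_schedule(path)
  expect_equal(s(-0.05), 0)
  expect_equal(s(0.05), 0)
  expect_equal(s(0.15), 0.5)
  expect_equal(s(0.25), 1)
  expect_equal(s(c(0.05, 0.15, 5)), c(0, 0.5, 1))
  writeLines(c("0.0 0.0", "0.0 0.5"), path)
  expect_error(read_activation_schedule(path), "strictly increasing")
  writeLines(c("0.0 2.0"), path)
  expect_error(read_activation_schedule(path), "\\[0, 1\\]")
})

test_that("muscle_activation validates its inputs", {
  expect_error(muscle_activation("timed"), "finite time")
  a <- muscle_activation("tetanic", scale = 0.05)
  expect_s3_class(a, "muscle_activation")
  expect_error(muscle_activation("tetanic", scale = 2))
})
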