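test_that("tumor-free equilibrium has the closed-form location and spectrum", {
  m <- dimensionless_params(10, 5, 1, 1, 2)
  E1 <- tumor_free_equilibrium(m)
  expect_equal(c(E1$Cbar, E1$Lbar), c(1, 0))
  expect_equal(sort(Re(E1$eigenvalues)), c(-1, -1))
  expect_match(E1$stability, "^stable")
  # 1/m4 for the trajectory-figure frame, and instability when m5 < m4
  E1b <- tumor_free_equilibrium(frame_m(20, 2.5))
  expect_equal(E1b$Cbar, 0.14)
  expect_equal(sort(Re(E1b$eigenvalues)),
               sort(c(-m4_exact, 1 - 2.5 / m4_exact)))
  expect_match(E1b$stability, "saddle")
  # degenerate at the transcritical collision m5 = m4
  E1c <- tumor_free_equilibrium(dimensionless_params(10, 5, 1, 3, 3))
  expect_true(E1c$degenerate)
})

test_that("coexistence quadratic coefficients match hand arithmetic", {
  q <- coexistence_quadratic(frame_m(20, 2.5))
  expect_equal(q$a, -10)           # -20 / (1 + 2.5/2.5)
  expect_equal(q$c, 2.5 - m4_exact)
  expect_equal(q$b, 40 + 2.5 - m4_exact - 10)
  expect_equal(q$Delta, q$b^2 - 4 * q$a * q$c)
  # the R5 exemplar sits strictly inside the Prop-3 non-existence window
  rep5 <- existence_report(frame_m(40, 3))
  expect_false(rep5$exists)
  expect_gt(rep5$k, rep5$k1)
  expect_lt(rep5$k, rep5$k2)
  expect_lt(coexistence_quadratic(frame_m(40, 3))$Delta, 0)
  # m5 = m4: one root of the quadratic is exactly 0 (c = 0)
  q0 <- coexistence_quadratic(frame_m(20, m4_exact))
  expect_equal(q0$c, 0)
})

test_that("coexistence equilibria reproduce the weak-immunosuppression loads", {
  # gamma = 1.5e-4, alpha = 2e-11 scenario: tiny m2 puts the saddle load
  # near 5e12 cells and the controlled load near 2e7 cells
  p <- preset("fig7")
  eq <- equilibria(p)
  expect_true(eq$E2$exists && eq$E3$exists)
  expect_equal(eq$E2$Cbar, 4)     # 1/m5
  # independent oracle: roots from polyroot on the same coefficients
  q <- coexistence_quadratic(nondimensionalize(p))
  pr <- sort(Re(polyroot(c(q$c, q$b, q$a))), decreasing = TRUE)
  expect_equal(eq$E2$Lbar, pr[1], tolerance = 1e-10)
  expect_equal(eq$E3$Lbar, pr[2], tolerance = 1e-6)
  expect_equal(eq$E3$L_cells, 2e7, tolerance = 0.1)
  expect_equal(eq$E2$L_cells, 5e12, tolerance = 0.1)
  # the stable quadratic form keeps the small root accurate where the
  # naive formula loses it
  naive_L3 <- (-q$b + sqrt(q$Delta)) / (2 * q$a)
  expect_lt(abs(eq$E3$Lbar - pr[2]) / pr[2],
            abs(naive_L3 - pr[2]) / pr[2] + 1e-12)
})

test_that("existence and positivity flags follow the case logic", {
  # m5 >= m4: pair always exists, high root positive, low root negative
  m_hi <- frame_m(22, 8.75)
  r <- existence_report(m_hi)
  expect_true(r$exists)
  expect_true(r$L2_positive)
  expect_false(r$L3_positive)
  co <- coexistence_equilibria(m_hi)
  expect_gt(co$E2$Lbar, 0)
  expect_lt(co$E3$Lbar, 0)
  # m5 < m4 with small m2: both roots positive
  m_lo <- frame_m(20, 2.5)
  r2 <- existence_report(m_lo)
  expect_true(r2$exists && r2$L2_positive && r2$L3_positive)
  co2 <- coexistence_equilibria(m_lo)
  expect_true(co2$E2$Lbar > 0 && co2$E3$Lbar > 0)
  # flags agree with signs across random draws
  for (m in random_m(60, seed = 5)) {
    r <- existence_report(m)
    co <- coexistence_equilibria(m)
    expect_identical(r$exists, co$E2$exists || co$E3$exists)
    if (r$exists) {
      expect_identical(r$L2_positive, co$E2$Lbar >= 0)
      expect_identical(r$L3_positive, co$E3$Lbar >= 0)
    }
  }
})

test_that("on the transcritical line a coexistence root collapses onto E1", {
  for (m2 in c(5, 20, 60)) {
    m <- frame_m(m2, m4_exact)
    co <- coexistence_equilibria(m)
    expect_lt(min(abs(co$E2$Lbar), abs(co$E3$Lbar)), 1e-10)
  }
})

test_that("analytic Jacobian matches a central-difference oracle", {
  set.seed(31)
  for (m in random_m(50, seed = 31)) {
    x <- c(10^runif(1, -1, 1), 10^runif(1, -1, 1))
    J <- jacobian_at(x, m)$J
    h <- 1e-6 * pmax(1, abs(x))
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h[j]
      fd <- (rhs_dimensionless(x[1] + e[1], x[2] + e[2], m) -
               rhs_dimensionless(x[1] - e[1], x[2] - e[2], m)) / (2 * h[j])
      expect_equal(unname(J[, j]), unname(fd), tolerance = 1e-6)
    }
  }
})

test_that("Jacobian at coexistence points has a vanishing lower-right entry", {
  for (m in random_m(40, seed = 8)) {
    co <- coexistence_equilibria(m)
    for (E in list(co$E2, co$E3)) {
      if (!E$exists) next
      J <- jacobian_at(E, m)$J
      expect_lt(abs(J[2, 2]), 1e-12 * max(1, abs(J[1, 1])))
    }
  }
})

test_that("stability classes match the phase-portrait descriptions", {
  co <- coexistence_equilibria(frame_m(12.5, 6.25))
  expect_identical(co$E3$stability, "stable node")
  co <- coexistence_equilibria(frame_m(20, 2.5))
  expect_identical(co$E3$stability, "stable focus")
  co <- coexistence_equilibria(frame_m(25, 1))
  expect_identical(co$E3$stability, "unstable focus")
  expect_identical(coexistence_equilibria(frame_m(25, 1))$E2$stability,
                   "saddle")
  expect_error(classify_stability(coexistence_equilibria(frame_m(40, 3))$E2,
                                  frame_m(40, 3)),
               "non-existent")
})

test_that("closed-form equilibria agree with grid-seeded Newton root-finding", {
  draws <- random_m(200, seed = 2024)
  n_checked <- 0
  for (m in draws) {
    eq <- equilibria(m)
    roots <- newton_roots_from_grid(m)
    for (E in list(eq$E1, eq$E2, eq$E3)) {
      if (!E$exists || E$Lbar < 0) next
      d <- vapply(roots, function(r)
        sqrt(sum((r - c(E$Cbar, E$Lbar))^2)) /
          max(1, abs(E$Lbar), abs(E$Cbar)), numeric(1))
      expect_lt(min(d), 1e-8)
      # residual of the closed form itself
      expect_lt(relative_residual(m, E$Cbar, E$Lbar), 1e-10)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 250)
})
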