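test_that("orbit fates match the homoclinic-side exemplars", {
  fate_a <- classify_orbit(preset("fig4_R4A"), c(10, 3), horizon = 1e4)
  expect_identical(fate_a$outcome, "LIMIT_CYCLE")
  expect_true(fate_a$cycle$converged)
  fate_b <- classify_orbit(preset("fig4_R4B"), c(10, 3), horizon = 1e4)
  expect_identical(fate_b$outcome, "ESCAPE")
  expect_true(is.finite(fate_b$time_to_outcome))
})

test_that("damped-oscillation control captures the coexistence equilibrium", {
  # dimensional initial conditions are rescaled internally
  fate <- classify_orbit(preset("fig6"), c(1e7, 1e8))
  expect_identical(fate$outcome, "COEXIST")
  eq <- equilibria(nondimensionalize(preset("fig6")))
  expect_lt(sqrt(sum((fate$final_state - c(eq$E3$Cbar, eq$E3$Lbar))^2)),
            1e-6)
})

test_that("tumor-free capture occurs when the clearance condition holds", {
  fate <- classify_orbit(frame_m(22, 8.75), c(1, 0.5))
  expect_identical(fate$outcome, "TUMOR_FREE")
})

test_that("escaping orbits grow monotonically towards the bound", {
  m <- preset("fig4_R4B")
  eq <- equilibria(m)
  bound <- 1e5 * max(1, eq$E2$Lbar)
  tr <- integrate_model(m, c(10, 3), 1000, escape_bound = bound)
  expect_true(tr$escaped)
  # strictly increasing tumor load over the final decade of the orbit
  n <- length(tr$times)
  late <- tr$L[tr$times > max(tr$times) * 0.9]
  expect_true(all(diff(late) > 0))
  # the escape channel is the collapse of the CAR T population:
  # Cbar < 1/m5 persistently once the orbit leaves
  lateC <- tr$C[tr$times > max(tr$times) * 0.9]
  expect_true(all(lateC < 1 / m$m5))
})

test_that("fates are stable under solver-tolerance halving", {
  cases <- list(list(preset("fig4_R4A"), c(10, 3), "LIMIT_CYCLE"),
                list(preset("fig4_R4B"), c(10, 3), "ESCAPE"),
                list(frame_m(20, 2.5), c(0.04, 1), "COEXIST"),
                list(frame_m(22, 8.75), c(1, 0.5), "TUMOR_FREE"))
  for (cs in cases) {
    f1 <- classify_orbit(cs[[1]], cs[[2]], horizon = 1e4, rtol = 1e-8)
    f2 <- classify_orbit(cs[[1]], cs[[2]], horizon = 1e4, rtol = 1e-9)
    expect_identical(f1$outcome, cs[[3]])
    expect_identical(f2$outcome, cs[[3]])
  }
})

test_that("limit-cycle detection requires genuine recurrence", {
  m <- preset("fig4_R4A")
  eq <- equilibria(m)
  # seeding exactly at the equilibrium is an error, not a cycle
  expect_error(detect_limit_cycle(m, c(eq$E3$Cbar, eq$E3$Lbar)),
               "equilibrium")
  # cycle amplitude shrinks approaching the Hopf curve from above
  m5 <- 1
  m2h <- hopf_curve(40, 2.5, m4_exact, m5)$samples$m2
  amps <- vapply(c(2, 0.5), function(dm) {
    m <- frame_m(m2h + dm, m5)
    eq <- equilibria(m)
    cyc <- detect_limit_cycle(m, c(eq$E3$Cbar * 1.02, eq$E3$Lbar * 1.02),
                              horizon = 4000, rel_tol = 1e-2)
    diff(cyc$Lbar_range)
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("saddle manifolds seed along the eigenvectors and validate forward", {
  m <- nondimensionalize(preset("fig7"))
  eq <- equilibria(m)
  man <- saddle_manifolds(eq$E2, m, arclength = 100)
  x_eq <- c(eq$E2$Cbar, eq$E2$Lbar)
  for (br in c("stable_plus", "stable_minus")) {
    v <- (as.numeric(man[[br]][1, c("Cbar", "Lbar")]) - x_eq) / man$offset
    align <- abs(sum(v * man$eigen$stable_vector))
    expect_equal(align, 1, tolerance = 1e-6)
  }
  for (br in c("unstable_plus", "unstable_minus")) {
    v <- (as.numeric(man[[br]][1, c("Cbar", "Lbar")]) - x_eq) / man$offset
    expect_equal(abs(sum(v * man$eigen$unstable_vector)), 1,
                 tolerance = 1e-6)
  }
  # a stable-manifold point integrated forward returns to the saddle
  b <- man$stable_minus
  i <- which(b$s >= 5)[1]
  tr <- integrate_model(m, c(b$Cbar[i], b$Lbar[i]), 30, n_out = 2000)
  d <- sqrt((tr$C - x_eq[1])^2 + (tr$L - x_eq[2])^2) /
    max(1, sqrt(sum(x_eq^2)))
  expect_lt(min(d), 1e-4)
  # non-saddle input is rejected
  expect_error(saddle_manifolds(eq$E3, m, arclength = 10), "not a saddle")
})

test_that("heteroclinic connections terminate at the printed targets", {
  # tumor-free-stable region: the unstable manifold of E2 reaches E1
  m <- frame_m(22, 8.75)
  eq <- equilibria(m)
  man <- saddle_manifolds(eq$E2, m, arclength = 30)
  ends <- lapply(c("unstable_plus", "unstable_minus"), function(br) {
    b <- man[[br]]; c(b$Cbar[nrow(b)], b$Lbar[nrow(b)])
  })
  d1 <- vapply(ends, function(e)
    sqrt(sum((e - c(eq$E1$Cbar, 0))^2)), numeric(1))
  expect_lt(min(d1), 1e-6)
  # stable-node region: unstable branches of both saddles reach E3
  m <- frame_m(12.5, 6.25)
  eq <- equilibria(m)
  for (saddle in list(eq$E1, eq$E2)) {
    man <- saddle_manifolds(saddle, m, arclength = 30)
    dist3 <- vapply(c("unstable_plus", "unstable_minus"), function(br) {
      b <- man[[br]]
      sqrt(sum((c(b$Cbar[nrow(b)], b$Lbar[nrow(b)]) -
                  c(eq$E3$Cbar, eq$E3$Lbar))^2))
    }, numeric(1))
    expect_lt(min(dist3), 1e-6)
  }
})

test_that("basin bisection finds the curable-burden threshold", {
  p <- preset("fig7")
  bt <- basin_threshold(p, C0 = 1e7, L_bracket = c(1e11, 5e12))
  expect_identical(bt$fate_lower, "COEXIST")
  expect_identical(bt$fate_upper, "ESCAPE")
  expect_lt(diff(bt$bracket) / bt$L0_star, 2e-3)
  # agrees with the stable-manifold crossing of the same vertical line
  m <- nondimensionalize(p)
  eq <- equilibria(m)
  man <- saddle_manifolds(eq$E2, m,
                          arclength = 2 * (eq$E2$Lbar + eq$E2$Cbar) + 10,
                          Lmax = 10 * eq$E2$Lbar + 10,
                          Cmax = 100 * eq$E2$Cbar + 10)
  cut <- cartnode:::branch_crossing(man$stable_minus, 0.04)
  if (is.na(cut)) cut <- cartnode:::branch_crossing(man$stable_plus, 0.04)
  expect_equal(bt$L0_star, p$H * cut, tolerance = 0.01)
  # the threshold is nondecreasing in the infused dose
  bt_lo <- basin_threshold(p, C0 = 2.5e5, L_bracket = c(1e11, 5e12))
  bt_hi <- basin_threshold(p, C0 = 1e8, L_bracket = c(1e11, 5e12))
  expect_gte(bt_hi$L0_star, bt_lo$L0_star)
  # a bracket entirely on the controlled side is rejected
  expect_error(basin_threshold(p, C0 = 1e7, L_bracket = c(1e9, 1e10)),
               "bracket invalid")
})

test_that("curable-burden curves sweep as the immunology dictates", {
  p <- preset("fig5")
  gamma_grid <- 10^seq(log10(1e-4), log10(5e-3), length.out = 5)
  cg <- curable_burden_curves(p, list(gamma = gamma_grid))
  low <- cg[cg$C_line == 2.5e5, ]
  expect_equal(nrow(low), 5)
  expect_true(all(is.finite(low$L_cutoff)))
  # stronger immunosuppression shrinks the curable burden
  expect_true(all(diff(low$L_cutoff) < 0))
  # the low-dose and high-dose lines bound a curability window
  hi <- cg[cg$C_line == 1e8, ]
  expect_true(all(hi$L_cutoff > low$L_cutoff))
  # cutoff approximately linear in the killing efficiency
  ca <- curable_burden_curves(p, list(alpha = seq(1e-11, 1e-10,
                                                  length.out = 5)))
  lowa <- ca[ca$C_line == 2.5e5, ]
  fit <- stats::lm(L_cutoff ~ value, data = lowa)
  expect_gt(summary(fit)$r.squared, 0.99)
})
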