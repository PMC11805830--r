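test_that("fold branches annihilate the coexistence pair", {
  m5g <- seq(0.5, m4_exact, length.out = 9)
  fc <- fold_curve(40, 2.5, m4_exact, m5g)
  for (i in seq_along(m5g)) {
    for (br in c("m2_minus", "m2_plus")) {
      m <- frame_m(fc$samples[[br]][i], m5g[i])
      q <- coexistence_quadratic(m)
      expect_lt(abs(q$Delta), 1e-8 * max(1, q$b^2))
      # on the curve the two roots coincide (E2 = E3)
      co <- coexistence_equilibria(m)
      if (co$E2$exists && co$E3$exists)
        expect_lt(abs(co$E2$Lbar - co$E3$Lbar),
                  1e-3 * max(1, abs(co$E2$Lbar)))
    }
    # strictly inside the wedge: no real coexistence roots
    m_in <- frame_m(0.5 * (fc$samples$m2_minus[i] + fc$samples$m2_plus[i]),
                    m5g[i])
    if (m5g[i] < m4_exact - 1e-6)
      expect_lt(coexistence_quadratic(m_in)$Delta, 0)
  }
  # branches meet at the pitchfork point m2 = m1 (1 + m3/m4)
  at_m4 <- fold_curve(40, 2.5, m4_exact, m4_exact)$samples
  expect_equal(at_m4$m2_minus, at_m4$m2_plus)
  expect_equal(at_m4$m2_minus, 40 * (1 + 2.5 / m4_exact))
  # m5 -> 0+: both branches blow up monotonically
  small <- fold_curve(40, 2.5, m4_exact, c(1e-3, 1e-2, 0.1))$samples
  expect_true(all(diff(small$m2_minus) < 0))
  expect_true(all(diff(small$m2_plus) < 0))
  expect_gt(small$m2_minus[1], 1e3)
  expect_error(fold_curve(40, 2.5, m4_exact, 8), "m5 <= m4")
})

test_that("the Hopf curve zeroes the trace of the Jacobian at E3", {
  m5g <- seq(0.3, 3, length.out = 8)
  hc <- hopf_curve(40, 2.5, m4_exact, m5g)
  expect_true(all(hc$samples$valid))
  for (i in seq_along(m5g)) {
    m <- frame_m(hc$samples$m2[i], m5g[i])
    co <- coexistence_equilibria(m)
    J <- jacobian_at(co$E3, m)
    expect_lt(abs(J$trace), 1e-8)
    expect_gt(J$det, 0)
    # purely imaginary eigenvalues
    expect_lt(max(abs(Re(J$eigenvalues))), 1e-7)
    # the equilibrium tumor level on the curve matches the reported form
    expect_equal(co$E3$Lbar, hc$samples$Lbar_H[i], tolerance = 1e-8)
  }
  # stable just below the curve, unstable just above
  m2h <- hc$samples$m2[3]; m5 <- m5g[3]
  expect_match(coexistence_equilibria(frame_m(m2h - 0.5, m5))$E3$stability,
               "^stable")
  expect_match(coexistence_equilibria(frame_m(m2h + 0.5, m5))$E3$stability,
               "^unstable")
  # no Hopf when m1 <= m4
  expect_true(hopf_curve(6, 2.5, m4_exact, m5g)$empty)
})

test_that("an attracting limit cycle is born across the Hopf curve", {
  # numerical supercriticality probe just above the curve
  m5 <- 1
  m2h <- hopf_curve(40, 2.5, m4_exact, m5)$samples$m2
  m <- frame_m(m2h + 0.5, m5)
  eq <- equilibria(m)
  cyc <- detect_limit_cycle(m, c(eq$E3$Cbar * 1.02, eq$E3$Lbar * 1.02),
                            horizon = 4000, rel_tol = 1e-2)
  expect_true(cyc$converged)
  expect_gt(diff(cyc$Lbar_range), 0)
  expect_lt(diff(cyc$Lbar_range), 0.3)   # small-amplitude near onset
})

test_that("the Bogdanov-Takens point lies on both curves", {
  bt <- bt_point(40, 2.5, m4_exact)
  expect_gt(bt$m5, 0)
  expect_lt(bt$m5, m4_exact)
  expect_lt(abs(bt$fold_residual), 1e-6)
  expect_lt(abs(bt$hopf_residual), 1e-6)
  # m1 barely above m4: the point still exists
  bt2 <- bt_point(7.5, 2.5, m4_exact)
  expect_lt(abs(bt2$fold_residual), 1e-6)
  expect_error(bt_point(6, 2.5, m4_exact), "no BT point")
})

test_that("crossing m5 = m4 exchanges the stability of E1", {
  for (m2 in c(10, 30)) {
    above <- tumor_free_equilibrium(frame_m(m2, m4_exact + 0.5))
    below <- tumor_free_equilibrium(frame_m(m2, m4_exact - 0.5))
    expect_match(above$stability, "^stable")
    expect_match(below$stability, "saddle")
    # the colliding coexistence root swaps the opposite way
    co_above <- coexistence_equilibria(frame_m(m2, m4_exact + 0.5))
    co_below <- coexistence_equilibria(frame_m(m2, m4_exact - 0.5))
    small_above <- if (abs(co_above$E2$Lbar) < abs(co_above$E3$Lbar))
      co_above$E2 else co_above$E3
    small_below <- if (abs(co_below$E2$Lbar) < abs(co_below$E3$Lbar))
      co_below$E2 else co_below$E3
    expect_match(small_above$stability, "saddle")
    expect_false(identical(small_below$stability, "saddle"))
  }
})

test_that("region classifier reproduces the printed exemplar labels", {
  pairs <- list(R1 = c(22, 8.75), R2 = c(12.5, 6.25), R3 = c(20, 2.5),
                R5 = c(40, 3))
  for (nm in names(pairs)) {
    lab <- classify_region(frame_m(pairs[[nm]][1], pairs[[nm]][2]))
    expect_identical(lab$name, nm)
    expect_false(lab$reconstructed)
  }
  # the unstable-focus zone without the (expensive) cycle probe
  expect_identical(classify_region(frame_m(25, 1), resolve_r4 = FALSE)$name,
                   "R4")
  # exactly on the transcritical line: boundary label
  expect_identical(classify_region(frame_m(20, m4_exact))$name, "boundary")
  # m1 < m4 with existing but non-positive pair: reconstructed inventory
  m9 <- dimensionless_params(6, 0.01, 2.5, m4_exact, 0.5)
  lab9 <- classify_region(m9)
  expect_true(lab9$name %in% c("R9", "R10"))
  expect_true(lab9$reconstructed)
})

test_that("the atlas raster is consistent with pointwise classification", {
  at <- region_atlas(40, 2.5, m4_exact, m2_range = c(5, 42),
                     m5_range = c(0.5, 9), resolution = 7)
  expect_equal(nrow(at$raster), 49)
  for (i in sample(nrow(at$raster), 10)) {
    m <- dimensionless_params(40, at$raster$m2[i], 2.5, m4_exact,
                              at$raster$m5[i])
    expect_identical(classify_region(m, resolve_r4 = FALSE)$name,
                     at$raster$region[i])
  }
  # qualitative layout of the frame: tumor-free-stable region at high m5,
  # controlled-coexistence at moderate m2 and m5 < m4, escape-only at
  # high m2 inside the fold wedge
  expect_identical(at$raster$region[at$raster$m5 == 9 & at$raster$m2 == 5],
                   "R1")
  expect_true("R5" %in% at$raster$region)
  expect_true(any(grepl("^R2|^R3", at$raster$region)))
  expect_error(region_atlas(40, 2.5, m4_exact, c(1, 40), c(0.5, 9),
                            resolution = 1), "resolution")
})

test_that("raising the inflow parameter m3 grows the controlled regions", {
  window <- expand.grid(m2 = seq(5, 40, length.out = 8),
                        m5 = seq(0.5, 6, length.out = 6))
  frac_controlled <- function(m3) {
    labs <- apply(window, 1, function(r) {
      classify_region(dimensionless_params(40, r[["m2"]], m3, m4_exact,
                                           r[["m5"]]),
                      resolve_r4 = FALSE)$name
    })
    mean(labs %in% c("R2", "R3", "R4"))
  }
  fr <- vapply(c(0.05, 2.5, 5), frac_controlled, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("homoclinic bisection separates cycle from escape", {
  hom <- locate_homoclinic(40, 2.5, m4_exact, 1, c(25, 33), rtol = 5e-3)
  expect_gt(hom$m2_hom, 25)
  expect_lt(hom$m2_hom, 33)
  expect_identical(hom$fate_lower, "LIMIT_CYCLE")
  expect_identical(hom$fate_upper, "ESCAPE")
  # period of the cycle grows approaching the homoclinic from below
  per <- vapply(c(25, 28, 31), function(m2) {
    m <- frame_m(m2, 1)
    eq <- equilibria(m)
    detect_limit_cycle(m, c(eq$E3$Cbar * 1.01, eq$E3$Lbar * 1.01),
                       horizon = 5000, rel_tol = 1e-2)$period
  }, numeric(1))
  expect_true(all(diff(per) > 0))
  # invalid bracket: both endpoints on the cycling side
  expect_error(locate_homoclinic(40, 2.5, m4_exact, 1, c(25, 26),
                                 horizon = 2000),
               "bracket invalid")
})
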