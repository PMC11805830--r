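# shared fixtures: the study frame and random parameter draws

m4_exact <- 1 / (0.02 * 7)  # = 1/(rho * tau_C) for the trajectory figures

# dimensionless set on the standard frame (m1, m3, m4) = (40, 2.5, 1/0.14)
frame_m <- function(m2, m5) dimensionless_params(40, m2, 2.5, m4_exact, m5)

# moderate random dimensionless draws for property tests
random_m <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    dimensionless_params(m1 = runif(1, 2, 50),
                         m2 = 10^runif(1, -1.3, 1.7),
                         m3 = 10^runif(1, -1, 0.7),
                         m4 = runif(1, 0.5, 10),
                         m5 = 10^runif(1, -1, 1))
  })
}

random_dimensional <- function(n, seed = 1) {
  sample_cohort(n, seed = seed)$params
}

# damped Newton root-finder on the dimensionless vector field with a
# central-difference Jacobian: the independent oracle for the closed-form
# equilibria
newton_root <- function(m, x0, tol = 1e-13, maxit = 80) {
  fd_jac <- function(x) {
    h <- 1e-7 * pmax(1, abs(x))
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h[j]
      fp <- rhs_dimensionless(x[1] + e[1], x[2] + e[2], m)
      fm <- rhs_dimensionless(x[1] - e[1], x[2] - e[2], m)
      J[, j] <- (fp - fm) / (2 * h[j])
    }
    J
  }
  x <- x0
  f <- rhs_dimensionless(x[1], x[2], m)
  for (it in seq_len(maxit)) {
    scale <- max(1, sqrt(sum(x^2)))
    if (sqrt(sum(f^2)) < tol * scale) return(x)
    J <- fd_jac(x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      fn <- tryCatch(rhs_dimensionless(xn[1], xn[2], m),
                     error = function(e) c(Inf, Inf))
      if (sum(fn^2) < sum(f^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn; f <- fn
  }
  if (sqrt(sum(f^2)) < 1e-10 * max(1, sqrt(sum(x^2)))) x else NULL
}

# Newton roots collected from a coarse grid of seeds around the relevant
# scales of the draw
newton_roots_from_grid <- function(m) {
  Cs <- unique(c(1 / m$m4, 1 / m$m5) %o% c(0.5, 1, 1.7))
  Ls <- c(0, 0.1, 1, 10, 1e3, 1e5)
  roots <- list()
  for (C0 in Cs) for (L0 in Ls) {
    r <- newton_root(m, c(C0, L0))
    if (is.null(r)) next
    dup <- any(vapply(roots, function(x)
      sqrt(sum((x - r)^2)) < 1e-6 * max(1, sqrt(sum(r^2))), logical(1)))
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  roots
}

# relative residual of the vector field at a point: |f| scaled by the
# largest term magnitude entering each component
relative_residual <- function(m, Cbar, Lbar) {
  f <- rhs_dimensionless(Cbar, Lbar, m)
  terms1 <- c(1, m$m1 * Cbar * Lbar / (1 + Lbar),
              m$m2 * Cbar * Lbar / (1 + m$m3 * Cbar), m$m4 * Cbar)
  terms2 <- c(Lbar, m$m5 * Cbar * Lbar)
  max(abs(f[1]) / max(1, abs(terms1)), abs(f[2]) / max(1, abs(terms2)))
}
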