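#' Coexistence quadratic
#'
#' The tumor coordinates of the coexistence equilibria are the roots of
#' \eqn{a\bar L^2 + b\bar L + c = 0} with
#' \eqn{a = -m_2/(1+m_3/m_5)}, \eqn{b = m_1+m_5-m_4-m_2/(1+m_3/m_5)},
#' \eqn{c = m_5-m_4}, and discriminant \eqn{\Delta = b^2-4ac}.
#'
#' @param m A `dimensionless_params` (or `dimensional_params`) object.
#' @return A list of class `coexistence_quadratic` with `a`, `b`, `c`,
#'   `Delta`.
#' @export
coexistence_quadratic <- function(m) {
  m <- as_m(m)
  if (m$m5 == 0) stop("m5 must be positive")
  k <- m$m2 / (1 + m$m3 / m$m5)
  a <- -k
  b <- m$m1 + m$m5 - m$m4 - k
  c_ <- m$m5 - m$m4
  structure(list(a = a, b = b, c = c_, Delta = b^2 - 4 * a * c_, k = k),
            class = "coexistence_quadratic")
}

# numerically stable roots of a x^2 + b x + c (a may be 0 -> linear).
# Returns c(L2, L3) with L2 >= L3 for a < 0, or NAs when no real root.
quadratic_roots <- function(a, b, c_) {
  if (a == 0) {
    if (b == 0) return(c(NA_real_, NA_real_))
    # linear limit: the finite root plays the role of the low-load branch
    return(c(NA_real_, -c_ / b))
  }
  Delta <- b^2 - 4 * a * c_
  if (Delta < 0) return(c(NA_real_, NA_real_))
  # stable form avoids cancellation when |4ac| << b^2 (tiny root regime)
  sgn <- if (b >= 0) 1 else -1
  q <- -(b + sgn * sqrt(Delta)) / 2
  r1 <- q / a
  r2 <- if (q != 0) c_ / q else -b / a - r1
  roots <- sort(c(r1, r2), decreasing = TRUE)  # L2 >= L3 when a < 0
  roots
}

new_equilibrium <- function(label, Cbar, Lbar, exists, positive, m,
                            degenerate = FALSE) {
  eig <- c(NA_complex_, NA_complex_)
  stability <- NA_character_
  if (exists && all(is.finite(c(Cbar, Lbar)))) {
    J <- jacobian_dimensionless(Cbar, Lbar, m)
    eig <- eigen(J, only.values = TRUE)$values
    eig <- as.complex(eig)
    stability <- classify_from_jacobian(J)
  }
  structure(list(label = label, Cbar = Cbar, Lbar = Lbar, exists = exists,
                 positive = positive, eigenvalues = eig,
                 stability = stability, degenerate = degenerate),
            class = "cartnode_equilibrium")
}

#' @export
print.cartnode_equilibrium <- function(x, ...) {
  if (!x$exists) {
    cat(sprintf("%s: does not exist\n", x$label))
  } else {
    cat(sprintf("%s: (Cbar, Lbar) = (%g, %g), %s%s, eigenvalues %s\n",
                x$label, x$Cbar, x$Lbar, x$stability,
                if (x$positive) "" else " (not biologically positive)",
                paste(format(x$eigenvalues, digits = 4), collapse = ", ")))
  }
  invisible(x)
}

#' Tumor-free equilibrium
#'
#' \eqn{E_1 = (1/m_4, 0)}: CAR T-cells at their inflow/death balance, no
#' tumor.  Eigenvalues are \eqn{-m_4} and \eqn{1 - m_5/m_4}; asymptotically
#' stable iff \eqn{m_5 > m_4}.  When \eqn{m_5 = m_4} (within tolerance) the
#' second eigenvalue vanishes (transcritical collision) and the equilibrium
#' is flagged degenerate.
#'
#' @param m A `dimensionless_params` (or `dimensional_params`) object.
#' @param tol Relative tolerance for the degeneracy flag.
#' @return A `cartnode_equilibrium`.
#' @export
tumor_free_equilibrium <- function(m, tol = 1e-9) {
  m <- as_m(m)
  degen <- abs(m$m5 - m$m4) <= tol * max(1, abs(m$m4))
  new_equilibrium("E1", 1 / m$m4, 0, exists = TRUE, positive = TRUE, m = m,
                  degenerate = degen)
}

#' Coexistence equilibria
#'
#' The high-tumor-load (`E2`) and low-tumor-load (`E3`) coexistence states,
#' both at \eqn{\bar C = 1/m_5} with \eqn{\bar L_2 = (-b-\sqrt\Delta)/(2a)}
#' \eqn{\ge \bar L_3 = (-b+\sqrt\Delta)/(2a)}.  Roots are computed in the
#' cancellation-safe form (via \eqn{q=-(b+\mathrm{sign}(b)\sqrt\Delta)/2}),
#' which matters when the two roots differ by many orders of magnitude.
#' A negative discriminant is a valid non-existence outcome, not an error.
#'
#' @inheritParams tumor_free_equilibrium
#' @return A list with elements `E2` and `E3` (`cartnode_equilibrium`).
#' @export
coexistence_equilibria <- function(m, tol = 1e-9) {
  m <- as_m(m)
  quad <- coexistence_quadratic(m)
  roots <- quadratic_roots(quad$a, quad$b, quad$c)
  Cb <- 1 / m$m5
  degen_scale <- tol * max(1, quad$b^2)
  make <- function(label, L) {
    if (is.na(L)) {
      new_equilibrium(label, NA_real_, NA_real_, exists = FALSE,
                      positive = FALSE, m = m)
    } else {
      new_equilibrium(label, Cb, L, exists = TRUE, positive = L >= 0, m = m,
                      degenerate = abs(quad$Delta) <= degen_scale ||
                        abs(L) <= tol)
    }
  }
  list(E2 = make("E2", roots[1]), E3 = make("E3", roots[2]))
}

#' Existence and positivity report for the coexistence pair
#'
#' Evaluates the case logic governing when `E2`/`E3` exist and are
#' non-negative.  With \eqn{k = m_2/(1+m_3/m_5)}: when \eqn{m_5 \ge m_4}
#' both always exist; when \eqn{m_5 < m_4} they exist iff \eqn{k \le k_1} or
#' \eqn{k \ge k_2}, where \eqn{k_{1,2} = (m_1+m_4-m_5) \mp
#' 2\sqrt{m_1(m_4-m_5)}}.  Positivity: \eqn{\bar L_2 \ge 0} iff
#' \eqn{m_5 \ge m_4} or \eqn{m_2 \le (1+m_3/m_5)(m_1+m_5-m_4)};
#' \eqn{\bar L_3 \ge 0} iff the latter inequality holds and
#' \eqn{m_5 \le m_4}.
#'
#' @inheritParams tumor_free_equilibrium
#' @return A list of class `existence_report` with `Delta`, `k`, `k1`, `k2`,
#'   `exists`, `case` (which existence branch held), `L2_positive`,
#'   `L3_positive`.
#' @export
existence_report <- function(m) {
  m <- as_m(m)
  quad <- coexistence_quadratic(m)
  k <- quad$k
  if (m$m5 >= m$m4) {
    k1 <- NA_real_; k2 <- NA_real_
    exists <- TRUE
    case <- "m5 >= m4"
  } else {
    s <- 2 * sqrt(m$m1 * (m$m4 - m$m5))
    k1 <- (m$m1 + m$m4 - m$m5) - s
    k2 <- (m$m1 + m$m4 - m$m5) + s
    exists <- (k <= k1) || (k >= k2)
    case <- if (!exists) "m5 < m4, k in (k1, k2): no coexistence"
    else if (k <= k1) "m5 < m4, k <= k1" else "m5 < m4, k >= k2"
  }
  bpos <- m$m2 <= (1 + m$m3 / m$m5) * (m$m1 + m$m5 - m$m4)
  structure(list(Delta = quad$Delta, k = k, k1 = k1, k2 = k2,
                 exists = exists, case = case,
                 L2_positive = exists && (m$m5 >= m$m4 || bpos),
                 L3_positive = exists && bpos && m$m5 <= m$m4),
            class = "existence_report")
}

#' Jacobian report at a point
#'
#' Analytic Jacobian of the dimensionless vector field with trace,
#' determinant, discriminant (trace^2 - 4 det) and eigenvalues.  At a
#' coexistence equilibrium (\eqn{\bar C = 1/m_5}) the lower-right entry is
#' identically 0.
#'
#' @param point A `cartnode_equilibrium`, or numeric `c(Cbar, Lbar)`.
#' @param m A `dimensionless_params` (or `dimensional_params`) object.
#' @return A list of class `jacobian_report` with `J`, `trace`, `det`,
#'   `discriminant`, `eigenvalues`.
#' @export
jacobian_at <- function(point, m) {
  m <- as_m(m)
  if (inherits(point, "cartnode_equilibrium")) {
    if (!point$exists) stop("equilibrium does not exist")
    point <- c(point$Cbar, point$Lbar)
  }
  J <- jacobian_dimensionless(point[1], point[2], m)
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  structure(list(J = J, trace = tr, det = dt,
                 discriminant = tr^2 - 4 * dt,
                 eigenvalues = as.complex(eigen(J, only.values = TRUE)$values)),
            class = "jacobian_report")
}

# planar classification from a Jacobian matrix; degenerate boundaries
# flagged within relative tolerance
classify_from_jacobian <- function(J, tol = 1e-9) {
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * dt
  scale_d <- max(1, abs(tr)^2, abs(dt))
  if (abs(dt) <= tol * scale_d) return("center/degenerate")
  if (dt < 0) return("saddle")
  if (abs(tr) <= tol * sqrt(scale_d)) return("center/degenerate")
  side <- if (tr < 0) "stable" else "unstable"
  if (abs(disc) <= tol * scale_d) return(paste(side, "degenerate node"))
  kind <- if (disc < 0) "focus" else "node"
  paste(side, kind)
}

#' Stability class of an equilibrium
#'
#' Standard planar classification from the Jacobian: saddle iff det < 0,
#' otherwise stable/unstable by the sign of the trace, focus vs node by the
#' sign of trace^2 - 4 det; boundary cases within relative tolerance 1e-9
#' are reported as degenerate.
#'
#' @param eq A `cartnode_equilibrium` (must exist).
#' @param m A `dimensionless_params` (or `dimensional_params`) object.
#' @return A character stability class.
#' @export
classify_stability <- function(eq, m) {
  stopifnot(inherits(eq, "cartnode_equilibrium"))
  if (!eq$exists) stop("cannot classify a non-existent equilibrium")
  classify_from_jacobian(jacobian_at(eq, m)$J)
}

#' All equilibria of the model
#'
#' Convenience wrapper returning `E1`, `E2`, `E3` together with the
#' existence/positivity report; when a dimensional parameter set is given,
#' cell-unit coordinates are attached to each equilibrium.
#'
#' @param par A `dimensional_params` or `dimensionless_params` object.
#' @return A list of class `equilibria_report` with `E1`, `E2`, `E3`,
#'   `existence`, and (dimensional input only) `C_cells` / `L_cells`
#'   entries on each equilibrium.
#' @export
equilibria <- function(par) {
  m <- as_m(par)
  E1 <- tumor_free_equilibrium(m)
  co <- coexistence_equilibria(m)
  out <- list(E1 = E1, E2 = co$E2, E3 = co$E3, existence = existence_report(m),
              m = m)
  if (inherits(par, "dimensional_params")) {
    for (nm in c("E1", "E2", "E3")) {
      if (out[[nm]]$exists) {
        dim_state <- map_state(out[[nm]]$Cbar, out[[nm]]$Lbar, 0, par,
                               "to_dimensional")
        out[[nm]]$C_cells <- dim_state$C
        out[[nm]]$L_cells <- dim_state$L
      }
    }
    out$params <- par
  }
  structure(out, class = "equilibria_report")
}

#' @export
print.equilibria_report <- function(x, ...) {
  cat("Equilibria of the CAR T / lymphoma model:\n")
  for (nm in c("E1", "E2", "E3")) {
    print(x[[nm]])
    if (!is.null(x[[nm]]$L_cells))
      cat(sprintf("    in cells: C = %.4g, L = %.4g\n",
                  x[[nm]]$C_cells, x[[nm]]$L_cells))
  }
  invisible(x)
}
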