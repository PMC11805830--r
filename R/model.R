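#' Dimensional vector field
#'
#' Right-hand side of the lymph-node model in cells/day:
#' \eqn{dC/dt = \sigma + \beta CL/(H+L) - \gamma CL/(G+C) - C/\tau_C},
#' \eqn{dL/dt = \rho L - \alpha L C}.
#'
#' @param C,L CAR T-cell and lymphoma cell counts (non-negative).
#' @param p A `dimensional_params` object.
#' @param t Time in days (only used when a time-dependent inflow hook is
#'   attached to `p`).
#' @return Numeric vector `c(dC, dL)`.
#' @export
rhs_dimensional <- function(C, L, p, t = 0) {
  stopifnot(inherits(p, "dimensional_params"))
  if (!all(is.finite(c(C, L))))
    stop("non-finite state: integration blow-up")
  sig <- if (is.null(p$sigma_fun)) p$sigma else p$sigma_fun(t)
  dC <- sig + p$beta * C * L / (p$H + L) - p$gamma * C * L / (p$G + C) -
    C / p$tau_C
  dL <- p$rho * L - p$alpha * L * C
  c(dC = dC, dL = dL)
}

#' Dimensionless vector field
#'
#' Right-hand side of the rescaled system:
#' \eqn{d\bar C/d\bar t = 1 + m_1\bar C\bar L/(1+\bar L)
#'   - m_2\bar C\bar L/(1+m_3\bar C) - m_4\bar C},
#' \eqn{d\bar L/d\bar t = \bar L - m_5\bar C\bar L}.
#'
#' @param Cbar,Lbar Dimensionless populations (non-negative).
#' @param m A `dimensionless_params` object (or `dimensional_params`,
#'   mapped internally).
#' @return Numeric vector `c(dCbar, dLbar)`.
#' @export
rhs_dimensionless <- function(Cbar, Lbar, m) {
  m <- as_m(m)
  if (!all(is.finite(c(Cbar, Lbar))))
    stop("non-finite state: integration blow-up")
  dC <- 1 + m$m1 * Cbar * Lbar / (1 + Lbar) -
    m$m2 * Cbar * Lbar / (1 + m$m3 * Cbar) - m$m4 * Cbar
  dL <- Lbar - m$m5 * Cbar * Lbar
  c(dCbar = dC, dLbar = dL)
}

#' Analytic Jacobian of the dimensionless vector field
#'
#' @inheritParams rhs_dimensionless
#' @return A 2x2 matrix of partial derivatives at `(Cbar, Lbar)`.
#' @keywords internal
jacobian_dimensionless <- function(Cbar, Lbar, m) {
  m <- as_m(m)
  s <- 1 + m$m3 * Cbar
  matrix(c(m$m1 * Lbar / (1 + Lbar) - m$m2 * Lbar / s^2 - m$m4,
           m$m1 * Cbar / (1 + Lbar)^2 - m$m2 * Cbar / s,
           -m$m5 * Lbar,
           1 - m$m5 * Cbar),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("Cbar", "Lbar"), c("Cbar", "Lbar")))
}

# deSolve derivative functions --------------------------------------------
#
# The tumor component is integrated in log space (u = log L) whenever
# L(0) > 0: trajectories can dip many orders of magnitude below the solver's
# absolute tolerance during remission phases, and in linear space the
# inevitable small negative overshoot grows exponentially (and hits the
# 1 + Lbar = 0 pole of the stimulation term).  In log space positivity is
# structural and deep dips are resolved exactly.  L(0) = 0 lies on the
# invariant axis and is integrated in linear space (dL/dt = 0 exactly).

deriv_dimensionless <- function(t, y, parms) {
  with(parms, {
    C <- y[1]; L <- y[2]
    dC <- 1 + m1 * C * L / (1 + L) - m2 * C * L / (1 + m3 * C) - m4 * C
    dL <- L - m5 * C * L
    list(c(dC, dL))
  })
}

deriv_dimensionless_log <- function(t, y, parms) {
  with(parms, {
    C <- y[1]
    L <- exp(min(y[2], 700))
    dC <- 1 + m1 * C / (1 + 1 / L) - m2 * C * L / (1 + m3 * C) - m4 * C
    du <- 1 - m5 * C
    list(c(dC, du))
  })
}

deriv_dimensional <- function(t, y, parms) {
  C <- y[1]; L <- y[2]
  sig <- if (is.null(parms$sigma_fun)) parms$sigma else parms$sigma_fun(t)
  dC <- sig + parms$beta * C * L / (parms$H + L) -
    parms$gamma * C * L / (parms$G + C) - C / parms$tau_C
  dL <- parms$rho * L - parms$alpha * L * C
  list(c(dC, dL))
}

deriv_dimensional_log <- function(t, y, parms) {
  C <- y[1]
  L <- exp(min(y[2], 700))
  sig <- if (is.null(parms$sigma_fun)) parms$sigma else parms$sigma_fun(t)
  dC <- sig + parms$beta * C / (1 + parms$H / L) -
    parms$gamma * C * L / (parms$G + C) - C / parms$tau_C
  du <- parms$rho - parms$alpha * C
  list(c(dC, du))
}

#' Integrate the model
#'
#' Stiff-capable integration (deSolve, `lsoda`) of either form of the model,
#' with optional terminal event when the tumor population crosses an escape
#' bound.  Output components in `(-atol, 0)` are clipped to 0 (positive
#' invariance of the model guarantees trajectories stay non-negative up to
#' solver error); more negative values raise an error.
#'
#' @param par A `dimensional_params` or `dimensionless_params` object; the
#'   matching form of the equations is integrated.
#' @param state Named numeric `c(C = , L = )` initial state (cells for the
#'   dimensional form, dimensionless otherwise); must be non-negative.
#' @param times Output times (days or dimensionless time).  A scalar is
#'   treated as a horizon and expanded to a uniform grid of `n_out` points.
#' @param escape_bound Terminate (event) when `L` exceeds this value;
#'   `NULL` disables the event.
#' @param n_out Number of output points when `times` is a scalar horizon.
#' @param rtol,atol Solver tolerances.  Defaults: `rtol = 1e-8` and
#'   `atol = 1e-10` (dimensionless) or `atol = 1e-2` cells (dimensional).
#' @return An object of class `cartnode_trajectory`: a list with `times`,
#'   `C`, `L`, `escaped` (logical), `diagnostics`.
#' @export
integrate_model <- function(par, state, times, escape_bound = NULL,
                            n_out = 2000, rtol = 1e-8, atol = NULL) {
  dimensional <- inherits(par, "dimensional_params")
  if (!dimensional) par <- as_m(par)
  if (is.null(atol)) atol <- if (dimensional) 1e-2 else 1e-10
  if (length(state) != 2 || any(!is.finite(state)) || any(state < 0))
    stop("initial state must be two finite non-negative values")
  if (length(times) == 1) times <- seq(0, times, length.out = n_out)
  log_L <- state[2] > 0
  y0 <- if (log_L) c(C = unname(state[1]), u = log(unname(state[2])))
  else c(C = unname(state[1]), L = 0)
  fn <- if (dimensional) {
    if (log_L) deriv_dimensional_log else deriv_dimensional
  } else {
    if (log_L) deriv_dimensionless_log else deriv_dimensionless
  }
  root <- NULL
  if (!is.null(escape_bound)) {
    root <- if (log_L) {
      function(t, y, parms) y[2] - log(escape_bound)
    } else {
      function(t, y, parms) y[2] - escape_bound
    }
  }
  # log-tumor component: tolerance on u is relative tolerance on L
  atol_vec <- if (log_L) c(atol, 1e-8) else atol
  sol <- try(deSolve::lsoda(y0, times, fn, parms = par, rtol = rtol,
                            atol = atol_vec, rootfunc = root,
                            maxsteps = 50000), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("solver failure: ", attr(sol, "condition")$message)
  escaped <- !is.null(root) && !is.null(attr(sol, "troot")) &&
    length(attr(sol, "troot")) > 0
  tt <- sol[, 1]; Cv <- sol[, 2]
  Lv <- if (log_L) exp(sol[, 3]) else sol[, 3]
  # positivity clipping: within -atol is solver noise, beyond is failure
  low <- min(min(Cv, na.rm = TRUE), min(Lv, na.rm = TRUE))
  if (is.finite(low) && low < -atol * 10)
    stop("trajectory violated positivity beyond solver tolerance (min = ",
         signif(low, 3), "): solver failure")
  Cv <- pmax(Cv, 0); Lv <- pmax(Lv, 0)
  structure(list(times = tt, C = Cv, L = Lv, escaped = escaped,
                 dimensional = dimensional,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    istate = attr(sol, "istate"),
                                    troot = attr(sol, "troot"))),
            class = "cartnode_trajectory")
}

#' @export
print.cartnode_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s): %d points, t in [%g, %g]%s\n",
              if (x$dimensional) "cells/days" else "dimensionless",
              length(x$times), min(x$times), max(x$times),
              if (x$escaped) ", terminated at escape bound" else ""))
  invisible(x)
}

#' @export
as.data.frame.cartnode_trajectory <- function(x, ...) {
  data.frame(t = x$times, C = x$C, L = x$L)
}
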