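#' Classify the long-run fate of an orbit
#'
#' Integrates the dimensionless system and classifies the outcome as one of
#' `TUMOR_FREE` (capture by the tumor-free equilibrium), `COEXIST` (capture
#' by the low-tumor coexistence equilibrium `E3`), `LIMIT_CYCLE` (bounded
#' non-equilibrium attractor with detected recurrence), `ESCAPE` (the tumor
#' population crossed the escape bound), or `UNRESOLVED`.
#'
#' Escape bound: \eqn{\bar L > 10^5 \max(1, \bar L_2)} (when the saddle
#' `E2` exists) — beyond every equilibrium scale the tumor grows
#' monotonically and cannot return.  Capture: distance to the equilibrium
#' below `capture_tol` sustained over the final 10 time units.  If the
#' horizon ends without resolution but the orbit is still contracting
#' towards an equilibrium, the integration is extended (up to
#' `max_extensions` doublings) before declaring `UNRESOLVED`.
#'
#' @param par A `dimensionless_params` or `dimensional_params` object (the
#'   dimensional form is rescaled internally; classification always runs in
#'   the dimensionless plane).
#' @param state Initial state: dimensionless `c(Cbar, Lbar)` for
#'   dimensionless input, cells `c(C, L)` for dimensional input.
#' @param horizon Base integration horizon in dimensionless time.
#' @param capture_tol Equilibrium-capture distance.
#' @param max_extensions Maximum number of horizon doublings.
#' @param rtol Relative solver tolerance forwarded to [integrate_model()].
#' @return A list of class `orbit_fate`: `outcome`, `time_to_outcome`
#'   (dimensionless), `final_state`, `cycle` (a `limit_cycle` when
#'   detected), `escape_bound`.
#' @export
classify_orbit <- function(par, state, horizon = 1000, capture_tol = 1e-6,
                           max_extensions = 3, rtol = 1e-8) {
  m <- as_m(par)
  if (inherits(par, "dimensional_params")) {
    s <- map_state(state[1], state[2], 0, par, "to_dimensionless")
    state <- c(s$C, s$L)
  }
  eq <- equilibria(m)
  L2 <- if (eq$E2$exists && eq$E2$positive) eq$E2$Lbar else NA_real_
  bound <- 1e5 * max(1, if (is.na(L2)) 1 else L2)
  targets <- list(TUMOR_FREE = c(eq$E1$Cbar, eq$E1$Lbar))
  if (eq$E3$exists && eq$E3$positive)
    targets$COEXIST <- c(eq$E3$Cbar, eq$E3$Lbar)

  run_horizon <- horizon
  x0 <- state
  t_offset <- 0
  for (round in 0:max_extensions) {
    # coarse pass: escape event + approach to an equilibrium
    tr <- integrate_model(m, x0, run_horizon, escape_bound = bound,
                          n_out = 2000, rtol = rtol)
    n <- length(tr$times)
    xe <- c(tr$C[n], tr$L[n])
    if (tr$escaped)
      return(orbit_fate("ESCAPE", t_offset + tr$times[n], xe, bound))
    # capture: close to a target now, and stays within tol for 10 units
    for (nm in names(targets)) {
      tg <- targets[[nm]]
      if (sqrt(sum((xe - tg)^2)) < capture_tol) {
        chk <- integrate_model(m, xe, 10, n_out = 200, rtol = rtol)
        d <- sqrt((chk$C - tg[1])^2 + (chk$L - tg[2])^2)
        if (all(d < capture_tol)) {
          dall <- sqrt((tr$C - tg[1])^2 + (tr$L - tg[2])^2)
          t_at <- t_offset + tr$times[which(dall < capture_tol)[1]]
          return(orbit_fate(nm, t_at, xe, bound))
        }
      }
    }
    # recurrence: densely sampled window from the end state
    win <- min(500, run_horizon)
    dense <- integrate_model(m, xe, win, escape_bound = bound,
                             n_out = 10000, rtol = rtol)
    if (dense$escaped)
      return(orbit_fate("ESCAPE", t_offset + run_horizon +
                          max(dense$times),
                        c(tail(dense$C, 1), tail(dense$L, 1)), bound))
    cyc <- try(cycle_from_trajectory(dense, min_peaks = 4, rel_tol = 1e-2,
                                     tail_frac = 1), silent = TRUE)
    if (!inherits(cyc, "try-error") && isTRUE(cyc$converged))
      return(orbit_fate("LIMIT_CYCLE", t_offset + run_horizon,
                        c(tail(dense$C, 1), tail(dense$L, 1)), bound,
                        cycle = cyc))
    # plausibly still in a transient: continue from the end state
    x0 <- c(tail(dense$C, 1), tail(dense$L, 1))
    t_offset <- t_offset + run_horizon + win
    run_horizon <- run_horizon * 2
  }
  orbit_fate("UNRESOLVED", NA_real_, x0, bound)
}

orbit_fate <- function(outcome, t, final_state, bound, cycle = NULL) {
  structure(list(outcome = outcome, time_to_outcome = t,
                 final_state = final_state, cycle = cycle,
                 escape_bound = bound),
            class = "orbit_fate")
}

#' @export
print.orbit_fate <- function(x, ...) {
  cat(sprintf("Orbit fate: %s%s\n", x$outcome,
              if (is.finite(x$time_to_outcome))
                sprintf(" (by t = %.4g)", x$time_to_outcome) else ""))
  invisible(x)
}

# recurrence analysis on the tail of a stored trajectory: successive maxima
# of Lbar as returns to a transversal section
cycle_from_trajectory <- function(tr, min_peaks = 3, rel_tol = 1e-3,
                                  tail_frac = 0.5) {
  n <- length(tr$times)
  idx <- which(tr$times >= tr$times[n] * (1 - tail_frac))
  L <- tr$L[idx]; C <- tr$C[idx]; tt <- tr$times[idx]
  k <- length(L)
  if (k < 10) stop("no cycle found: trajectory tail too short")
  peaks <- which(L[2:(k - 1)] > L[1:(k - 2)] & L[2:(k - 1)] >= L[3:k]) + 1
  if (length(peaks) < min_peaks) stop("no cycle found: too few recurrences")
  # quadratic refinement of peak times/values
  pt <- numeric(length(peaks)); pv <- numeric(length(peaks))
  for (j in seq_along(peaks)) {
    i <- peaks[j]
    fit <- refine_peak(tt[(i - 1):(i + 1)], L[(i - 1):(i + 1)])
    pt[j] <- fit[1]; pv[j] <- fit[2]
  }
  last <- tail(seq_along(peaks), min_peaks)
  periods <- diff(pt)[tail(seq_len(length(pt) - 1), min_peaks - 1)]
  amp_spread <- (max(pv[last]) - min(pv[last])) / max(abs(pv[last]), 1e-12)
  per_spread <- (max(periods) - min(periods)) / max(mean(periods), 1e-12)
  converged <- amp_spread < rel_tol && per_spread < rel_tol &&
    diff(range(L)) > 1e-8
  one <- tt >= pt[length(pt)] - mean(periods) & tt <= pt[length(pt)]
  structure(list(period = mean(periods),
                 Cbar_range = range(C[one]), Lbar_range = range(L[one]),
                 n_peaks = length(peaks),
                 amplitude_spread = amp_spread, period_spread = per_spread,
                 converged = converged),
            class = "limit_cycle")
}

refine_peak <- function(t3, y3) {
  # vertex of the parabola through three points
  d <- (t3[2] - t3[1]) * (t3[3] - t3[2]) * (t3[3] - t3[1])
  if (d == 0) return(c(t3[2], y3[2]))
  A <- (y3[3] * (t3[2] - t3[1]) + y3[2] * (t3[1] - t3[3]) +
          y3[1] * (t3[3] - t3[2])) / d
  B <- (y3[3] * (t3[1]^2 - t3[2]^2) + y3[2] * (t3[3]^2 - t3[1]^2) +
          y3[1] * (t3[2]^2 - t3[3]^2)) / d
  if (A == 0) return(c(t3[2], y3[2]))
  tv <- -B / (2 * A)
  yv <- A * tv^2 + B * tv +
    (y3[2] - A * t3[2]^2 - B * t3[2])
  c(tv, yv)
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf(
    "Limit cycle: period %.6g, Cbar in [%.4g, %.4g], Lbar in [%.4g, %.4g]\n",
    x$period, x$Cbar_range[1], x$Cbar_range[2],
    x$Lbar_range[1], x$Lbar_range[2]))
  invisible(x)
}

#' Detect the attracting limit cycle
#'
#' Integrates from `seed` past the transient and estimates the period and
#' extrema of the attractor from successive refined maxima of \eqn{\bar L}
#' (returns to a transversal section).  Errors if the seed is an
#' equilibrium of the system or no recurrence is found within the horizon.
#'
#' @param m A `dimensionless_params` (or `dimensional_params`) object.
#' @param seed Dimensionless initial state `c(Cbar, Lbar)`.
#' @param horizon Integration horizon (dimensionless).
#' @param rel_tol Convergence tolerance on the spread of late peak
#'   amplitudes and periods.
#' @return A `limit_cycle`: `period`, `Cbar_range`, `Lbar_range`,
#'   `amplitude_spread`, `period_spread`, `converged`.
#' @export
detect_limit_cycle <- function(m, seed, horizon = 2000, rel_tol = 1e-3) {
  m <- as_m(m)
  f0 <- rhs_dimensionless(seed[1], seed[2], m)
  if (sqrt(sum(f0^2)) < 1e-9)
    stop("seed is an equilibrium, not a cycle")
  eq <- equilibria(m)
  L2 <- if (eq$E2$exists && eq$E2$positive) eq$E2$Lbar else 1
  bound <- 1e5 * max(1, L2)
  # transient burn-in at coarse output, then a densely sampled window
  win <- min(500, horizon / 2)
  tr <- integrate_model(m, seed, horizon - win, escape_bound = bound,
                        n_out = 2000)
  if (tr$escaped) stop("no cycle found: orbit escaped")
  n <- length(tr$times)
  dense <- integrate_model(m, c(tr$C[n], tr$L[n]), win,
                           escape_bound = bound, n_out = 20000)
  if (dense$escaped) stop("no cycle found: orbit escaped")
  cyc <- cycle_from_trajectory(dense, min_peaks = 4, rel_tol = rel_tol,
                               tail_frac = 1)
  if (!isTRUE(cyc$converged))
    stop("no cycle found: recurrence did not converge within horizon")
  cyc
}

#' Stable and unstable manifolds of a saddle
#'
#' Seeds four branches at \eqn{\pm\varepsilon} along the stable and
#' unstable eigenvectors of the saddle and traces each by integrating the
#' arclength-normalized vector field (forward for unstable branches,
#' backward for stable ones), so `arclength` bounds the curve length
#' directly.
#'
#' @param eq A `cartnode_equilibrium` that is a saddle.
#' @param m A `dimensionless_params` (or `dimensional_params`) object.
#' @param arclength Maximum arclength to trace per branch.
#' @param eps Seeding offset scale; the actual offset is
#'   `eps * (1 + |equilibrium|)`.
#' @param n_out Points per branch.
#' @param Lmax,Cmax Stop a branch when it leaves `[0-, Cmax] x [0-, Lmax]`
#'   (slightly negative values allowed so crossings of the axes are
#'   recorded).
#' @return A list of class `saddle_manifolds` with elements
#'   `stable_plus`, `stable_minus`, `unstable_plus`, `unstable_minus`,
#'   each a data frame (`s`, `Cbar`, `Lbar`), plus `eigen` (values and
#'   vectors at the saddle).
#' @export
saddle_manifolds <- function(eq, m, arclength = 50, eps = 1e-6,
                             n_out = 2000, Lmax = NULL, Cmax = NULL) {
  m <- as_m(m)
  stopifnot(inherits(eq, "cartnode_equilibrium"))
  if (!eq$exists) stop("equilibrium does not exist")
  J <- jacobian_dimensionless(eq$Cbar, eq$Lbar, m)
  ev <- eigen(J)
  lam <- ev$values
  if (any(Im(lam) != 0) || prod(Re(lam)) >= 0)
    stop("equilibrium is not a saddle")
  lam <- Re(lam); vec <- Re(ev$vectors)
  iu <- which.max(lam); is_ <- which.min(lam)
  x_eq <- c(eq$Cbar, eq$Lbar)
  off <- eps * (1 + sqrt(sum(x_eq^2)))
  if (is.null(Lmax)) Lmax <- max(10 * (1 + abs(eq$Lbar)), 1e6)
  if (is.null(Cmax)) Cmax <- max(10 * (1 + abs(eq$Cbar)), 1e6)
  trace_branch <- function(v, direction) {
    x0 <- x_eq + off * v
    dfun <- function(s, y, parms) {
      f <- rhs_dimensionless(y[1], y[2], m)
      nf <- sqrt(sum(f^2))
      list(direction * f / max(nf, 1e-300))
    }
    # chunked integration; a branch stops just past the coordinate axes
    # (so axis crossings are recorded), at the domain box, on arrival at
    # another equilibrium (|f| ~ 0, where the arclength-normalized field
    # is singular), or when the solver stalls
    ds <- arclength / n_out
    chunk <- max(min(250, arclength), 10 * ds)
    rows <- list(data.frame(s = 0, Cbar = x0[1], Lbar = x0[2]))
    s0 <- 0
    x <- c(x0[1], x0[2])
    n_chunks <- 0
    while (s0 < arclength - 1e-12 && n_chunks < 500) {
      n_chunks <- n_chunks + 1
      sc <- min(chunk, arclength - s0)
      grid <- seq(0, sc, length.out = max(2, ceiling(sc / ds) + 1))
      sol <- suppressWarnings(
        deSolve::lsoda(x, grid, dfun, parms = NULL, rtol = 1e-8,
                       atol = 1e-10, maxsteps = 10000))
      new <- data.frame(s = s0 + sol[-1, 1], Cbar = sol[-1, 2],
                        Lbar = sol[-1, 3])
      f2 <- vapply(seq_len(nrow(new)), function(i) {
        if (!all(is.finite(c(new$Cbar[i], new$Lbar[i])))) return(-1)
        sum(rhs_dimensionless(max(new$Cbar[i], 0), max(new$Lbar[i], 0),
                              m)^2)
      }, numeric(1))
      stop_i <- which(!is.finite(new$Cbar) | !is.finite(new$Lbar) |
                        new$Cbar < -0.005 | new$Lbar < -0.005 |
                        new$Cbar > Cmax | new$Lbar > Lmax |
                        f2 < 1e-16 | f2 < 0)
      if (length(stop_i) > 0) {
        rows[[length(rows) + 1]] <- new[seq_len(stop_i[1]), , drop = FALSE]
        break
      }
      rows[[length(rows) + 1]] <- new
      progressed <- max(sol[, 1])
      if (nrow(new) == 0 || progressed < 1e-3 * sc) break
      # a restart clears transient step-size collapse (e.g. the stiff
      # boundary layer near the seed); stop only when progress dies out
      x <- c(new$Cbar[nrow(new)], new$Lbar[nrow(new)])
      s0 <- s0 + progressed
    }
    do.call(rbind, rows)
  }
  vu <- vec[, iu] / sqrt(sum(vec[, iu]^2))
  vs <- vec[, is_] / sqrt(sum(vec[, is_]^2))
  structure(list(
    unstable_plus = trace_branch(vu, +1),
    unstable_minus = trace_branch(-vu, +1),
    stable_plus = trace_branch(vs, -1),
    stable_minus = trace_branch(-vs, -1),
    eigen = list(values = lam[c(is_, iu)], stable_vector = vs,
                 unstable_vector = vu),
    equilibrium = x_eq, offset = off),
    class = "saddle_manifolds")
}

# first crossing of a traced branch with the vertical line Cbar = c_line,
# linearly interpolated; NA when the branch never crosses
branch_crossing <- function(branch, c_line) {
  d <- branch$Cbar - c_line
  i <- which(d[-1] * d[-length(d)] <= 0 & !is.na(d[-1]))
  i <- i[d[i] != d[i + 1]]
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  w <- d[i] / (d[i] - d[i + 1])
  branch$Lbar[i] + w * (branch$Lbar[i + 1] - branch$Lbar[i])
}

#' Basin-of-attraction threshold on the initial tumor load
#'
#' At fixed initial CAR T-cell dose `C0`, bisects the initial lymphoma load
#' between a controlled fate (capture by an equilibrium or the limit cycle)
#' and escape.  The threshold approximates the crossing of the stable
#' manifold of the saddle `E2` — the boundary between curable and
#' non-curable initial burdens.
#'
#' @param p A `dimensional_params` object.
#' @param C0 Initial CAR T-cell count (cells).
#' @param L_bracket Length-2 bracket of initial lymphoma loads (cells)
#'   whose fates must differ.
#' @param rel_tol Relative bracket width at which bisection stops.
#' @param horizon Classification horizon (dimensionless time).
#' @return A list: `L0_star` (threshold, cells), `bracket`, `fate_lower`,
#'   `fate_upper`, `n_evaluations`.
#' @export
basin_threshold <- function(p, C0, L_bracket, rel_tol = 1e-3,
                            horizon = 1000) {
  stopifnot(inherits(p, "dimensional_params"), length(L_bracket) == 2,
            diff(L_bracket) > 0)
  controlled <- function(f) {
    if (f == "UNRESOLVED")
      stop("fate unresolved during bisection; increase horizon")
    f != "ESCAPE"
  }
  fate_at <- function(L0)
    classify_orbit(p, c(C0, L0), horizon = horizon)$outcome
  f_lo <- fate_at(L_bracket[1]); f_hi <- fate_at(L_bracket[2])
  n_eval <- 2
  if (controlled(f_lo) == controlled(f_hi))
    stop("bracket invalid: both endpoints have the same fate (",
         f_lo, ", ", f_hi, ")")
  lo <- L_bracket[1]; hi <- L_bracket[2]
  while ((hi - lo) > rel_tol * (lo + hi) / 2) {
    mid <- (lo + hi) / 2
    f_mid <- fate_at(mid); n_eval <- n_eval + 1
    if (controlled(f_mid) == controlled(f_lo)) lo <- mid else hi <- mid
  }
  list(L0_star = (lo + hi) / 2, bracket = c(lo, hi),
       fate_lower = f_lo, fate_upper = f_hi, n_evaluations = n_eval)
}

#' Curable-burden curves from the stable manifold of E2
#'
#' For each value of a swept parameter (`gamma` or `alpha`), computes the
#' saddle `E2`, traces its stable manifold backward, and records the
#' lymphoma load at which the manifold crosses each vertical line of
#' constant CAR T-cell count.  The lower line (default 2.5e5 cells)
#' gives the burden curable at any feasible dose; the upper line (default
#' 1e8 cells) the burden curable only at the largest feasible dose; the
#' band between them is the dose-dependent curability window.
#'
#' @param p Base `dimensional_params`; the swept parameter is overridden.
#' @param sweep Named list with one element, `gamma` or `alpha`: the grid
#'   of values to sweep.
#' @param C_lines CAR T-cell counts (cells) of the vertical lines.
#' @param arclength Manifold trace length (dimensionless).
#' @return A data frame of class `curable_burden`: columns `param`,
#'   `value`, `C_line`, `L_cutoff` (cells; `NA` records a curve gap where
#'   `E2` is absent or not a saddle, or the manifold misses the line).
#' @export
curable_burden_curves <- function(p, sweep, C_lines = c(2.5e5, 1e8),
                                  arclength = NULL) {
  stopifnot(inherits(p, "dimensional_params"), length(sweep) == 1,
            names(sweep) %in% c("gamma", "alpha"))
  pname <- names(sweep)
  rows <- list()
  for (v in sweep[[1]]) {
    pv <- p
    pv[[pname]] <- v
    pv <- dimensional_params(pv$sigma, pv$beta, pv$H, pv$gamma, pv$G,
                             pv$tau_C, pv$rho, pv$alpha)
    m <- nondimensionalize(pv)
    eq <- equilibria(m)
    cuts <- rep(NA_real_, length(C_lines))
    ok <- eq$E2$exists && eq$E2$positive &&
      identical(eq$E2$stability, "saddle")
    if (ok) {
      arc <- if (is.null(arclength)) 2 * (eq$E2$Lbar + eq$E2$Cbar) + 10
      else arclength
      man <- saddle_manifolds(eq$E2, m, arclength = arc,
                              Lmax = 10 * eq$E2$Lbar + 10,
                              Cmax = 100 * eq$E2$Cbar + 10)
      c_lines_bar <- (pv$rho / pv$sigma) * C_lines
      for (j in seq_along(C_lines)) {
        x <- branch_crossing(man$stable_minus, c_lines_bar[j])
        if (is.na(x)) x <- branch_crossing(man$stable_plus, c_lines_bar[j])
        cuts[j] <- if (is.na(x)) NA_real_ else pv$H * x
      }
    }
    for (j in seq_along(C_lines))
      rows[[length(rows) + 1]] <- data.frame(param = pname, value = v,
                                             C_line = C_lines[j],
                                             L_cutoff = cuts[j])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("curable_burden", class(out))
  out
}
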