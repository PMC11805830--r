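#' Fold (saddle-node) bifurcation curve
#'
#' For fixed `m1`, `m3`, `m4`, the coexistence pair is created/destroyed on
#' the two branches \eqn{m_2 = (1+m_3/m_5)(\sqrt{m_1} \mp \sqrt{m_4-m_5})^2},
#' defined for \eqn{0 < m_5 \le m_4}.  The branches meet at
#' \eqn{m_5 = m_4}, \eqn{m_2 = m_1(1+m_3/m_4)}, the subcritical pitchfork
#' point.
#'
#' @param m1,m3,m4 Fixed dimensionless parameters.
#' @param m5_grid Strictly positive values of `m5`; samples with
#'   `m5 > m4` are rejected with an error.
#' @return A list of class `bifurcation_curve` with `kind = "fold"`, and
#'   data frame `samples` (`m5`, `m2_minus`, `m2_plus`).
#' @export
fold_curve <- function(m1, m3, m4, m5_grid) {
  if (any(m5_grid <= 0)) stop("m5 samples must be positive")
  if (any(m5_grid > m4)) stop("fold branches are defined only for m5 <= m4")
  pref <- 1 + m3 / m5_grid
  root <- sqrt(pmax(m4 - m5_grid, 0))
  samples <- data.frame(m5 = m5_grid,
                        m2_minus = pref * (sqrt(m1) - root)^2,
                        m2_plus  = pref * (sqrt(m1) + root)^2)
  structure(list(kind = "fold", m1 = m1, m3 = m3, m4 = m4, samples = samples),
            class = "bifurcation_curve")
}

# scalar evaluators used by the BT locator and the region classifier
fold_m2 <- function(m1, m3, m4, m5, branch = c("minus", "plus")) {
  branch <- match.arg(branch)
  s <- sqrt(max(m4 - m5, 0))
  pref <- 1 + m3 / m5
  if (branch == "minus") pref * (sqrt(m1) - s)^2 else pref * (sqrt(m1) + s)^2
}

hopf_m2 <- function(m1, m3, m4, m5) {
  (m3 + m5)^2 * (m1 * m3 - m4 * m3 - m5^2) / (m3 * (m3 * m4 + m5^2))
}

hopf_conditions <- function(m1, m3, m4, m5) {
  m4 > m5 && m1 > (m3 * m4 + m5^2)^2 / (m3^2 * (m4 - m5))
}

#' Hopf bifurcation curve
#'
#' The low-tumor coexistence equilibrium `E3` loses stability through a Hopf
#' bifurcation on
#' \eqn{m_2 = (m_3+m_5)^2 (m_1 m_3 - m_4 m_3 - m_5^2) /
#' (m_3 (m_3 m_4 + m_5^2))}, valid where \eqn{m_4 > m_5} and
#' \eqn{m_1 > (m_3 m_4 + m_5^2)^2 / (m_3^2 (m_4 - m_5))}.  If
#' \eqn{m_1 \le m_4} no sample is valid and the curve is empty.
#'
#' @inheritParams fold_curve
#' @param m5_grid Values of `m5` to sample; invalid samples are kept with
#'   `valid = FALSE`.
#' @return A `bifurcation_curve` with `kind = "hopf"` and samples
#'   (`m5`, `m2`, `valid`, `Lbar_H`), where `Lbar_H` is the equilibrium
#'   tumor value \eqn{(m_3 m_4 + m_5^2)/(m_1 m_3 - m_3 m_4 - m_5^2)} on the
#'   curve.
#' @export
hopf_curve <- function(m1, m3, m4, m5_grid) {
  if (any(m5_grid <= 0)) stop("m5 samples must be positive")
  m2 <- hopf_m2(m1, m3, m4, m5_grid)
  valid <- vapply(m5_grid, function(v) hopf_conditions(m1, m3, m4, v),
                  logical(1))
  denomL <- m1 * m3 - m3 * m4 - m5_grid^2
  Lbar_H <- ifelse(denomL > 0, (m3 * m4 + m5_grid^2) / denomL, NA_real_)
  samples <- data.frame(m5 = m5_grid, m2 = m2, valid = valid,
                        Lbar_H = Lbar_H)
  structure(list(kind = "hopf", m1 = m1, m3 = m3, m4 = m4,
                 samples = samples, empty = !any(valid)),
            class = "bifurcation_curve")
}

#' Bogdanov-Takens point
#'
#' Codimension-two point where the fold and Hopf curves meet: the
#' \eqn{m_5 \in (0, m_4)} solving
#' \eqn{m_1 = (m_3 m_4 + m_5^2)^2 / (m_3^2 (m_4 - m_5))}.  Substituting
#' this `m1` back into either curve gives
#' \eqn{m_2 = m_5 (m_3 + m_5)^3 / (m_3^2 (m_4 - m_5))}; the fold (minus
#' branch) and Hopf expressions agree there, which is the defining property
#' of the point.  Requires \eqn{m_1 > m_4}.  Found by bracketed scalar
#' root-finding.
#'
#' @inheritParams fold_curve
#' @param tol Root-finding tolerance on `m5`.
#' @return A list with `m5`, `m2` and the residuals of the point against
#'   the fold (minus branch) and Hopf curves.
#' @export
bt_point <- function(m1, m3, m4, tol = 1e-12) {
  g <- function(m5) m1 - (m3 * m4 + m5^2)^2 / (m3^2 * (m4 - m5))
  eps <- m4 * 1e-10
  lo <- eps
  hi <- m4 - eps
  if (!is.finite(g(lo)) || !is.finite(g(hi)) || g(lo) * g(hi) > 0)
    stop("no BT point: defining function has no sign change on (0, m4) ",
         "(requires m1 > m4)")
  m5 <- stats::uniroot(g, c(lo, hi), tol = tol)$root
  m2 <- m5 * (m3 + m5)^3 / (m3^2 * (m4 - m5))
  list(m5 = m5, m2 = m2,
       fold_residual = m2 - fold_m2(m1, m3, m4, m5, "minus"),
       hopf_residual = m2 - hopf_m2(m1, m3, m4, m5))
}

#' Locate the homoclinic bifurcation by fate bisection
#'
#' On the far side of the Hopf curve, the attracting limit cycle around `E3`
#' grows with `m2` until it collides with a saddle connection and
#' disappears; beyond that all orbits escape.  This locator bisects `m2` on
#' the limit-cycle/escape dichotomy, classifying the fate of an orbit
#' started 1% away from `E3` at each trial value.
#'
#' @param m1,m3,m4 Fixed dimensionless parameters.
#' @param m5 The `m5` value at which to locate the homoclinic `m2`.
#' @param m2_bracket Length-2 bracket; the two endpoints must have opposite
#'   fates (bounded attractor vs escape), otherwise an error is raised.
#' @param rtol Relative bracket width at which bisection stops.
#' @param horizon Integration horizon (dimensionless time) for each fate.
#' @return A list with `m2_hom`, the final `bracket`, and the fates at the
#'   final endpoints.
#' @export
locate_homoclinic <- function(m1, m3, m4, m5, m2_bracket, rtol = 1e-3,
                              horizon = 1e4) {
  stopifnot(length(m2_bracket) == 2, diff(m2_bracket) > 0)
  fate_at <- function(m2) {
    m <- dimensionless_params(m1, m2, m3, m4, m5)
    co <- coexistence_equilibria(m)
    if (!co$E3$exists || !co$E3$positive)
      stop("E3 not positive at m2 = ", m2, "; bracket outside the R4 zone")
    x0 <- c(co$E3$Cbar * 1.01, co$E3$Lbar * 1.01)
    classify_orbit(m, x0, horizon = horizon)$outcome
  }
  bounded <- function(f) f %in% c("LIMIT_CYCLE", "COEXIST", "TUMOR_FREE")
  f_lo <- fate_at(m2_bracket[1])
  f_hi <- fate_at(m2_bracket[2])
  if (bounded(f_lo) == bounded(f_hi))
    stop("bracket invalid: both endpoints have the same fate (",
         f_lo, ", ", f_hi, ")")
  lo <- m2_bracket[1]; hi <- m2_bracket[2]
  while ((hi - lo) > rtol * (lo + hi) / 2) {
    mid <- (lo + hi) / 2
    f_mid <- fate_at(mid)
    if (bounded(f_mid) == bounded(f_lo)) lo <- mid else hi <- mid
  }
  list(m2_hom = (lo + hi) / 2, bracket = c(lo, hi),
       fate_lower = if (bounded(f_lo)) f_lo else fate_at(lo),
       fate_upper = if (bounded(f_hi)) f_hi else fate_at(hi))
}

#' Classify the (m2, m5) parameter-plane region
#'
#' Reproduces the region taxonomy of the bifurcation atlas by a decision
#' tree over computed properties: stability of the tumor-free equilibrium
#' (`m5` vs `m4`, the transcritical line), the discriminant of the
#' coexistence quadratic (fold), positivity of the coexistence pair, the
#' stability class of `E3`, and — in the zone where `E3` is an unstable
#' focus — the presence of the attracting limit cycle (separating `R4A`
#' from `R4B` across the homoclinic curve).
#'
#' Labels:
#' \itemize{
#'   \item `R1`: tumor-free state stable (`m5 > m4`); `E2` a positive
#'     saddle bounding its basin.
#'   \item `R2`/`R3`: positive `E3` a stable node / stable focus (tumor
#'     controlled at a small load).
#'   \item `R4A`/`R4B`: `E3` an unstable focus with / without the
#'     attracting limit cycle.
#'   \item `R5`: no coexistence pair (discriminant < 0) and tumor-free
#'     state unstable: all orbits escape.
#'   \item `R8`: positive `E3` an unstable node (escape, as `R4B`).
#'   \item `R6`/`R7` (`m1 > m4`) and `R9`/`R10` (`m1 <= m4`): coexistence
#'     pair exists but is not biologically positive; dynamics as `R5`.
#'     These names are a reconstruction keyed on computed properties
#'     (no closed-form inventory pins them down) and are flagged
#'     `reconstructed`.
#' }
#'
#' @param m A `dimensionless_params` (or `dimensional_params`) object.
#' @param resolve_r4 If `TRUE` (default), split `R4A`/`R4B` by a limit-cycle
#'   search (integration horizon `horizon`); if `FALSE`, return the
#'   unresolved label `"R4"` cheaply.
#' @param horizon Integration horizon for the limit-cycle probe.
#' @param boundary_tol Relative tolerance within which a point on a
#'   bifurcation curve is labelled `"boundary"`.
#' @return A list of class `region_label` with `name`, `description`,
#'   `reconstructed` flag, and the `properties` used by the tree.
#' @export
classify_region <- function(m, resolve_r4 = TRUE, horizon = 1e4,
                            boundary_tol = 1e-6) {
  m <- as_m(m)
  quad <- coexistence_quadratic(m)
  rel <- function(x, ref) abs(x) <= boundary_tol * max(1, abs(ref))
  # boundary checks on the defining quantities
  if (rel(m$m5 - m$m4, m$m4))
    return(region_label("boundary", "on the transcritical line m5 = m4", m))
  if (m$m5 < m$m4) {
    for (br in c("minus", "plus")) {
      f <- fold_m2(m$m1, m$m3, m$m4, m$m5, br)
      if (rel(m$m2 - f, f))
        return(region_label("boundary", paste("on the fold branch", br), m))
    }
    if (hopf_conditions(m$m1, m$m3, m$m4, m$m5)) {
      h <- hopf_m2(m$m1, m$m3, m$m4, m$m5)
      if (rel(m$m2 - h, h))
        return(region_label("boundary", "on the Hopf curve", m))
    }
  }
  rep_ <- existence_report(m)
  if (m$m5 > m$m4) {
    return(region_label(
      "R1", "tumor-free equilibrium stable; positive saddle E2 bounds its basin",
      m))
  }
  # m5 < m4: E1 unstable (saddle)
  if (!rep_$exists) {
    return(region_label(
      "R5", "no coexistence equilibria; tumor-free state unstable: escape", m))
  }
  co <- coexistence_equilibria(m)
  if (rep_$L2_positive && rep_$L3_positive) {
    cls <- co$E3$stability
    if (cls == "stable node")
      return(region_label("R2", "E3 a stable node: controlled tumor", m))
    if (cls == "stable focus" || cls == "stable degenerate node")
      return(region_label("R3", "E3 a stable focus: controlled tumor (damped oscillations)", m))
    if (cls == "unstable node")
      return(region_label("R8", "E3 an unstable node: escape", m))
    # unstable focus: limit cycle decides R4A vs R4B
    if (!resolve_r4)
      return(region_label("R4", "E3 an unstable focus (R4A/R4B unresolved)", m))
    x0 <- c(co$E3$Cbar * 1.01, co$E3$Lbar * 1.01)
    fate <- classify_orbit(m, x0, horizon = horizon)$outcome
    if (fate == "LIMIT_CYCLE")
      return(region_label("R4A", "E3 an unstable focus inside an attracting limit cycle: controllable oscillation", m))
    if (fate == "ESCAPE")
      return(region_label("R4B", "E3 an unstable focus, limit cycle destroyed at the homoclinic: escape", m))
    return(region_label("R4", paste0("E3 unstable focus, probe fate ", fate),
                        m))
  }
  # coexistence pair exists but not (both) positive: dynamics as R5
  high_side <- !is.na(rep_$k2) && rep_$k >= rep_$k2
  if (m$m1 > m$m4) {
    nm <- if (grepl("^stable", co$E3$stability)) "R6" else "R7"
    return(region_label(nm,
      "coexistence pair exists but is not positive (high-m2 side); escape as R5",
      m, reconstructed = TRUE))
  }
  nm <- if (high_side) "R10" else "R9"
  region_label(nm,
    "m1 <= m4: coexistence pair exists but is not positive; escape as R5",
    m, reconstructed = TRUE)
}

region_label <- function(name, description, m, reconstructed = FALSE) {
  structure(list(name = name, description = description,
                 reconstructed = reconstructed, m = m),
            class = "region_label")
}

#' @export
print.region_label <- function(x, ...) {
  cat(sprintf("Region %s%s: %s\n", x$name,
              if (x$reconstructed) " (reconstructed label)" else "",
              x$description))
  invisible(x)
}

#' Region atlas over an (m5, m2) window
#'
#' Classifies a raster of cell centres and overlays the analytic curves
#' (transcritical line, fold branches, Hopf curve) and the Bogdanov-Takens
#' point.
#'
#' @param m1,m3,m4 Fixed dimensionless parameters.
#' @param m2_range,m5_range Length-2 positive ranges.
#' @param resolution Number of cells per axis (>= 2).
#' @param resolve_r4 Passed to [classify_region()]; the default `FALSE`
#'   labels the unstable-focus zone `"R4"` without the (expensive)
#'   limit-cycle probe.
#' @param horizon Probe horizon when `resolve_r4 = TRUE`.
#' @return A list of class `region_atlas`: `raster` (data frame `m5`, `m2`,
#'   `region`, `reconstructed`), `curves`, `bt` (or `NULL` when absent).
#' @export
region_atlas <- function(m1, m3, m4, m2_range, m5_range, resolution = 25,
                         resolve_r4 = FALSE, horizon = 1e4) {
  if (resolution < 2) stop("resolution must be at least 2")
  if (any(c(m2_range, m5_range) <= 0)) stop("ranges must be positive")
  m2s <- seq(m2_range[1], m2_range[2], length.out = resolution)
  m5s <- seq(m5_range[1], m5_range[2], length.out = resolution)
  grid <- expand.grid(m5 = m5s, m2 = m2s)
  labs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    labs[[i]] <- classify_region(
      dimensionless_params(m1, grid$m2[i], m3, m4, grid$m5[i]),
      resolve_r4 = resolve_r4, horizon = horizon)
  }
  raster <- data.frame(
    m5 = grid$m5, m2 = grid$m2,
    region = vapply(labs, `[[`, character(1), "name"),
    reconstructed = vapply(labs, `[[`, logical(1), "reconstructed"))
  m5_curve <- seq(max(m5_range[1], 1e-6), min(m4, m5_range[2]),
                  length.out = 200)
  curves <- list(
    transcritical = data.frame(m5 = m4, m2 = m2s),
    fold = fold_curve(m1, m3, m4, m5_curve)$samples,
    hopf = hopf_curve(m1, m3, m4, m5_curve)$samples)
  bt <- tryCatch(bt_point(m1, m3, m4), error = function(e) NULL)
  structure(list(raster = raster, curves = curves, bt = bt,
                 m1 = m1, m3 = m3, m4 = m4),
            class = "region_atlas")
}

#' Serialize a region atlas
#'
#' Writes the raster as CSV and the curves + Bogdanov-Takens point as JSON.
#'
#' @param atlas A `region_atlas`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "region_atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raster_path <- file.path(dir, "atlas_raster.csv")
  utils::write.csv(atlas$raster, raster_path, row.names = FALSE)
  curves_path <- file.path(dir, "atlas_curves.json")
  jsonlite::write_json(list(m1 = atlas$m1, m3 = atlas$m3, m4 = atlas$m4,
                            curves = atlas$curves, bt = atlas$bt),
                       curves_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(raster_path, curves_path))
}
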