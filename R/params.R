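#' Dimensional model parameters
#'
#' Container for the eight rates and constants of the lymph-node model of
#' CAR T-cell / B-cell lymphoma dynamics, in units of cells and days:
#'
#' \deqn{dC/dt = \sigma + \beta C L/(H+L) - \gamma C L/(G+C) - C/\tau_C}
#' \deqn{dL/dt = \rho L - \alpha L C}
#'
#' @param sigma External inflow of CAR T-cells into the lymph node area
#'   (cells/day).  Assumed constant; a time-dependent inflow can be attached
#'   via the `sigma_fun` hook, but all analyses in this package use the
#'   constant value.
#' @param beta Maximum mitotic stimulation of CAR T-cells by tumor antigen
#'   (1/day).
#' @param H Lymphoma load giving half-maximal stimulation (cells).
#' @param gamma Maximum tumor-induced inactivation (immunosuppression) rate
#'   of CAR T-cells (1/day).  May be zero.
#' @param G CAR T-cell level at which inactivation saturates (cells).
#' @param tau_C Mean lifetime of activated CAR T-cells (days).
#' @param rho Lymphoma net growth rate (1/day).
#' @param alpha CAR T-cell killing efficiency (1/day/cell).  May be zero.
#' @param sigma_fun Optional function of time returning the inflow
#'   (cells/day); reserved hook, not used by the analyses.
#' @param check_ranges If `TRUE`, warn (do not error) when a value falls
#'   outside the literature plausibility ranges (see [table1_ranges()]).
#'
#' @return An object of class `dimensional_params` (a named list).
#' @seealso [nondimensionalize()], [table1_ranges()], [preset()]
#' @examples
#' p <- dimensional_params(sigma = 5e6, beta = 0.8, H = 1e8, gamma = 0.4,
#'                         G = 1e8, tau_C = 7, rho = 0.02, alpha = 2e-10)
#' nondimensionalize(p)
#' @export
dimensional_params <- function(sigma, beta, H, gamma, G, tau_C, rho, alpha,
                               sigma_fun = NULL, check_ranges = FALSE) {
  vals <- c(sigma = sigma, beta = beta, H = H, gamma = gamma, G = G,
            tau_C = tau_C, rho = rho, alpha = alpha)
  if (any(!is.finite(vals)))
    stop("all parameters must be finite numbers")
  pos <- c("sigma", "beta", "H", "G", "tau_C", "rho")
  if (any(vals[pos] <= 0))
    stop("parameters ", paste(pos[vals[pos] <= 0], collapse = ", "),
         " must be strictly positive")
  if (gamma < 0 || alpha < 0)
    stop("gamma and alpha must be non-negative")
  if (!is.null(sigma_fun) && !is.function(sigma_fun))
    stop("sigma_fun must be a function of time or NULL")
  p <- structure(as.list(vals), class = "dimensional_params")
  p$sigma_fun <- sigma_fun
  if (isTRUE(check_ranges)) validate_table1(p)
  p
}

#' Literature plausibility ranges for the dimensional parameters
#'
#' Ranges (cells, days) within which each dimensional parameter is considered
#' biologically plausible for diffuse large B-cell lymphoma under CAR T-cell
#' therapy.  Used as a soft validator and as the sampling frame for
#' [sample_cohort()] and the Sobol design.
#'
#' @return A named list; each element is `c(lower, upper)`.
#' @export
table1_ranges <- function() {
  list(sigma = c(1e5, 1e7),
       beta  = c(0.1, 0.9),
       H     = c(1e7, 1e10),
       gamma = c(0, 1),
       G     = c(1e6, 1e9),
       tau_C = c(7, 14),
       rho   = c(0.01, 0.2),
       alpha = c(1e-11, 1e-9))
}

#' Soft range check against the plausibility ranges
#'
#' Warns (never errors) for every parameter outside its [table1_ranges()]
#' interval.
#'
#' @param p A `dimensional_params` object.
#' @return Invisibly, a named logical vector: `TRUE` where in range.
#' @export
validate_table1 <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  rng <- table1_ranges()
  ok <- vapply(names(rng), function(nm) {
    v <- p[[nm]]
    v >= rng[[nm]][1] && v <= rng[[nm]][2]
  }, logical(1))
  if (any(!ok))
    warning("parameter(s) outside plausibility range: ",
            paste(names(ok)[!ok], collapse = ", "), call. = FALSE)
  invisible(ok)
}

#' @export
print.dimensional_params <- function(x, ...) {
  cat("Dimensional parameters (cells, days):\n")
  for (nm in c("sigma", "beta", "H", "gamma", "G", "tau_C", "rho", "alpha"))
    cat(sprintf("  %-6s = %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Dimensionless model parameters
#'
#' The five dimensionless groups governing the rescaled system
#' \deqn{d\bar C/d\bar t = 1 + m_1 \bar C\bar L/(1+\bar L)
#'   - m_2 \bar C\bar L/(1+m_3\bar C) - m_4 \bar C}
#' \deqn{d\bar L/d\bar t = \bar L - m_5 \bar C \bar L}
#' with \eqn{m_1=\beta/\rho}, \eqn{m_2=\gamma H/(\rho G)},
#' \eqn{m_3=\sigma/(\rho G)}, \eqn{m_4=1/(\rho\tau_C)},
#' \eqn{m_5=\alpha\sigma/\rho^2}.
#'
#' @param m1,m2,m3,m4,m5 Dimensionless non-negative values; `m1`, `m3`,
#'   `m4`, `m5` must be strictly positive (`m2` may be 0 when the
#'   immunosuppression rate gamma is 0).
#' @return An object of class `dimensionless_params`.
#' @export
dimensionless_params <- function(m1, m2, m3, m4, m5) {
  vals <- c(m1 = m1, m2 = m2, m3 = m3, m4 = m4, m5 = m5)
  if (any(!is.finite(vals))) stop("all m must be finite")
  if (m2 < 0) stop("m2 must be >= 0")
  strict <- c("m1", "m3", "m4", "m5")
  if (any(vals[strict] <= 0))
    stop(paste(strict[vals[strict] <= 0], collapse = ", "),
         " must be strictly positive")
  structure(as.list(vals), class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat(sprintf("Dimensionless parameters: m1 = %g, m2 = %g, m3 = %g, m4 = %g, m5 = %g\n",
              x$m1, x$m2, x$m3, x$m4, x$m5))
  invisible(x)
}

#' Map dimensional to dimensionless parameters
#'
#' @param p A `dimensional_params` object.
#' @return A `dimensionless_params` object with
#'   `m1 = beta/rho`, `m2 = gamma*H/(rho*G)`, `m3 = sigma/(rho*G)`,
#'   `m4 = 1/(rho*tau_C)`, `m5 = alpha*sigma/rho^2`.
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  if (p$rho == 0 || p$tau_C == 0) stop("rho and tau_C must be non-zero")
  dimensionless_params(m1 = p$beta / p$rho,
                       m2 = p$gamma * p$H / (p$rho * p$G),
                       m3 = p$sigma / (p$rho * p$G),
                       m4 = 1 / (p$rho * p$tau_C),
                       m5 = p$alpha * p$sigma / p$rho^2)
}

#' Map states between dimensional and dimensionless variables
#'
#' The rescaling is \eqn{\bar C = (\rho/\sigma) C}, \eqn{\bar L = L/H},
#' \eqn{\bar t = \rho t}; the inverse is the exact round trip.
#'
#' @param C,L,t Cell counts and time (days) if `direction = "to_dimensionless"`,
#'   or dimensionless values if `direction = "to_dimensional"`.  Vectors are
#'   mapped elementwise.
#' @param p A `dimensional_params` object supplying `rho`, `sigma`, `H`.
#' @param direction One of `"to_dimensionless"` or `"to_dimensional"`.
#' @return A list with elements `C`, `L`, `t` on the target scale.
#' @export
map_state <- function(C, L, t = 0, p, direction = c("to_dimensionless",
                                                    "to_dimensional")) {
  stopifnot(inherits(p, "dimensional_params"))
  direction <- match.arg(direction)
  if (direction == "to_dimensionless") {
    list(C = (p$rho / p$sigma) * C, L = L / p$H, t = p$rho * t)
  } else {
    list(C = (p$sigma / p$rho) * C, L = p$H * L, t = t / p$rho)
  }
}

#' Read or write a parameter set as YAML or JSON
#'
#' Parameter sets are serialized as a flat map keyed by the symbol names
#' (`sigma`, `beta`, `H`, `gamma`, `G`, `tau_C`, `rho`, `alpha`), together
#' with a `units` entry recording the cells/days convention.  JSON output
#' keeps full double precision and round-trips bit-exactly.
#'
#' @param p A `dimensional_params` object.
#' @param path Output (or input) file; format chosen by extension
#'   (`.json`, `.yaml`/`.yml`).
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a `dimensional_params` object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "dimensional_params"))
  x <- p[c("sigma", "beta", "H", "gamma", "G", "tau_C", "rho", "alpha")]
  x$units <- "cells, days"
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 17)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  dimensional_params(sigma = x$sigma, beta = x$beta, H = x$H, gamma = x$gamma,
                     G = x$G, tau_C = x$tau_C, rho = x$rho, alpha = x$alpha)
}

# internal: accept either parameter class, return dimensionless
as_m <- function(x) {
  if (inherits(x, "dimensionless_params")) return(x)
  if (inherits(x, "dimensional_params")) return(nondimensionalize(x))
  stop("expected dimensional_params or dimensionless_params")
}
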