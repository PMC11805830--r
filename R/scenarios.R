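#' Named study parameter presets
#'
#' Exact parameter sets used by the package's reproduction experiments
#' (trajectory panels, curable-burden curves, the atlas frame, the Sobol
#' fixed values, and the two homoclinic-side exemplars).
#'
#' Available presets:
#' \itemize{
#'   \item `"fig6"` (dimensional): beta = 0.8, H = G = 1e8, tau_C = 7,
#'     sigma = 5e6, gamma = 0.4, rho = 0.02, alpha = 2e-10; maps to
#'     (m2, m5) = (20, 2.5) — damped-oscillation tumor control.
#'   \item `"fig7"` (dimensional): as `"fig6"` but gamma = 1.5e-4,
#'     alpha = 2e-11; maps to (m2, m5) = (7.5e-3, 0.25) — weak
#'     immunosuppression, very high saddle burden.
#'   \item `"fig5"` (dimensional): the curable-burden base set
#'     (alpha = 2e-11, gamma = 1.5e-3; sweeps override one of them).
#'   \item `"fig8_fixed"` (list): the four fixed Sobol values
#'     (rho = 0.02, beta = 0.8, tau_C = 7, sigma = 2e5).
#'   \item `"fig4_R4A"` / `"fig4_R4B"` (dimensionless): (m1, m3, m4) =
#'     (40, 2.5, 7.142857...) with m2 = 25 / 33, m5 = 1 — the two sides of
#'     the homoclinic bifurcation.
#'   \item `"fig1b_frame"` (list): the fixed atlas frame m1 = 40,
#'     m3 = 2.5, m4 = 7.142857... .
#' }
#'
#' @param name Preset name.
#' @return A `dimensional_params`, `dimensionless_params`, or a plain list
#'   for the frame/fixed presets.
#' @export
preset <- function(name) {
  m4 <- 1 / (0.02 * 7)
  presets <- list(
    fig6 = function() dimensional_params(sigma = 5e6, beta = 0.8, H = 1e8,
                                         gamma = 0.4, G = 1e8, tau_C = 7,
                                         rho = 0.02, alpha = 2e-10),
    fig7 = function() dimensional_params(sigma = 5e6, beta = 0.8, H = 1e8,
                                         gamma = 1.5e-4, G = 1e8, tau_C = 7,
                                         rho = 0.02, alpha = 2e-11),
    fig5 = function() dimensional_params(sigma = 5e6, beta = 0.8, H = 1e8,
                                         gamma = 1.5e-3, G = 1e8, tau_C = 7,
                                         rho = 0.02, alpha = 2e-11),
    fig8_fixed = function() list(rho = 0.02, beta = 0.8, tau_C = 7,
                                 sigma = 2e5),
    fig4_R4A = function() dimensionless_params(40, 25, 2.5, m4, 1),
    fig4_R4B = function() dimensionless_params(40, 33, 2.5, m4, 1),
    fig1b_frame = function() list(m1 = 40, m3 = 2.5, m4 = m4)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]()
}

#' Sample a virtual cohort of parameter sets
#'
#' Seeded reproducible draws from the plausibility ranges: log-uniform
#' across ranges spanning a decade or more, uniform otherwise (and for
#' `gamma`, whose range starts at 0).
#'
#' @param n Number of parameter sets (> 0).
#' @param seed Integer seed.
#' @param ranges Named list overriding [table1_ranges()] entries; each
#'   override must lie inside the corresponding plausibility range.
#' @return A list of class `cohort_sample`: `params` (list of
#'   `dimensional_params`), `draws` (data frame), and the provenance
#'   (`seed`, `ranges`, `distributions`).
#' @export
sample_cohort <- function(n, seed = 1, ranges = list()) {
  if (n <= 0) stop("n must be positive")
  rng <- table1_ranges()
  for (nm in names(ranges)) {
    if (!nm %in% names(rng)) stop("unknown parameter: ", nm)
    if (ranges[[nm]][1] < rng[[nm]][1] || ranges[[nm]][2] > rng[[nm]][2])
      stop("override for ", nm, " outside the plausibility range")
    rng[[nm]] <- ranges[[nm]]
  }
  dists <- vapply(names(rng), function(nm) {
    r <- rng[[nm]]
    if (r[1] > 0 && r[2] / r[1] >= 10) "loguniform" else "uniform"
  }, character(1))
  set.seed(seed)
  draws <- as.data.frame(lapply(names(rng), function(nm) {
    r <- rng[[nm]]
    u <- stats::runif(n)
    if (dists[[nm]] == "loguniform")
      exp(log(r[1]) + u * (log(r[2]) - log(r[1])))
    else r[1] + u * (r[2] - r[1])
  }))
  names(draws) <- names(rng)
  params <- lapply(seq_len(n), function(i)
    dimensional_params(sigma = draws$sigma[i], beta = draws$beta[i],
                       H = draws$H[i], gamma = draws$gamma[i],
                       G = draws$G[i], tau_C = draws$tau_C[i],
                       rho = draws$rho[i], alpha = draws$alpha[i]))
  structure(list(params = params, draws = draws, seed = seed,
                 ranges = rng, distributions = dists),
            class = "cohort_sample")
}

#' Run a named figure-style experiment
#'
#' Executes the analysis pipeline behind one of the reproduction
#' experiments and writes its tables (CSV/JSON) plus a manifest recording
#' the preset, overrides, seed and solver tolerances.  Deterministic
#' experiments re-run bit-exactly from the manifest.
#'
#' Names: `"fig4"` (the two homoclinic-side orbits and their fates),
#' `"fig5"` (curable-burden curves over a gamma sweep and an alpha sweep),
#' `"fig6"` / `"fig7"` (initial-condition trajectory panels), `"fig1b"`
#' (region atlas for the fixed frame), `"fig8"` (Sobol first-order
#' indices).
#'
#' @param name Experiment name.
#' @param out_dir Output directory.
#' @param overrides Named list of experiment-specific overrides (e.g.
#'   `list(n = 128)` for `"fig8"`, `list(resolution = 15)` for
#'   `"fig1b"`, `list(horizon = 2000)` for `"fig4"`).
#' @param seed Seed for stochastic experiments (only `"fig8"`).
#' @return Invisibly, a list with the computed objects and `files`
#'   written.
#' @export
run_figure_experiment <- function(name, out_dir, overrides = list(),
                                  seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ov <- function(key, default)
    if (!is.null(overrides[[key]])) overrides[[key]] else default
  files <- character(0)
  result <- switch(
    name,
    fig4 = {
      horizon <- ov("horizon", 1e4)
      out <- lapply(c(fig4_R4A = "fig4_R4A", fig4_R4B = "fig4_R4B"),
                    function(ps) {
        m <- preset(ps)
        tr <- integrate_model(m, c(10, 3), ov("t_end", 300),
                              escape_bound = 1e7)
        fate <- classify_orbit(m, c(10, 3), horizon = horizon)
        list(trajectory = tr, fate = fate)
      })
      for (nm in names(out)) {
        f <- file.path(out_dir, paste0(nm, "_trajectory.csv"))
        utils::write.csv(as.data.frame(out[[nm]]$trajectory), f,
                         row.names = FALSE)
        files <- c(files, f)
      }
      f <- file.path(out_dir, "fig4_fates.json")
      jsonlite::write_json(
        lapply(out, function(x) x$fate$outcome), f, auto_unbox = TRUE)
      files <- c(files, f)
      out
    },
    fig5 = {
      p <- preset("fig5")
      gamma_grid <- ov("gamma_grid",
                       10^seq(log10(5e-5), log10(1e-2), length.out = 8))
      alpha_grid <- ov("alpha_grid", seq(1e-11, 1e-10, length.out = 8))
      cg <- curable_burden_curves(p, list(gamma = gamma_grid))
      ca <- curable_burden_curves(p, list(alpha = alpha_grid))
      out <- rbind(cg, ca)
      f <- file.path(out_dir, "curable_burden.csv")
      utils::write.csv(out, f, row.names = FALSE)
      files <- c(files, f)
      out
    },
    fig6 = ,
    fig7 = {
      p <- preset(name)
      grids <- if (name == "fig6") {
        list(L0 = c(5e7, 1e8, 1e9), C0_fixed = 1e7,
             C0 = c(1e7, 5e7, 1e8), L0_fixed = 1e8, t_end = 100)
      } else {
        list(L0 = c(1e9, 1e10, 1e11), C0_fixed = 1e7,
             C0 = c(1e6, 1e7, 1e8), L0_fixed = 1e10, t_end = 30)
      }
      t_end <- ov("t_end", grids$t_end)
      rows <- list()
      for (L0 in grids$L0) {
        tr <- integrate_model(p, c(grids$C0_fixed, L0), t_end, n_out = 500)
        rows[[length(rows) + 1]] <- cbind(as.data.frame(tr),
                                          C0 = grids$C0_fixed, L0 = L0,
                                          panel = "vary_L0")
      }
      for (C0 in grids$C0) {
        tr <- integrate_model(p, c(C0, grids$L0_fixed), t_end, n_out = 500)
        rows[[length(rows) + 1]] <- cbind(as.data.frame(tr),
                                          C0 = C0, L0 = grids$L0_fixed,
                                          panel = "vary_C0")
      }
      out <- do.call(rbind, rows)
      f <- file.path(out_dir, paste0(name, "_trajectories.csv"))
      utils::write.csv(out, f, row.names = FALSE)
      files <- c(files, f)
      out
    },
    fig1b = {
      frame <- preset("fig1b_frame")
      atlas <- region_atlas(frame$m1, frame$m3, frame$m4,
                            m2_range = ov("m2_range", c(1, 45)),
                            m5_range = ov("m5_range", c(0.25, 10)),
                            resolution = ov("resolution", 15),
                            resolve_r4 = ov("resolve_r4", FALSE))
      files <- c(files, write_atlas(atlas, out_dir))
      atlas
    },
    fig8 = {
      design <- sobol_design(n = ov("n", 1024), seed = seed)
      res <- sobol_first_order(design, n_boot = ov("n_boot", 200))
      files <- c(files, sensitivity_report(res, out_dir))
      res
    },
    stop("unknown experiment '", name, "'")
  )
  manifest <- list(experiment = name, seed = seed, overrides = overrides,
                   package_version = as.character(utils::packageVersion("cartnode")),
                   solver = list(rtol = 1e-8, atol_dimensionless = 1e-10,
                                 atol_cells = 1e-2),
                   files = basename(files))
  mf <- file.path(out_dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(list(result = result, files = c(files, mf)))
}
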