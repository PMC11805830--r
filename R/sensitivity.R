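#' Sobol sensitivity design
#'
#' Design for the variance-based first-order sensitivity of the model
#' outputs \eqn{C(t)} and \eqn{L(t)} to the four poorly known parameters
#' (`alpha`, `G`, `gamma`, `H`) over the first year after infusion.  The
#' remaining parameters are held at their study values
#' (`rho = 0.02`, `beta = 0.8`, `tau_C = 7`, `sigma = 2e5`).  `alpha`, `G`
#' and `H` are sampled log-uniformly over their multi-decade plausibility
#' ranges; `gamma` (whose range starts at 0) uniformly.
#'
#' @param n Base sample size N (the design has `n * (k + 2)` model runs,
#'   k = 4).  A warning is issued when `n` is not a power of two (sample
#'   balance), but the design still runs.
#' @param seed Integer seed controlling the whole design.
#' @param state0 Initial state `c(C, L)` in cells.
#' @param times Output times in days (within the first year).
#' @param fixed Named list overriding the fixed parameters.
#' @param ranges Named list overriding the varied ranges (each
#'   `c(lower, upper)`); defaults from [table1_ranges()].
#' @return A list of class `sobol_design`: `varied` (ranges and
#'   distributions), `fixed`, `state0`, `times`, `n`, `seed`, and the
#'   sampled matrices `A`, `B`, `AB` (list over parameters).
#' @export
sobol_design <- function(n = 1024, seed = 1, state0 = c(C = 1e7, L = 1e8),
                         times = seq(30, 360, by = 30), fixed = list(),
                         ranges = list()) {
  if (n <= 0) stop("n must be positive")
  if (bitwAnd(n, n - 1L) != 0)
    warning("base sample size n is not a power of two; ",
            "sample balance is better when it is")
  if (any(times < 0) || any(times > 365))
    stop("output times must lie in [0, 365] days")
  tab <- table1_ranges()
  varied <- list(alpha = list(range = tab$alpha, dist = "loguniform"),
                 G     = list(range = tab$G,     dist = "loguniform"),
                 gamma = list(range = tab$gamma, dist = "uniform"),
                 H     = list(range = tab$H,     dist = "loguniform"))
  for (nm in names(ranges)) {
    if (!nm %in% names(varied)) stop("unknown varied parameter: ", nm)
    stopifnot(ranges[[nm]][1] >= tab[[nm]][1],
              ranges[[nm]][2] <= tab[[nm]][2])
    varied[[nm]]$range <- ranges[[nm]]
  }
  fx <- list(rho = 0.02, beta = 0.8, tau_C = 7, sigma = 2e5)
  fx[names(fixed)] <- fixed
  k <- length(varied)
  set.seed(seed)
  U_A <- matrix(stats::runif(n * k), n, k)
  U_B <- matrix(stats::runif(n * k), n, k)
  transform <- function(U) {
    out <- U
    for (j in seq_len(k)) {
      r <- varied[[j]]$range
      out[, j] <- if (varied[[j]]$dist == "loguniform") {
        exp(log(r[1]) + U[, j] * (log(r[2]) - log(r[1])))
      } else {
        r[1] + U[, j] * (r[2] - r[1])
      }
    }
    colnames(out) <- names(varied)
    out
  }
  A <- transform(U_A)
  B <- transform(U_B)
  AB <- lapply(seq_len(k), function(j) {
    U <- U_A; U[, j] <- U_B[, j]; transform(U)
  })
  names(AB) <- names(varied)
  structure(list(varied = varied, fixed = fx, state0 = state0,
                 times = times, n = n, seed = seed,
                 A = A, B = B, AB = AB),
            class = "sobol_design")
}

# evaluate the model at one sampled parameter row -> c(C(times), L(times)),
# capped at the escape bound
sobol_model_eval <- function(row, design) {
  fx <- design$fixed
  p <- dimensional_params(sigma = fx$sigma, beta = fx$beta, H = row[["H"]],
                          gamma = row[["gamma"]], G = row[["G"]],
                          tau_C = fx$tau_C, rho = fx$rho,
                          alpha = row[["alpha"]])
  tr <- tryCatch(integrate_model(p, design$state0,
                                 times = c(0, design$times)),
                 error = function(e) NULL)
  if (is.null(tr))
    return(c(C = rep(NA_real_, length(design$times)),
             L = rep(NA_real_, length(design$times))))
  i <- match(design$times, tr$times)
  c(C = tr$C[i], L = tr$L[i])
}

#' First-order Sobol indices of the model outputs
#'
#' Saltelli-style estimator: with model values \eqn{f_A}, \eqn{f_B} on the
#' two base matrices and \eqn{f_{AB^{(i)}}} on A with column i taken from
#' B, \eqn{S_1^{(i)} = \mathrm{mean}(f_B (f_{AB^{(i)}} - f_A)) /
#' \mathrm{Var}(f_{A \cup B})}.  Bootstrap confidence intervals are
#' computed by resampling design rows.  Runs whose tumor output exceeds
#' the escape bound (\eqn{10^5 H} cells) are capped at the bound rather
#' than discarded, keeping the design balanced; the capped fraction is
#' reported.
#'
#' @param design A `sobol_design`.
#' @param model Evaluation function `(row, design) -> named outputs`;
#'   the default integrates the lymph-node model.  Replaceable so closed
#'   -form test functions can be used to validate the estimator.
#' @param n_boot Bootstrap replicates for the confidence intervals.
#' @param conf Confidence level.
#' @return A list of class `sobol_result`: `S1` (data frame `parameter`,
#'   `output`, `time`, `S1`, `CI_low`, `CI_high`), `capped_fraction`,
#'   `n`, `seed`, `times`.
#' @export
sobol_first_order <- function(design, model = sobol_model_eval,
                              n_boot = 200, conf = 0.95) {
  stopifnot(inherits(design, "sobol_design"))
  k <- length(design$varied)
  n <- design$n
  eval_matrix <- function(M) {
    res <- apply(M, 1, function(r) model(r, design))
    if (is.null(dim(res))) {
      # single-output model: apply returns a plain vector
      nm <- names(model(M[1, ], design))
      matrix(res, ncol = 1, dimnames = list(NULL, nm))
    } else {
      t(res)
    }
  }
  fA <- eval_matrix(design$A)
  fB <- eval_matrix(design$B)
  fAB <- lapply(design$AB, eval_matrix)
  n_outputs <- ncol(fA)
  bad <- !is.finite(fA) | !is.finite(fB)
  for (M in fAB) bad <- bad | !is.finite(M)
  if (mean(bad) > 0.01)
    stop("more than 1% of model evaluations are non-finite (",
         signif(100 * mean(bad), 3), "%)")
  # cap tumor outputs at the escape bound (tumor columns are the L block)
  cap <- 1e5 * max(vapply(list(design$A, design$B), function(M)
    max(M[, "H"]), numeric(1)))
  n_capped <- 0
  cap_mat <- function(M) {
    over <- M > cap
    n_capped <<- n_capped + sum(over, na.rm = TRUE)
    M[over] <- cap
    M
  }
  fA <- cap_mat(fA); fB <- cap_mat(fB); fAB <- lapply(fAB, cap_mat)
  total_evals <- n * (k + 2) * n_outputs
  good <- which(!apply(bad, 1, any))

  s1_est <- function(idx) {
    sapply(seq_len(n_outputs), function(j) {
      V <- stats::var(c(fA[idx, j], fB[idx, j]))
      vapply(seq_len(k), function(i) {
        if (V == 0) return(0)
        mean(fB[idx, j] * (fAB[[i]][idx, j] - fA[idx, j])) / V
      }, numeric(1))
    })  # k x n_outputs
  }
  S1 <- s1_est(good)
  boot <- array(NA_real_, dim = c(k, n_outputs, n_boot))
  for (b in seq_len(n_boot)) {
    boot[, , b] <- s1_est(sample(good, length(good), replace = TRUE))
  }
  alpha2 <- (1 - conf) / 2
  out_names <- colnames(fA)
  rows <- list()
  for (j in seq_len(n_outputs)) {
    nm <- if (is.null(out_names)) paste0("y", j) else out_names[j]
    output <- sub("[0-9]+$", "", nm)
    t_idx <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", nm)))
    for (i in seq_len(k)) {
      ci <- stats::quantile(boot[i, j, ], c(alpha2, 1 - alpha2),
                            na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = names(design$varied)[i], output = output,
        time = design$times[t_idx], S1 = S1[i, j],
        CI_low = ci[1], CI_high = ci[2], row.names = NULL)
    }
  }
  structure(list(S1 = do.call(rbind, rows),
                 capped_fraction = n_capped / total_evals,
                 n = n, seed = design$seed, times = design$times),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat(sprintf("Sobol first-order indices (N = %d, seed = %d, %.2g%% capped runs)\n",
              x$n, x$seed, 100 * x$capped_fraction))
  agg <- stats::aggregate(S1 ~ parameter + output, data = x$S1, FUN = mean)
  print(agg)
  invisible(x)
}

#' Serialize a Sobol result
#'
#' Writes the tidy index table (`parameter`, `output`, `time`, `S1`,
#' `CI_low`, `CI_high`) as CSV and a metadata JSON (seed, N, capped-run
#' fraction).
#'
#' @param result A `sobol_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
sensitivity_report <- function(result, dir) {
  stopifnot(inherits(result, "sobol_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "sobol_first_order.csv")
  utils::write.csv(result$S1, csv, row.names = FALSE)
  meta <- file.path(dir, "sobol_metadata.json")
  jsonlite::write_json(list(n = result$n, seed = result$seed,
                            times_days = result$times,
                            capped_fraction = result$capped_fraction),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}
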