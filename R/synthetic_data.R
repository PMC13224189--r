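# Seeded generators emulating a solvatochromic titration study: exchange
# model forward curves over ~11-point composition grids with Gaussian noise
# on E_T, and KAT descriptor panels with energies from a known linear
# relation. Everything is bit-reproducible for a fixed seed.

#' Noise specification for the synthetic generators
#'
#' @param sigma Gaussian standard deviation on E_T, kcal/mol, nonnegative.
#'   The default 0.05 is roughly the E_T jitter implied by a +-0.5 nm
#'   reading uncertainty on a band near 430 nm.
#' @param seed Integer seed; identical seed and spec give identical output.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0.05, seed = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single nonnegative number (kcal/mol)",
         call. = FALSE)
  }
  structure(list(sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a titration series from the solvent-exchange model
#'
#' Evaluates [exchange_model_energy()] on a composition grid and adds iid
#' Gaussian noise on E_T. With `sigma = 0` the exact model curve is
#' returned. The default 11-point grid mimics the usual volumetric
#' titration series.
#'
#' @param params An [exchange_params()] truth.
#' @param grid Mole fractions of the cosolvent, at least 4 distinct values
#'   in \[0, 1\].
#' @param noise A [noise_spec()].
#' @param mixture_name Label stored on the series.
#' @return A [titration_series()].
#' @export
simulate_exchange_series <- function(params, grid = seq(0, 1, by = 0.1),
                                     noise = noise_spec(),
                                     mixture_name = "simulated") {
  stopifnot(inherits(params, "exchange_params"),
            inherits(noise, "noise_spec"))
  check_mole_fraction(grid, "grid")
  if (length(grid) < 4 || anyDuplicated(grid)) {
    stop("`grid` needs at least 4 distinct mole fractions", call. = FALSE)
  }
  grid <- sort(grid)
  et <- exchange_model_energy(grid, params)
  if (noise$sigma > 0) {
    et <- et + withr::with_seed(noise$seed,
                                stats::rnorm(length(grid), 0, noise$sigma))
  }
  titration_series(grid, et, mixture_name = mixture_name,
                   et1_pure = params$et1, et2_pure = params$et2)
}

#' Simulate a KAT solvent panel from known coefficients
#'
#' Draws descriptor triples uniformly (seeded) from the given ranges,
#' computes energies from \eqn{E_T = E_T^0 + a\pi^* + b\alpha + c\beta}
#' plus Gaussian noise, and guarantees a full-rank design by rejection
#' resampling (at most 100 attempts).
#'
#' @param coefficients Numeric vector `c(et0, a, b, c)`.
#' @param n_solvents Panel size, at least 4.
#' @param ranges List of length-2 ranges for `pi_star`, `alpha`, `beta`.
#'   Defaults span the usual tabulated KAT values.
#' @param noise A [noise_spec()].
#' @return List with `energies` (kcal/mol) and `descriptors` (data frame
#'   with columns `name`, `pi_star`, `alpha`, `beta`).
#' @export
simulate_lser_panel <- function(coefficients, n_solvents = 10,
                                ranges = list(pi_star = c(0, 1.1),
                                              alpha = c(0, 1.2),
                                              beta = c(0, 1)),
                                noise = noise_spec()) {
  stopifnot(is.numeric(coefficients), length(coefficients) == 4,
            inherits(noise, "noise_spec"))
  if (n_solvents < 4) {
    stop("`n_solvents` must be at least 4", call. = FALSE)
  }
  for (r in ranges) {
    if (length(r) != 2 || diff(r) <= 0) {
      stop("each descriptor range must be a nondegenerate interval",
           call. = FALSE)
    }
  }
  draw <- withr::with_seed(noise$seed, {
    for (attempt in 1:100) {
      d <- data.frame(
        pi_star = stats::runif(n_solvents, ranges$pi_star[1], ranges$pi_star[2]),
        alpha = stats::runif(n_solvents, ranges$alpha[1], ranges$alpha[2]),
        beta = stats::runif(n_solvents, ranges$beta[1], ranges$beta[2])
      )
      if (qr(cbind(1, as.matrix(d)))$rank == 4) break
      d <- NULL
    }
    eps <- if (noise$sigma > 0) stats::rnorm(n_solvents, 0, noise$sigma) else 0
    list(d = d, eps = eps)
  })
  if (is.null(draw$d)) {
    stop("failed to draw a full-rank descriptor panel in 100 attempts",
         call. = FALSE)
  }
  d <- draw$d
  energies <- coefficients[1] + coefficients[2] * d$pi_star +
    coefficients[3] * d$alpha + coefficients[4] * d$beta + draw$eps
  d <- cbind(name = sprintf("synthetic_%02d", seq_len(n_solvents)), d)
  list(energies = energies, descriptors = d)
}

#' Library of solvent-exchange scenarios
#'
#' Named [exchange_params()] sets for eight binary mixtures of an
#' isoquinolinium zwitterion indicator, spanning the isotherm shapes a
#' titration study encounters (near-ideal, concave, hyperbolic, sigmoid)
#' and both model variants. These serve as generating truths for
#' simulation and round-trip tests.
#'
#' @return Named list of [exchange_params()].
#' @examples
#' names(scenario_library())
#' scenario_library()[["Benzene + MeOH"]]
#' @export
scenario_library <- function() {
  list(
    "Water + MeOH" = exchange_params(68.5, 69.05, 68.91, 0.39, 1.55, m = 2),
    "Water + EtOH" = exchange_params(67.73, 69.05, 67.99, 0.74, 1.69, m = 2),
    "DMSO + MeOH" = exchange_params(64.22, 68.5, 68.1, 0.83, 1.69, m = 2,
                                    k = -0.0006, variant = "corrected"),
    "Benzene + MeOH" = exchange_params(60.68, 68.7, 63.58, 2.17, 1.41, m = 2),
    "DMF + MeOH" = exchange_params(63.53, 68.47, 68.33, 0.41, 1.29, m = 2),
    "DCE + Oct" = exchange_params(62.53, 63.72, 66.71, 0.58, 0.91, m = 2,
                                  k = -5.69, variant = "corrected"),
    "DMF + PropDiol" = exchange_params(63.32, 68.77, 68.13, 0.11, 3.50, m = 2,
                                       k = 0.0015, variant = "corrected"),
    "Diox + EG" = exchange_params(60.84, 68.75, 64.77, 0.29, 2.19, m = 3)
  )
}
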