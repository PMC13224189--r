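# Conversion constant between absorption maximum (nm) and molar transition
# energy (kcal/mol): E_T = 28590 / lambda_max. Fixed at the conventional
# printed value; no CODATA-refined alternative is offered, so that outputs
# stay comparable with the solvatochromic literature.
ET_LAMBDA_CONSTANT <- 28590

#' Convert an absorption maximum to a molar transition energy
#'
#' The molar transition energy of a solvatochromic band is
#' \eqn{E_T\ \mathrm{(kcal/mol)} = 28590 / \lambda_{max}\ \mathrm{(nm)}}.
#'
#' @param lambda_max Absorption maximum in nm. Must be positive. Vectorized.
#' @return Molar transition energy in kcal/mol.
#' @seealso [transition_energy_to_lambda()] for the inverse.
#' @examples
#' lambda_to_transition_energy(414) # pure water, ~69.06 kcal/mol
#' @export
lambda_to_transition_energy <- function(lambda_max) {
  stopifnot(is.numeric(lambda_max))
  if (any(!is.finite(lambda_max)) || any(lambda_max <= 0)) {
    stop("`lambda_max` must be finite and positive (nm)", call. = FALSE)
  }
  ET_LAMBDA_CONSTANT / lambda_max
}

#' Convert a molar transition energy to an absorption maximum
#'
#' Inverse of [lambda_to_transition_energy()]: \eqn{\lambda_{max} = 28590 / E_T}.
#'
#' @param et Molar transition energy in kcal/mol. Must be positive. Vectorized.
#' @return Absorption maximum in nm.
#' @export
transition_energy_to_lambda <- function(et) {
  stopifnot(is.numeric(et))
  if (any(!is.finite(et)) || any(et <= 0)) {
    stop("`et` must be finite and positive (kcal/mol)", call. = FALSE)
  }
  ET_LAMBDA_CONSTANT / et
}

#' Transition energy of an ideal (linearly mixing) binary solvent
#'
#' Reference line against which preferential solvation is judged: the mole
#' fraction weighted mean of the two pure-solvent energies,
#' \eqn{E_T^{id}(x_2) = (1 - x_2) E_{T1} + x_2 E_{T2}}.
#'
#' @param x2 Bulk mole fraction of cosolvent S2, in \[0, 1\]. Vectorized.
#' @param et1,et2 Pure-solvent transition energies (kcal/mol) of the base
#'   solvent S1 and cosolvent S2.
#' @return Ideal-mixture transition energy in kcal/mol.
#' @export
ideal_mixture_energy <- function(x2, et1, et2) {
  check_mole_fraction(x2)
  (1 - x2) * et1 + x2 * et2
}

#' Deviation of a measured energy from the ideal mixing line
#'
#' \eqn{\Delta E_T = E_{T,exp} - E_{T,calc}}; negative values mean the
#' measured band lies below the ideal line.
#'
#' @param et_obs Observed transition energy (kcal/mol).
#' @inheritParams ideal_mixture_energy
#' @return Signed deviation in kcal/mol.
#' @export
deviation_from_ideal <- function(et_obs, x2, et1, et2) {
  et_obs - ideal_mixture_energy(x2, et1, et2)
}

check_mole_fraction <- function(x2, arg = "x2") {
  stopifnot(is.numeric(x2))
  if (any(!is.finite(x2)) || any(x2 < 0) || any(x2 > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", arg), call. = FALSE)
  }
  invisible(x2)
}

#' Solvent descriptor record
#'
#' Bundles one solvent's Kamlet-Abboud-Taft descriptors: pi* (dipolarity/
#' polarizability), alpha (hydrogen-bond donor acidity) and beta
#' (hydrogen-bond acceptor basicity), optionally with the relative
#' permittivity and a reference polarity value.
#'
#' @param name Solvent label (nonempty string).
#' @param pi_star,alpha,beta KAT descriptors, dimensionless; `alpha` and
#'   `beta` must be nonnegative.
#' @param epsilon_r Optional relative permittivity.
#' @param et30 Optional reference polarity value, kcal/mol.
#' @return An object of class `solvent_descriptor`.
#' @export
solvent_descriptor <- function(name, pi_star, alpha, beta,
                               epsilon_r = NA_real_, et30 = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a nonempty string", call. = FALSE)
  }
  vals <- c(pi_star = pi_star, alpha = alpha, beta = beta)
  if (any(!is.finite(vals))) {
    stop("`pi_star`, `alpha`, `beta` must all be finite", call. = FALSE)
  }
  if (alpha < 0 || beta < 0) {
    stop("`alpha` and `beta` must be nonnegative", call. = FALSE)
  }
  structure(
    list(name = name, pi_star = pi_star, alpha = alpha, beta = beta,
         epsilon_r = epsilon_r, et30 = et30),
    class = "solvent_descriptor"
  )
}

#' @export
print.solvent_descriptor <- function(x, ...) {
  cat(sprintf("<solvent_descriptor> %s: pi* = %.3g, alpha = %.3g, beta = %.3g\n",
              x$name, x$pi_star, x$alpha, x$beta))
  invisible(x)
}

#' Titration series of a solvatochromic indicator in a binary mixture
#'
#' Holds the measured (x2, E_T) points of one binary-mixture titration,
#' sorted by increasing bulk mole fraction of the cosolvent S2. Pure-solvent
#' energies may be supplied explicitly; otherwise endpoint rows at x2 = 0 and
#' x2 = 1 (when present) play that role downstream.
#'
#' @param x2 Bulk mole fractions of cosolvent S2, each in \[0, 1\]; must be
#'   distinct.
#' @param et Molar transition energies, kcal/mol, all positive.
#' @param mixture_name Label for the mixture (e.g. `"Water + MeOH"`).
#' @param et1_pure,et2_pure Optional measured pure-solvent energies
#'   (kcal/mol) for S1 and S2.
#' @return An object of class `titration_series`: a data frame with columns
#'   `x2` and `et` plus metadata attributes.
#' @export
titration_series <- function(x2, et, mixture_name = "mixture",
                             et1_pure = NA_real_, et2_pure = NA_real_) {
  stopifnot(is.numeric(x2), is.numeric(et))
  if (length(x2) != length(et)) {
    stop("`x2` and `et` must have the same length", call. = FALSE)
  }
  check_mole_fraction(x2)
  if (any(!is.finite(et)) || any(et <= 0)) {
    stop("every `et` must be finite and positive (kcal/mol)", call. = FALSE)
  }
  ord <- order(x2)
  x2 <- x2[ord]; et <- et[ord]
  if (any(diff(x2) <= 0)) {
    stop("`x2` values must be distinct", call. = FALSE)
  }
  structure(
    data.frame(x2 = x2, et = et),
    mixture_name = mixture_name,
    et1_pure = et1_pure,
    et2_pure = et2_pure,
    class = c("titration_series", "data.frame")
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s: %d points, x2 in [%.3g, %.3g]\n",
              attr(x, "mixture_name"), nrow(x), min(x$x2), max(x$x2)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Endpoint energies of a titration series
#'
#' Returns the pure-solvent energies (E_T1, E_T2) of a series: the declared
#' `et1_pure`/`et2_pure` when present, otherwise the measured values at
#' x2 = 0 and x2 = 1.
#'
#' @param series A [titration_series()].
#' @return Named numeric vector `c(et1 = , et2 = )`.
#' @export
series_endpoints <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  et1 <- attr(series, "et1_pure")
  et2 <- attr(series, "et2_pure")
  if (!is.finite(et1)) {
    i <- which(series$x2 == 0)
    et1 <- if (length(i)) series$et[i[1]] else NA_real_
  }
  if (!is.finite(et2)) {
    i <- which(series$x2 == 1)
    et2 <- if (length(i)) series$et[i[1]] else NA_real_
  }
  if (!is.finite(et1) || !is.finite(et2)) {
    stop("endpoint energies unavailable: supply `et1_pure`/`et2_pure` or ",
         "include measurements at x2 = 0 and x2 = 1", call. = FALSE)
  }
  c(et1 = et1, et2 = et2)
}
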