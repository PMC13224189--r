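# Two-step solvent-exchange model (Bosch-Roses / Skwierczynski-Connors).
# The solute's first shell holds either base solvent S1, cosolvent S2, or the
# 1:1 intersolvent complex S12; the exchange equilibria are parameterized by
# f2/1 and f12/1 and an exchange order m, giving local shell fractions
#   x1s : x2s : x12s  =  (1-x2)^m : f2/1 x2^m : f12/1 (x2(1-x2))^(m/2)
# and E_T = E_T1 x1s + E_T2 x2s + E_T12 x12s (+ a water-structure correction
# in the "corrected" variant).

#' Solvent-exchange model parameter set
#'
#' Parameters of the two-step solvent-exchange model of preferential
#' solvation. `variant = "general"` is the plain weighted-mean model of
#' arbitrary exchange order m; `variant = "corrected"` is the m = 2 model
#' augmented with the water-structure correction term with proportionality
#' constant `k`, describing structured water (or base solvent) at low
#' cosolvent content.
#'
#' @param et1,et2,et12 Transition energies (kcal/mol) of the solute solvated
#'   purely by S1, by S2, and by the S12 intersolvent complex.
#' @param f2_1,f12_1 Preference of the solute's shell for S2 and for the S12
#'   complex, relative to S1. Nonnegative; `f2_1 = 1, f12_1 = 0` means no
#'   preference and no complex.
#' @param m Exchange order (number of exchanged solvent molecules), positive.
#'   Must equal 2 for `variant = "corrected"`.
#' @param k Water-structure correction constant (kcal/mol); required for, and
#'   only allowed with, `variant = "corrected"`.
#' @param variant `"general"` or `"corrected"`.
#' @return An object of class `exchange_params`.
#' @examples
#' exchange_params(60.68, 68.7, 63.58, f2_1 = 2.17, f12_1 = 1.41, m = 2)
#' @export
exchange_params <- function(et1, et2, et12, f2_1, f12_1, m = 2,
                            k = NULL, variant = c("general", "corrected")) {
  variant <- match.arg(variant)
  vals <- c(et1 = et1, et2 = et2, et12 = et12, f2_1 = f2_1, f12_1 = f12_1,
            m = m)
  if (any(!is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (f2_1 < 0 || f12_1 < 0) {
    stop("`f2_1` and `f12_1` must be nonnegative", call. = FALSE)
  }
  if (m <= 0) stop("`m` must be positive", call. = FALSE)
  if (variant == "corrected") {
    if (is.null(k) || !is.finite(k)) {
      stop("`variant = \"corrected\"` requires a finite `k`", call. = FALSE)
    }
    if (m != 2) {
      stop("the corrected variant is defined for m = 2 only", call. = FALSE)
    }
  } else if (!is.null(k)) {
    stop("`k` is only meaningful for `variant = \"corrected\"`", call. = FALSE)
  }
  structure(
    list(et1 = et1, et2 = et2, et12 = et12, f2_1 = f2_1, f12_1 = f12_1,
         m = m, k = if (variant == "corrected") k else NULL,
         variant = variant),
    class = "exchange_params"
  )
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf("<exchange_params> variant = %s, m = %g\n", x$variant, x$m))
  cat(sprintf("  E_T1 = %.4g  E_T2 = %.4g  E_T12 = %.4g kcal/mol\n",
              x$et1, x$et2, x$et12))
  cat(sprintf("  f2/1 = %.4g  f12/1 = %.4g%s\n", x$f2_1, x$f12_1,
              if (!is.null(x$k)) sprintf("  k = %.4g kcal/mol", x$k) else ""))
  invisible(x)
}

# Unvalidated evaluator used inside the least-squares loop (and by its
# finite-difference Jacobian, whose probes may step just past the bounds).
# `p12` is the cross-term exponent. Endpoint limits as in the public path.
exchange_energy_raw <- function(x2, et1, et2, et12, f2_1, f12_1, m, p12,
                                k = NULL) {
  w1 <- (1 - x2)^m
  w2 <- f2_1 * x2^m
  w12 <- f12_1 * (x2 * (1 - x2))^p12
  et <- (et1 * w1 + et2 * w2 + et12 * w12) / (w1 + w2 + w12)
  if (!is.null(k)) {
    num <- k * f2_1 * x2^2 * ((1 - x2)^2 + f12_1 * (1 - x2) * x2 / 2)
    den <- ((1 - x2)^2 + f2_1 * x2^2 + f12_1 * x2 * (1 - x2))^2
    corr <- num / den
    corr[x2 %in% c(0, 1)] <- 0
    et <- et + corr
  }
  et[x2 == 0] <- et1
  et[x2 == 1] <- et2
  et
}

# Unnormalized shell weights. `cross_term = "half"` uses exponent m/2 on the
# cross term (the Bosch-Roses form, consistent with the m = 2 special case);
# "as_printed" uses exponent m literally. Identical at m = 2.
exchange_weights <- function(x2, params, cross_term = c("half", "as_printed")) {
  cross_term <- match.arg(cross_term)
  m <- params$m
  p12 <- if (cross_term == "half") m / 2 else m
  w1 <- (1 - x2)^m
  w2 <- params$f2_1 * x2^m
  w12 <- params$f12_1 * (x2 * (1 - x2))^p12
  cbind(w1 = w1, w2 = w2, w12 = w12)
}

#' Local mole fractions in the first solvation shell
#'
#' Evaluates the exchange model's shell composition at a bulk composition:
#' the fractions of solute molecules solvated by S1, S2 and the S12 complex.
#' They are normalized weights
#' \eqn{(1-x_2)^m : f_{2/1} x_2^m : f_{12/1}(x_2(1-x_2))^{m/2}} and sum to 1.
#'
#' @param x2 Bulk mole fraction(s) of cosolvent S2, in \[0, 1\]. Vectorized.
#' @param params An [exchange_params()] object.
#' @param cross_term Exponent convention for the S12 cross term: `"half"`
#'   (default; exponent m/2, the form whose m = 2 case has exponent 1) or
#'   `"as_printed"` (exponent m).
#' @return A data frame with columns `x2`, `x1s`, `x2s`, `x12s`.
#' @export
local_shell_fractions <- function(x2, params,
                                  cross_term = c("half", "as_printed")) {
  stopifnot(inherits(params, "exchange_params"))
  check_mole_fraction(x2)
  w <- exchange_weights(x2, params, cross_term)
  tot <- rowSums(w)
  # limits at exact endpoints: shell is pure S1 at x2 = 0, pure S2 at x2 = 1
  frac <- w / tot
  frac[x2 == 0, ] <- rep(c(1, 0, 0), each = sum(x2 == 0))
  frac[x2 == 1, ] <- rep(c(0, 1, 0), each = sum(x2 == 1))
  if (any(tot == 0 & x2 > 0 & x2 < 1)) {
    stop("degenerate shell weights at interior composition", call. = FALSE)
  }
  data.frame(x2 = x2, x1s = frac[, "w1"], x2s = frac[, "w2"],
             x12s = frac[, "w12"])
}

#' Water-structure correction term of the corrected exchange model
#'
#' The corrected variant adds \eqn{\Delta E_T} to the weighted-mean energy,
#' accounting for the enhancement of the structured base solvent (typically
#' water) at low cosolvent concentrations:
#' \deqn{\Delta E_T = \frac{k f_{2/1} x_2^2 \left[(1-x_2)^2 +
#'   f_{12/1}(1-x_2)x_2/2\right]}{\left[(1-x_2)^2 + f_{2/1}x_2^2 +
#'   f_{12/1}x_2(1-x_2)\right]^2}}
#' It vanishes at both pure-solvent endpoints.
#'
#' @inheritParams local_shell_fractions
#' @return Correction energy in kcal/mol (vector along `x2`).
#' @export
water_structure_correction <- function(x2, params) {
  stopifnot(inherits(params, "exchange_params"))
  if (params$variant != "corrected") {
    stop("correction term is defined only for `variant = \"corrected\"`",
         call. = FALSE)
  }
  check_mole_fraction(x2)
  f2 <- params$f2_1; f12 <- params$f12_1; k <- params$k
  num <- k * f2 * x2^2 * ((1 - x2)^2 + f12 * (1 - x2) * x2 / 2)
  den <- ((1 - x2)^2 + f2 * x2^2 + f12 * x2 * (1 - x2))^2
  out <- num / den
  out[x2 %in% c(0, 1)] <- 0
  out
}

#' Transition energy predicted by the solvent-exchange model
#'
#' Shell-fraction weighted mean of the three solvation-state energies,
#' \eqn{E_T = E_{T1} x_1^s + E_{T2} x_2^s + E_{T12} x_{12}^s}, plus the
#' water-structure correction when `params$variant == "corrected"`. At
#' x2 = 0 and x2 = 1 it returns exactly `et1` and `et2`.
#'
#' @inheritParams local_shell_fractions
#' @return Predicted transition energy in kcal/mol (vector along `x2`).
#' @examples
#' p <- exchange_params(68.5, 69.05, 68.91, f2_1 = 0.39, f12_1 = 1.55, m = 2)
#' exchange_model_energy(c(0, 0.5, 1), p)
#' @export
exchange_model_energy <- function(x2, params,
                                  cross_term = c("half", "as_printed")) {
  fr <- local_shell_fractions(x2, params, cross_term)
  et <- params$et1 * fr$x1s + params$et2 * fr$x2s + params$et12 * fr$x12s
  if (params$variant == "corrected") {
    et <- et + water_structure_correction(x2, params)
  }
  et
}
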