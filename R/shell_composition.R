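# Model-free first-solvation-shell composition. In the simplest two-state
# reading the measured energy is the shell-fraction weighted mean of the
# pure-solvent energies, E_T = E_T1 x1s + E_T2 x2s, so the local cosolvent
# fraction follows by inversion and the preferential solvation parameter is
# delta_s,2 = x2s - x2 (positive: the cosolvent S2 is enriched around the
# solute).

#' Local cosolvent mole fraction from a measured energy (two-state)
#'
#' Inverts \eqn{E_T = E_{T1} x_1^s + E_{T2} x_2^s} with
#' \eqn{x_1^s + x_2^s = 1}: \eqn{x_2^s = (E_T - E_{T1})/(E_{T2} - E_{T1})}.
#' For synergistic mixtures, where the measured energy can fall outside the
#' range spanned by the pure solvents, the result may leave \[0, 1\]; it is
#' returned as-is (see `attr(, "out_of_range")`), never clipped, so
#' synergism stays visible.
#'
#' @param et Measured transition energy(ies), kcal/mol.
#' @param et1,et2 Pure-solvent energies (kcal/mol); must differ.
#' @return Local mole fraction(s) of S2 in the first shell, with attribute
#'   `out_of_range` flagging values outside \[0, 1\].
#' @export
shell_mole_fraction_simple <- function(et, et1, et2) {
  if (!is.finite(et1) || !is.finite(et2) || et1 == et2) {
    stop("degenerate endpoints: `et1` and `et2` must be distinct, finite ",
         "energies (shell composition is unidentifiable otherwise)",
         call. = FALSE)
  }
  x2s <- (et - et1) / (et2 - et1)
  structure(x2s, out_of_range = x2s < 0 | x2s > 1)
}

#' Preferential solvation parameter
#'
#' \eqn{\delta_{s,2} = x_2^s - x_2}: local minus bulk mole fraction of the
#' cosolvent S2. Positive values mean S2 preferentially solvates the
#' indicator; negative values mean the base solvent S1 does.
#'
#' @param x2s Local (shell) mole fraction of S2; values outside \[0, 1\]
#'   (synergistic mixtures) are accepted.
#' @param x2 Bulk mole fraction of S2, in \[0, 1\].
#' @return Dimensionless preference parameter(s).
#' @export
preferential_solvation_parameter <- function(x2s, x2) {
  check_mole_fraction(x2)
  as.numeric(x2s) - x2
}

#' Shell-composition curve of a titration series
#'
#' Applies the two-state inversion at every composition of a series, giving
#' the local cosolvent fraction and \eqn{\delta_{s,2}} per point, plus
#' summary attributes: the composition of the extreme preference
#' (argmax/argmin of \eqn{\delta_{s,2}} over the measured grid), sign
#' crossings, and two excess-energy summaries of the deviation curve
#' \eqn{\Delta E_T(x_2)} (its signed extremum and its trapezoidal integral
#' over \[0, 1\]).
#'
#' @param series A [titration_series()]; endpoint energies must be available
#'   (declared, or measured at x2 = 0 and 1).
#' @return A data frame of class `shell_series` with columns `x2`, `et`,
#'   `x2s`, `delta_s2`, `out_of_range`, and attributes `delta_max`,
#'   `delta_min` (each a named vector `c(x2 = , delta_s2 = )`),
#'   `sign_crossings` (compositions where the interior
#'   \eqn{\delta_{s,2}} changes sign, by linear interpolation),
#'   `excess_extremum` and `excess_integral` (kcal/mol).
#' @export
shell_series <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  ends <- series_endpoints(series)
  x2s <- shell_mole_fraction_simple(series$et, ends["et1"], ends["et2"])
  delta <- preferential_solvation_parameter(x2s, series$x2)
  d_et <- deviation_from_ideal(series$et, series$x2, ends["et1"], ends["et2"])

  i_max <- which.max(delta)
  i_min <- which.min(delta)
  interior <- series$x2 > 0 & series$x2 < 1
  crossings <- numeric(0)
  xi <- series$x2[interior]; di <- delta[interior]
  if (length(di) > 1) {
    s <- sign(di)
    flip <- which(s[-1] * s[-length(s)] < 0)
    crossings <- xi[flip] + (xi[flip + 1] - xi[flip]) *
      abs(di[flip]) / (abs(di[flip]) + abs(di[flip + 1]))
  }
  i_ext <- which.max(abs(d_et))

  structure(
    data.frame(x2 = series$x2, et = series$et,
               x2s = as.numeric(x2s), delta_s2 = delta,
               out_of_range = attr(x2s, "out_of_range")),
    delta_max = c(x2 = series$x2[i_max], delta_s2 = delta[i_max]),
    delta_min = c(x2 = series$x2[i_min], delta_s2 = delta[i_min]),
    sign_crossings = crossings,
    excess_extremum = unname(d_et[i_ext]),
    excess_integral = trapezoid(series$x2, d_et),
    mixture_name = attr(series, "mixture_name"),
    class = c("shell_series", "data.frame")
  )
}

trapezoid <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' @export
print.shell_series <- function(x, ...) {
  cat(sprintf("<shell_series> %s: %d points\n",
              attr(x, "mixture_name"), nrow(x)))
  dm <- attr(x, "delta_max"); dn <- attr(x, "delta_min")
  cat(sprintf("  delta_s2 max %+.3f at x2 = %.2f; min %+.3f at x2 = %.2f\n",
              dm["delta_s2"], dm["x2"], dn["delta_s2"], dn["x2"]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a shell-composition table
#'
#' Emits the per-mixture table (x2, x2s, delta_s2) as delimited text, the
#' format consumed by [fit_cell_model()] workflows.
#'
#' @param shell A [shell_series()] result.
#' @param path Output file path.
#' @export
write_shell_table <- function(shell, path) {
  stopifnot(inherits(shell, "shell_series"))
  utils::write.csv(shell[, c("x2", "x2s", "delta_s2")], path,
                   row.names = FALSE)
  invisible(path)
}
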