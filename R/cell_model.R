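# Statistical cell model of ternary solutions: a lattice-like model in which
# the shell log-odds of the cosolvent depend linearly on the bulk log-ratio,
#   ln(x2s / (1 - x2s)) = m ln(x2 / x1) + (omega1 - omega2) / (kB T),
# so the intercept measures the difference between the solute-S1 and
# solute-S2 pair interaction energies in units of kB T.

BOLTZMANN_J_PER_K <- 1.380649e-23

#' Fit the statistical cell model to a shell-composition curve
#'
#' Ordinary least squares of the shell log-odds
#' \eqn{\ln(x_2^s/(1-x_2^s))} on the bulk log-ratio \eqn{\ln(x_2/x_1)}.
#' The slope recovers the exchange order and the intercept gives
#' \eqn{(\omega_1-\omega_2)/k_B T}, the solute-solvent interaction-energy
#' difference in thermal units. Only interior points (both fractions
#' strictly inside (0, 1)) enter the regression; boundary points, where the
#' log transform is undefined, are dropped with a warning rather than
#' clipped.
#'
#' For exchange-model data without the intersolvent complex
#' (\eqn{f_{12/1}=0}) the relation is exact: slope = m, intercept =
#' \eqn{\ln f_{2/1}}.
#'
#' @param x2 Bulk mole fractions of S2.
#' @param x2s Local (shell) mole fractions of S2, e.g. the `x2s` column of a
#'   [shell_series()] table. Alternatively pass a `shell_series` object as
#'   `x2` and omit `x2s`.
#' @param temperature Absolute temperature in kelvin; default 295.15 K
#'   (ambient, 22 degrees C).
#' @param ratio `"odds"` (default) regresses \eqn{\ln(x_2^s/(1-x_2^s))};
#'   `"s1"` regresses \eqn{\ln(x_2^s/x_1^s)} and then requires `x1s`.
#' @param x1s Local S1 fractions, only for `ratio = "s1"` (from a full
#'   three-state [local_shell_fractions()] composition).
#' @return An object of class `cell_model_fit`: list with `slope`,
#'   `intercept` (dimensionless), `omega_diff` (joules,
#'   \eqn{\omega_1-\omega_2} = intercept \eqn{\times k_B T}), `temperature`,
#'   `r_squared`, `n_points`, `n_dropped`, and the underlying `lm`.
#' @export
fit_cell_model <- function(x2, x2s = NULL, temperature = 295.15,
                           ratio = c("odds", "s1"), x1s = NULL) {
  ratio <- match.arg(ratio)
  if (inherits(x2, "shell_series")) {
    x2s <- x2$x2s
    x2 <- x2$x2
  }
  stopifnot(is.numeric(x2), is.numeric(x2s), length(x2) == length(x2s))
  if (!is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  }
  denom <- if (ratio == "s1") {
    if (is.null(x1s)) {
      stop("`ratio = \"s1\"` requires `x1s`", call. = FALSE)
    }
    x1s
  } else {
    1 - x2s
  }
  usable <- x2 > 0 & x2 < 1 & x2s > 0 & denom > 0
  n_drop <- sum(!usable)
  if (n_drop > 0) {
    warning(sprintf("%d boundary point(s) dropped (log-odds undefined)",
                    n_drop), call. = FALSE)
  }
  if (sum(usable) < 3) {
    stop("need at least 3 interior points to fit the cell model",
         call. = FALSE)
  }
  lx <- log(x2[usable] / (1 - x2[usable]))
  ly <- log(x2s[usable] / denom[usable])
  mod <- stats::lm(ly ~ lx)
  co <- stats::coef(mod)
  intercept <- unname(co[1])
  structure(
    list(slope = unname(co[2]),
         intercept = intercept,
         omega_diff = intercept * BOLTZMANN_J_PER_K * temperature,
         temperature = temperature,
         r_squared = r_squared_lm(mod),
         n_points = sum(usable),
         n_dropped = n_drop,
         ratio = ratio,
         model = mod),
    class = "cell_model_fit"
  )
}

#' @export
print.cell_model_fit <- function(x, ...) {
  cat(sprintf("<cell_model_fit> slope = %.4f, intercept = %.4f (n = %d, R^2 = %.4f)\n",
              x$slope, x$intercept, x$n_points, x$r_squared))
  cat(sprintf("  omega1 - omega2 = %.3e J (%.3f x 10^-21 J) at T = %.2f K\n",
              x$omega_diff, x$omega_diff * 1e21, x$temperature))
  invisible(x)
}

#' Solute-solvent interaction-energy difference
#'
#' Extracts \eqn{\omega_1 - \omega_2} from a cell-model fit, in SI joules
#' and on the \eqn{10^{-21}} J convenience scale customary for single-pair
#' interaction energies.
#'
#' @param fit A [fit_cell_model()] result.
#' @return Named numeric vector `c(joules = , zeptojoule_scale = )`, where
#'   `zeptojoule_scale` is the value in units of \eqn{10^{-21}} J.
#' @export
interaction_energy_difference <- function(fit) {
  stopifnot(inherits(fit, "cell_model_fit"))
  c(joules = fit$omega_diff, zeptojoule_scale = fit$omega_diff * 1e21)
}
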