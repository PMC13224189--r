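# Kamlet-Abboud-Taft linear solvation energy relationship:
#   E_T = E_T0 + a pi* + b alpha + c beta
# fitted by ordinary least squares over a panel of solvents with known
# descriptors. pi* = dipolarity/polarizability, alpha = H-bond donor
# acidity, beta = H-bond acceptor basicity (universal KAT convention).

#' Fit the Kamlet-Abboud-Taft relation to a solvent panel
#'
#' Ordinary least-squares regression of measured transition energies on the
#' KAT descriptors, \eqn{E_T = E_T^0 + a\,\pi^* + b\,\alpha + c\,\beta}.
#' The intercept \eqn{E_T^0} estimates the transition energy in the absence
#' of solvent effects; positive slopes mean a hypsochromic (blue) shift with
#' that solvent property.
#'
#' @param energies Measured transition energies, kcal/mol, one per solvent.
#' @param descriptors A list of [solvent_descriptor()] objects, or a data
#'   frame with columns `pi_star`, `alpha`, `beta` (and optionally `name`).
#' @return An object of class `kat_fit`: list with `et0`, `a`, `b`, `c`,
#'   `r_squared`, `residuals`, `n_solvents`, and the underlying `lm` object.
#' @examples
#' panel <- simulate_lser_panel(c(59.08, 6.16, 7.19, -1.75), n_solvents = 10,
#'                              noise = noise_spec(0, 7))
#' fit_kat(panel$energies, panel$descriptors)
#' @export
fit_kat <- function(energies, descriptors) {
  df <- as_descriptor_frame(descriptors)
  if (length(energies) != nrow(df)) {
    stop("`energies` and `descriptors` must have the same length",
         call. = FALSE)
  }
  if (length(energies) < 4) {
    stop("at least 4 solvents are needed to fit the 4 KAT coefficients",
         call. = FALSE)
  }
  X <- cbind(1, df$pi_star, df$alpha, df$beta)
  qrX <- qr(X)
  if (qrX$rank < 4) {
    cols <- c("intercept", "pi_star", "alpha", "beta")
    dropped <- cols[setdiff(seq_len(4), qrX$pivot[seq_len(qrX$rank)])]
    stop("singular descriptor design: column(s) ",
         paste(dropped, collapse = ", "),
         " are collinear with the others", call. = FALSE)
  }
  dat <- data.frame(et = energies, pi_star = df$pi_star,
                    alpha = df$alpha, beta = df$beta)
  mod <- stats::lm(et ~ pi_star + alpha + beta, data = dat)
  co <- stats::coef(mod)
  structure(
    list(et0 = unname(co["(Intercept)"]), a = unname(co["pi_star"]),
         b = unname(co["alpha"]), c = unname(co["beta"]),
         r_squared = r_squared_lm(mod),
         residuals = unname(stats::residuals(mod)),
         n_solvents = length(energies),
         model = mod),
    class = "kat_fit"
  )
}

#' @export
print.kat_fit <- function(x, ...) {
  cat(sprintf(
    "<kat_fit> E_T = %.2f %+.2f pi* %+.2f alpha %+.2f beta  (n = %d, R^2 = %.4f)\n",
    x$et0, x$a, x$b, x$c, x$n_solvents, x$r_squared))
  invisible(x)
}

#' Predict a transition energy from a fitted KAT relation
#'
#' @param fit A [fit_kat()] result.
#' @param descriptor A [solvent_descriptor()], or a data frame of descriptor
#'   columns for several solvents.
#' @return Predicted transition energy(ies) in kcal/mol.
#' @export
predict_kat <- function(fit, descriptor) {
  stopifnot(inherits(fit, "kat_fit"))
  df <- as_descriptor_frame(descriptor)
  fit$et0 + fit$a * df$pi_star + fit$b * df$alpha + fit$c * df$beta
}

# R^2 without summary.lm (whose perfect-fit warning is spurious for
# noiseless synthetic panels); a zero-variance response counts as fully
# explained when the residuals are zero
r_squared_lm <- function(mod) {
  rss <- sum(stats::residuals(mod)^2)
  y <- stats::fitted(mod) + stats::residuals(mod)
  tss <- sum((y - mean(y))^2)
  if (tss > 0) 1 - rss / tss else as.numeric(rss == 0)
}

as_descriptor_frame <- function(descriptors) {
  if (inherits(descriptors, "solvent_descriptor")) {
    descriptors <- list(descriptors)
  }
  if (is.list(descriptors) && !is.data.frame(descriptors) &&
      all(vapply(descriptors, inherits, logical(1), "solvent_descriptor"))) {
    return(data.frame(
      name = vapply(descriptors, `[[`, character(1), "name"),
      pi_star = vapply(descriptors, `[[`, numeric(1), "pi_star"),
      alpha = vapply(descriptors, `[[`, numeric(1), "alpha"),
      beta = vapply(descriptors, `[[`, numeric(1), "beta")
    ))
  }
  df <- as.data.frame(descriptors)
  need <- c("pi_star", "alpha", "beta")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("descriptor table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a solvent descriptor table
#'
#' Delimited text with header columns `name`, `pi_star`, `alpha`, `beta` and
#' optionally `epsilon_r`, `et30`; `#` lines are comments.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A data frame of descriptors, one row per solvent.
#' @export
read_descriptors <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", strip.white = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("name", "pi_star", "alpha", "beta")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("descriptor file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}
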