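# Nonlinear least-squares estimation of the solvent-exchange model.
#
# The objective Sum (et_obs - exchange_model_energy)^2 is multimodal in
# (E_T12, f2/1, f12/1), so the fit is multi-start: a seeded Latin-hypercube
# sample over the parameter box plus one "informed" start (endpoints at the
# data ends, E_T12 at the mid-composition energy, f's at 1, k at 0). Each
# start runs bounded Levenberg-Marquardt (minpack.lm); the lowest-RSS
# converged start wins, ties broken by start index.

#' Fit the solvent-exchange model to a titration series
#'
#' Estimates (E_T1, E_T2, E_T12, f2/1, f12/1) — plus k for the corrected
#' variant — by seeded multi-start bounded least squares. The exchange order
#' m is a fixed hyperparameter, never optimized continuously; use
#' [compare_model_variants()] for the discrete choice between m values and
#' variants.
#'
#' Endpoint energies are fitted by default (initialized at the series' first
#' and last measured energies) because the model treats them as outputs of
#' the regression; `fix_endpoints = TRUE` pins them to the measured values.
#' Bounds: f2/1 and f12/1 nonnegative, energies within
#' \[min(et) - 5, max(et) + 5\] kcal/mol, k unbounded.
#'
#' @param series A [titration_series()] with more points than free
#'   parameters (5 for `"general"`, 6 for `"corrected"`).
#' @param variant `"general"` or `"corrected"` (adds the water-structure
#'   correction constant k as a sixth free parameter; m is then fixed at 2).
#' @param m Exchange order, fixed during the fit.
#' @param n_starts Number of Latin-hypercube starts in addition to the
#'   informed start.
#' @param seed Integer seed making the start sample reproducible.
#' @param fix_endpoints If `TRUE`, E_T1 and E_T2 are held at the series
#'   endpoint energies instead of being fitted.
#' @param cross_term Cross-term exponent convention, see
#'   [local_shell_fractions()].
#' @return An object of class `exchange_fit`: a list with elements `params`
#'   (an [exchange_params()]), `rss`, `r_squared`, `sd` (residual standard
#'   deviation, \eqn{\sqrt{RSS/(n-p)}}), `n_points`, `converged`, `n_starts`,
#'   `best_start`, `stability_flag` (raised when converged near-optimal
#'   starts disagree on any parameter by more than 1%), `start_log` (per-start
#'   diagnostics), `fitted`, `residuals`.
#' @examples
#' truth <- exchange_params(60.68, 68.7, 63.58, 2.17, 1.41, m = 2)
#' s <- simulate_exchange_series(truth, grid = seq(0, 1, 0.05),
#'                               noise = noise_spec(0, 1))
#' fit <- fit_exchange_model(s, m = 2, seed = 1)
#' fit$params$f2_1
#' @export
fit_exchange_model <- function(series, variant = c("general", "corrected"),
                               m = 2, n_starts = 32, seed = 1,
                               fix_endpoints = FALSE,
                               cross_term = c("half", "as_printed")) {
  variant <- match.arg(variant)
  cross_term <- match.arg(cross_term)
  stopifnot(inherits(series, "titration_series"))
  if (variant == "corrected" && m != 2) {
    stop("the corrected variant is defined for m = 2 only", call. = FALSE)
  }
  x2 <- series$x2
  et <- series$et
  n <- length(et)
  free <- c(if (!fix_endpoints) c("et1", "et2"), "et12", "f2_1", "f12_1",
            if (variant == "corrected") "k")
  p <- length(free)
  if (n <= p) {
    stop(sprintf("need more than %d points to fit %d free parameters", p, p),
         call. = FALSE)
  }

  e_lo <- min(et) - 5
  e_hi <- max(et) + 5
  bounds <- list(
    et1 = c(e_lo, e_hi), et2 = c(e_lo, e_hi), et12 = c(e_lo, e_hi),
    f2_1 = c(0, Inf), f12_1 = c(0, Inf), k = c(-Inf, Inf)
  )
  lower <- vapply(bounds[free], `[`, numeric(1), 1L)
  upper <- vapply(bounds[free], `[`, numeric(1), 2L)

  fixed <- list(m = m)
  if (fix_endpoints) {
    ends <- series_endpoints(series)
    fixed$et1 <- unname(ends["et1"])
    fixed$et2 <- unname(ends["et2"])
  }

  make_params <- function(theta) {
    a <- c(as.list(theta), fixed)
    exchange_params(et1 = a$et1, et2 = a$et2, et12 = a$et12,
                    f2_1 = a$f2_1, f12_1 = a$f12_1, m = a$m,
                    k = if (variant == "corrected") a$k else NULL,
                    variant = variant)
  }
  p12 <- if (cross_term == "half") m / 2 else m
  predict_raw <- function(theta) {
    a <- c(as.list(theta), fixed)
    exchange_energy_raw(x2, a$et1, a$et2, a$et12, a$f2_1, a$f12_1, m, p12,
                        k = if (variant == "corrected") a$k else NULL)
  }
  resid_fn <- function(theta) {
    names(theta) <- free
    et - predict_raw(theta)
  }
  # central differences keep the Jacobian accurate near machine-zero
  # residuals, where the default forward differences stall the descent
  jac_fn <- function(theta) {
    names(theta) <- free
    h <- pmax(abs(theta), 1) * 1e-6
    J <- matrix(0, n, length(theta))
    for (j in seq_along(theta)) {
      tp <- theta; tm <- theta
      tp[j] <- theta[j] + h[j]; tm[j] <- theta[j] - h[j]
      J[, j] <- (predict_raw(tm) - predict_raw(tp)) / (2 * h[j])
    }
    J
  }

  starts <- exchange_starts(free, n_starts, seed, x2, et, e_lo, e_hi)

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 1000, maxfev = 5000)
  log_rows <- vector("list", nrow(starts))
  results <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    th0 <- starts[i, ]
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(res)) {
      log_rows[[i]] <- data.frame(start = i, converged = FALSE,
                                  rss = NA_real_, info = NA_integer_)
      next
    }
    theta <- stats::setNames(unname(res$par), free)
    ok <- res$info %in% 1:4 && all(is.finite(theta))
    log_rows[[i]] <- data.frame(start = i, converged = ok,
                                rss = res$deviance, info = res$info)
    results[[i]] <- list(theta = theta, rss = res$deviance, converged = ok)
  }
  start_log <- do.call(rbind, log_rows)

  conv <- which(vapply(results, function(r) !is.null(r) && r$converged,
                       logical(1)))
  if (!length(conv)) {
    stop(paste0("no start converged; per-start diagnostics:\n",
                paste(utils::capture.output(print(start_log)),
                      collapse = "\n")), call. = FALSE)
  }
  rsss <- vapply(results[conv], `[[`, numeric(1), "rss")
  # lowest rss wins; ties (within 1e-12) broken by start index
  best_i <- conv[which(rsss <= min(rsss) + 1e-12)[1]]
  best <- results[[best_i]]

  # stability: do converged starts that reached (numerically) the optimum
  # agree on the parameters? Disagreement > 1% flags weak identifiability.
  near <- conv[rsss <= best$rss + pmax(1e-8, 1e-6 * best$rss)]
  stability_flag <- FALSE
  if (length(near) > 1) {
    mat <- do.call(rbind, lapply(results[near], `[[`, "theta"))
    spread <- apply(mat, 2, function(v) diff(range(v)))
    scale <- pmax(abs(best$theta), 1e-8)
    stability_flag <- any(spread / scale > 0.01)
  }

  params <- make_params(best$theta)
  fitted <- exchange_model_energy(x2, params, cross_term)
  rss <- sum((et - fitted)^2)
  tss <- sum((et - mean(et))^2)
  structure(
    list(
      params = params,
      rss = rss,
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      sd = sqrt(rss / (n - p)),
      n_points = n,
      converged = TRUE,
      n_starts = nrow(starts),
      best_start = best_i,
      stability_flag = stability_flag,
      start_log = start_log,
      fitted = fitted,
      residuals = et - fitted,
      fix_endpoints = fix_endpoints,
      cross_term = cross_term,
      seed = seed,
      mixture_name = attr(series, "mixture_name")
    ),
    class = "exchange_fit"
  )
}

# Start matrix: one informed start + a seeded Latin-hypercube over the box.
# Unbounded dimensions (f's above, k) are sampled on a finite surrogate range.
exchange_starts <- function(free, n_starts, seed, x2, et, e_lo, e_hi) {
  informed <- c(et1 = et[1], et2 = et[length(et)],
                et12 = mean(range(et)), f2_1 = 1, f12_1 = 1, k = 0)
  span <- list(
    et1 = c(e_lo, e_hi), et2 = c(e_lo, e_hi), et12 = c(e_lo, e_hi),
    f2_1 = c(0.01, 10), f12_1 = c(0.01, 10), k = c(-10, 10)
  )
  u <- withr::with_seed(seed, lhs::randomLHS(n_starts, length(free)))
  lo <- vapply(span[free], `[`, numeric(1), 1L)
  hi <- vapply(span[free], `[`, numeric(1), 2L)
  hyper <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(hyper) <- free
  rbind(informed[free], hyper)
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("<exchange_fit> %s (%s, m = %g): %d points\n",
              x$mixture_name, x$params$variant, x$params$m, x$n_points))
  print(x$params)
  cat(sprintf("  rss = %.4g (kcal/mol)^2, R^2 = %.4f, sd = %.4g kcal/mol\n",
              x$rss, x$r_squared, x$sd))
  cat(sprintf("  %d/%d starts converged; best start %d%s\n",
              sum(x$start_log$converged), x$n_starts, x$best_start,
              if (x$stability_flag) "; STABILITY FLAG raised" else ""))
  invisible(x)
}

#' Fit and rank several exchange-model variants
#'
#' Fits every candidate (variant, m) combination to the same series and
#' ranks them: converged fits first, then stability-flag-clear fits, then by
#' residual standard deviation. Candidates whose regression fails are kept
#' in the report with their error message rather than dropped.
#'
#' @param series A [titration_series()].
#' @param candidates A list of `list(variant = , m = )` pairs; default
#'   compares the general model at m = 2 and m = 3 and the corrected model.
#' @param ... Passed on to [fit_exchange_model()] (e.g. `seed`, `n_starts`).
#' @return An object of class `variant_comparison`: a data frame (one row
#'   per candidate, ranked) with the fits in attribute `fits`.
#' @export
compare_model_variants <- function(series,
                                   candidates = list(
                                     list(variant = "general", m = 2),
                                     list(variant = "general", m = 3),
                                     list(variant = "corrected", m = 2)
                                   ),
                                   ...) {
  stopifnot(length(candidates) >= 1)
  fits <- vector("list", length(candidates))
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    fit <- tryCatch(
      fit_exchange_model(series, variant = cand$variant, m = cand$m, ...),
      error = function(e) e
    )
    failed <- inherits(fit, "error")
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      variant = cand$variant, m = cand$m,
      converged = !failed,
      stability_flag = if (failed) NA else fit$stability_flag,
      rss = if (failed) NA_real_ else fit$rss,
      sd = if (failed) NA_real_ else fit$sd,
      r_squared = if (failed) NA_real_ else fit$r_squared,
      note = if (failed) conditionMessage(fit) else ""
    )
  }
  tab <- do.call(rbind, rows)
  ord <- order(!tab$converged, tab$stability_flag %in% TRUE, tab$sd)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], class = c("variant_comparison",
                                             "data.frame"))
}

#' Best fit from a variant comparison
#'
#' @param comparison A [compare_model_variants()] result.
#' @return The top-ranked `exchange_fit`.
#' @export
best_fit <- function(comparison) {
  stopifnot(inherits(comparison, "variant_comparison"))
  fit <- attr(comparison, "fits")[[1]]
  if (inherits(fit, "error")) {
    stop("no candidate converged: ", conditionMessage(fit), call. = FALSE)
  }
  fit
}
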