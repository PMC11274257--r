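#' Automatic starting values for a Randles fit
#'
#' Heuristic initialization read directly off the spectrum:
#' * `r_u`: minimum real impedance over the grid (high-frequency intercept);
#' * `r_p`: `max(z_real) - r_u`, clamped to a small positive floor;
#' * `alpha`: 0.8, a typical rough-electrode value;
#' * `y0`: `1 / (omega_peak * r_p)` where `omega_peak` is the angular
#'   frequency of the `-z_imag` maximum (the apex of the charge-transfer
#'   semicircle, where `omega * r_p * C` is about 1); falls back to the grid
#'   midpoint when the spectrum has no capacitive apex;
#' * `w_d`: `0.1 * r_p * sqrt(omega_min)`, a diffusion tail comparable to a
#'   tenth of the charge-transfer arc at the lowest measured frequency.
#'
#' @param spectrum A spectrum data frame with at least 5 points spanning at
#'   least 2 decades of frequency.
#' @return A [randles_params()] row.
#' @export
initial_guess <- function(spectrum) {
  s <- as_eis_spectrum(spectrum)
  if (nrow(s) < 5) rlang::abort("need at least 5 frequency points for initialization")
  span <- log10(max(s$frequency_hz) / min(s$frequency_hz))
  if (span < 2) rlang::abort("need a frequency span of at least 2 decades")

  r_u <- max(min(s$z_real_ohm), 1e-9)
  r_p <- max(max(s$z_real_ohm) - r_u, 1e-3 * r_u, 1e-9)
  neg_zim <- -s$z_imag_ohm
  if (any(neg_zim > 0)) {
    omega_peak <- 2 * pi * s$frequency_hz[which.max(neg_zim)]
  } else {
    omega_peak <- 2 * pi * exp(mean(log(range(s$frequency_hz))))
  }
  y0 <- 1 / (omega_peak * r_p)
  w_d <- 0.1 * r_p * sqrt(2 * pi * min(s$frequency_hz))
  randles_params(r_u = r_u, y0 = y0, alpha = 0.8, w_d = w_d, r_p = r_p)
}

# Map between natural parameters and the unconstrained-ish optimizer space:
# log for the positive magnitudes, identity for alpha (box-bounded).
theta_pack <- function(p) {
  c(log_r_u = log(max(p$r_u, 1e-12)), log_y0 = log(p$y0), alpha = p$alpha,
    log_w_d = log(max(p$w_d, 1e-12)), log_r_p = log(max(p$r_p, 1e-12)))
}

theta_unpack <- function(theta) {
  randles_params(r_u = exp(theta[[1]]), y0 = exp(theta[[2]]),
                 alpha = theta[[3]], w_d = exp(theta[[4]]),
                 r_p = exp(theta[[5]]))
}

# unvalidated unpack for use inside the optimizer's residual function,
# where trial steps may momentarily leave the admissible region
theta_unpack_raw <- function(theta) {
  list(r_u = exp(theta[[1]]), y0 = exp(theta[[2]]), alpha = theta[[3]],
       w_d = exp(theta[[4]]), r_p = exp(theta[[5]]))
}

fit_weights <- function(s, weighting) {
  zmod2 <- s$z_real_ohm^2 + s$z_imag_ohm^2
  switch(weighting,
    unit = list(wr = rep(1, nrow(s)), wi = rep(1, nrow(s))),
    modulus = list(wr = 1 / zmod2, wi = 1 / zmod2),
    proportional = {
      # per-component relative weights; fall back to the modulus when a
      # component vanishes so no point gets infinite weight
      wr <- 1 / pmax(s$z_real_ohm^2, 1e-6 * zmod2)
      wi <- 1 / pmax(s$z_imag_ohm^2, 1e-6 * zmod2)
      list(wr = wr, wi = wi)
    },
    rlang::abort("weighting must be one of 'unit', 'modulus', 'proportional'")
  )
}

weighted_residuals <- function(theta, s, omega, w) {
  p <- theta_unpack_raw(theta)
  faradaic <- complex(real = p$r_p, imaginary = 0) + p$w_d * (1i * omega)^(-0.5)
  z_cpe <- 1 / (p$y0 * (1i * omega)^p$alpha)
  z <- p$r_u + z_parallel(z_cpe, faradaic)
  r <- c(sqrt(w$wr) * (Re(z) - s$z_real_ohm),
         sqrt(w$wi) * (Im(z) - s$z_imag_ohm))
  r[!is.finite(r)] <- 1e12 # reject overflowing trial steps
  r
}

#' Fit the Randles equivalent circuit to an impedance spectrum
#'
#' Weighted complex nonlinear least squares: minimizes
#' \deqn{\sum_i w_i \left[(Z_{R,i} - \hat Z_{R,i})^2 +
#'   (Z_{IM,i} - \hat Z_{IM,i})^2\right]}
#' over the five Randles parameters by Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]). `r_u`, `y0`, `w_d` and `r_p` are fitted in log
#' space (positive by construction); `alpha` is box-bounded to `(0, 1]`.
#' The fit is deterministic given `(spectrum, init, weighting)`.
#'
#' Weightings:
#' * `"modulus"` (default): `w_i = 1/|Z_i|^2` on both components. Impedance
#'   magnitudes span several decades across an EIS sweep; modulus weighting
#'   makes every frequency contribute its *relative* misfit.
#' * `"unit"`: unweighted; low-frequency (large `|Z|`) points dominate.
#' * `"proportional"`: per-component relative weights `1/Z_R^2`, `1/Z_{IM}^2`
#'   (guarded against vanishing components).
#'
#' Convergence: relative change in the objective below 1e-10 or a gradient
#' (ftol/gtol) criterion, with up to 500 iterations, followed by a short
#' polishing pass at tighter tolerance to resolve weakly identified
#' parameters (the Warburg coefficient can contribute as little as 1e-6 of
#' the total impedance). Non-convergence is reported via `converged =
#' FALSE` with the best parameters found, never silently.
#'
#' @param spectrum A spectrum data frame (see [eis_spectrum()]).
#' @param init Optional [randles_params()] starting point; default
#'   [initial_guess()].
#' @param weighting `"modulus"`, `"unit"` or `"proportional"`.
#' @param max_iter Iteration cap for the main Levenberg-Marquardt pass.
#' @return An object of class `randles_fit`: a list with elements `params`
#'   (a `randles_params` row), `residual_norm` (the weighted objective),
#'   `std_errors` (delta-method standard errors on the natural scale),
#'   `n_iterations`, `converged`, `weighting`, `objective_trace` (the
#'   non-increasing per-iteration objective), and `data` (the fitted
#'   spectrum). Has [tidy()], [glance()], [augment()] and `autoplot()`
#'   methods.
#' @examples
#' truth <- randles_params(313.2, 12.43e-6, 0.7199, 28.53e-6, 3785)
#' spec <- evaluate_spectrum(truth, frequency_grid(1, 1e5, 8))
#' fit <- fit_randles(spec)
#' tidy(fit)
#' @export
fit_randles <- function(spectrum, init = NULL,
                        weighting = c("modulus", "unit", "proportional"),
                        max_iter = 500) {
  weighting <- match.arg(weighting)
  s <- as_eis_spectrum(spectrum)
  omega <- 2 * pi * s$frequency_hz
  w <- fit_weights(s, weighting)
  if (is.null(init)) init <- initial_guess(s)
  init <- as_randles_params(init)

  # log-parameter box wide enough for any physical circuit (1e-28..1e28)
  # while keeping exp() inside double range during trial steps
  lower <- c(-65, -65, 1e-3, -65, -65)
  upper <- c(65, 65, 1, 65, 65)
  ctrl <- minpack.lm::nls.lm.control(
    ftol = 1e-10, ptol = 1e-12, gtol = 0, maxiter = max_iter
  )
  fit <- minpack.lm::nls.lm(
    par = theta_pack(init), lower = lower, upper = upper,
    fn = weighted_residuals, s = s, omega = omega, w = w, control = ctrl
  )
  trace <- fit$rsstrace
  n_iter <- fit$niter

  # Polishing pass: restart at the optimum with machine-level tolerances so
  # that parameters with tiny leverage (Warburg tail under a large r_p)
  # still converge in their own direction.
  polish <- minpack.lm::nls.lm(
    par = fit$par, lower = lower, upper = upper,
    fn = weighted_residuals, s = s, omega = omega, w = w,
    control = minpack.lm::nls.lm.control(
      ftol = .Machine$double.eps, ptol = .Machine$double.eps, gtol = 0,
      maxiter = 1024
    )
  )
  if (polish$deviance <= fit$deviance) {
    fit <- polish
    trace <- c(trace, polish$rsstrace)
    n_iter <- n_iter + polish$niter
  }

  params <- theta_unpack(fit$par)
  converged <- fit$info %in% c(1, 2, 3, 4) && is.finite(fit$deviance)

  # delta-method standard errors on the natural scale
  std_errors <- rep(NA_real_, 5)
  names(std_errors) <- c("r_u", "y0", "alpha", "w_d", "r_p")
  n_res <- 2 * nrow(s)
  dof <- n_res - 5
  if (dof > 0) {
    cov_theta <- tryCatch(
      solve(fit$hessian) * fit$deviance / dof,
      error = function(e) NULL
    )
    if (!is.null(cov_theta)) {
      se_theta <- sqrt(pmax(diag(cov_theta), 0))
      scale <- c(params$r_u, params$y0, 1, params$w_d, params$r_p)
      std_errors[] <- se_theta * scale
    }
  }

  structure(
    list(
      params = params,
      residual_norm = fit$deviance,
      std_errors = std_errors,
      n_iterations = n_iter,
      converged = converged,
      weighting = weighting,
      objective_trace = as.numeric(trace),
      init = init,
      data = s
    ),
    class = "randles_fit"
  )
}

#' Goodness of fit of Randles parameters against a spectrum
#'
#' Residuals are model minus data on both impedance components, weighted
#' exactly as in [fit_randles()], so `residual_norm` here equals the
#' objective reported inside a `randles_fit` for the same weighting.
#'
#' @inheritParams fit_randles
#' @param params A [randles_params()] row.
#' @return A list with `residual_norm` and `residuals`, a tibble of
#'   per-point raw and weighted residuals.
#' @export
goodness_of_fit <- function(spectrum, params,
                            weighting = c("modulus", "unit", "proportional")) {
  weighting <- match.arg(weighting)
  s <- as_eis_spectrum(spectrum)
  p <- as_randles_params(params)
  omega <- 2 * pi * s$frequency_hz
  w <- fit_weights(s, weighting)
  z <- randles_impedance(p, omega)
  res <- tibble::tibble(
    frequency_hz = s$frequency_hz,
    resid_real = Re(z) - s$z_real_ohm,
    resid_imag = Im(z) - s$z_imag_ohm,
    wresid_real = sqrt(w$wr) * (Re(z) - s$z_real_ohm),
    wresid_imag = sqrt(w$wi) * (Im(z) - s$z_imag_ohm)
  )
  list(
    residual_norm = sum(res$wresid_real^2 + res$wresid_imag^2),
    residuals = res
  )
}

#' @export
print.randles_fit <- function(x, ...) {
  cat("Randles equivalent-circuit fit (", x$weighting, " weighting)\n", sep = "")
  cat(sprintf("  %d frequency points, %.4g Hz - %.4g Hz\n",
              nrow(x$data), min(x$data$frequency_hz), max(x$data$frequency_hz)))
  p <- x$params
  cat(sprintf("  r_u = %.6g ohm, y0 = %.6g S s^alpha, alpha = %.4f,\n",
              p$r_u, p$y0, p$alpha))
  cat(sprintf("  w_d = %.6g ohm s^-1/2, r_p = %.6g ohm\n", p$w_d, p$r_p))
  cat(sprintf("  residual norm %.4g after %d iterations (%s)\n",
              x$residual_norm, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidiers for Randles fits
#'
#' `tidy()` returns one row per circuit parameter with its estimate and
#' standard error; `glance()` returns a one-row fit summary; `augment()`
#' returns the data with fitted impedance and residuals column-bound.
#'
#' @param x A `randles_fit` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @export
tidy.randles_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("r_u", "y0", "alpha", "w_d", "r_p"),
    estimate = c(p$r_u, p$y0, p$alpha, p$w_d, p$r_p),
    std.error = unname(x$std_errors),
    unit = c("ohm", "S s^alpha", "", "ohm s^-1/2", "ohm")
  )
}

#' @rdname tidy.randles_fit
#' @export
glance.randles_fit <- function(x, ...) {
  tibble::tibble(
    residual_norm = x$residual_norm,
    n_iterations = x$n_iterations,
    converged = x$converged,
    weighting = x$weighting,
    nobs = nrow(x$data)
  )
}

#' @rdname tidy.randles_fit
#' @export
augment.randles_fit <- function(x, ...) {
  z <- randles_impedance(x$params, 2 * pi * x$data$frequency_hz)
  dplyr::mutate(
    tibble::as_tibble(x$data),
    .fitted_z_real = Re(z),
    .fitted_z_imag = Im(z),
    .resid_real = Re(z) - .data$z_real_ohm,
    .resid_imag = Im(z) - .data$z_imag_ohm
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment
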