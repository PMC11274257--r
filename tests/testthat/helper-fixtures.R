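# Shared fixtures: published parameter ranges for the nanomolar dilution
# series, and a reproducible random draw inside them.

reference_ranges <- list(
  r_u = c(313, 2700),
  y0 = c(1e-6, 14e-6),
  alpha = c(0.65, 1.0),
  w_d = c(2e-5, 3.5e-5),
  r_p = c(24, 24000)
)

draw_reference_params <- function() {
  r <- reference_ranges
  randles_params(
    r_u = exp(stats::runif(1, log(r$r_u[1]), log(r$r_u[2]))),
    y0 = exp(stats::runif(1, log(r$y0[1]), log(r$y0[2]))),
    alpha = stats::runif(1, r$alpha[1], r$alpha[2]),
    w_d = stats::runif(1, r$w_d[1], r$w_d[2]),
    r_p = exp(stats::runif(1, log(r$r_p[1]), log(r$r_p[2])))
  )
}

# lossy-sphere quadruple (sigma_p, sigma_m, eps_p, eps_m) guaranteed to
# admit a real DEP crossover: conductivity and permittivity contrasts must
# have opposite signs
draw_crossover_quadruple <- function() {
  repeat {
    q <- list(
      sigma_p = stats::runif(1, 1e-4, 1),
      sigma_m = stats::runif(1, 1e-4, 1),
      eps_p = stats::runif(1, 2, 100),
      eps_m = stats::runif(1, 2, 100)
    )
    if ((q$sigma_m - q$sigma_p) * (q$eps_p - q$eps_m) > 0) return(q)
  }
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

max_param_rel_err <- function(fit_params, truth) {
  max(rel_err(unlist(fit_params), unlist(truth)))
}
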