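#' Log-spaced frequency grid
#'
#' Strictly increasing grid with a fixed number of points per decade,
#' including both endpoints. The package default (0.1 Hz to 1 MHz, 10
#' points per decade) spans both the charge-transfer semicircle and the
#' low-frequency Warburg diffusion tail for all reference parameter sets.
#'
#' @param f_min,f_max Grid limits in Hz, `0 < f_min < f_max`.
#' @param points_per_decade Number of points per frequency decade.
#' @return A numeric vector of frequencies in Hz.
#' @export
frequency_grid <- function(f_min = 0.1, f_max = 1e6, points_per_decade = 10) {
  if (!is.finite(f_min) || !is.finite(f_max) || f_min <= 0 || f_max <= f_min) {
    rlang::abort("need 0 < f_min < f_max")
  }
  lo <- log10(f_min); hi <- log10(f_max)
  f <- 10^seq(lo, hi, by = 1 / points_per_decade)
  if (utils::tail(f, 1) < f_max * (1 - 1e-12)) f <- c(f, f_max)
  f
}

#' Molarity of a protein solution from mass concentration
#'
#' `molarity [nM] = mass_conc [mg/mL] / molecular_mass [kDa] * 1e6`, i.e.
#' (g/L) / (g/mol) expressed in nmol/L. The reference stock the package
#' emulates is 0.01 mg/mL Tau-441 at 45.8 kDa, i.e. 218.34 nM.
#'
#' @param mass_conc Mass concentration in mg/mL, `> 0`.
#' @param molecular_mass Molecular mass in kDa, `> 0`.
#' @return Molarity in nM.
#' @examples
#' molarity_from_mass_concentration(0.01, 45.8) # 218.34 nM
#' @export
molarity_from_mass_concentration <- function(mass_conc, molecular_mass) {
  if (!all(is.finite(mass_conc)) || any(mass_conc <= 0)) {
    rlang::abort("mass_conc must be > 0")
  }
  if (!all(is.finite(molecular_mass)) || any(molecular_mass <= 0)) {
    rlang::abort("molecular_mass must be > 0")
  }
  mass_conc / molecular_mass * 1e6
}

#' Serial dilution series
#'
#' Exact geometric dilution: `start, start/factor, ..., start/factor^steps`.
#' A 1:1 mix with diluent is `factor = 2`. Note that published labels for
#' such series are often rounded at each step and so drift slightly from
#' the exact geometric values; this function keeps the exact arithmetic.
#'
#' @param start Starting concentration (any unit), `> 0`.
#' @param factor Dilution factor per step, `> 1`.
#' @param steps Number of dilution steps, `>= 0`.
#' @return Numeric vector of length `steps + 1`.
#' @examples
#' serial_dilution(218.34, 2, 4)
#' @export
serial_dilution <- function(start, factor, steps) {
  if (!is.finite(start) || start <= 0) rlang::abort("start must be > 0")
  if (!is.finite(factor) || factor <= 1) rlang::abort("factor must be > 1")
  if (!is.finite(steps) || steps < 0 || steps != round(steps)) {
    rlang::abort("steps must be a non-negative integer")
  }
  start / factor^(0:steps)
}

#' Generate a synthetic impedance spectrum
#'
#' Evaluates the Randles model on a frequency grid and perturbs each
#' impedance component with independent proportional Gaussian noise:
#' `ZR -> ZR * (1 + N(0, relative_sd^2))` and likewise for `ZIM`.
#' Proportional (not additive) noise matches real sweeps, where `|Z|`
#' spans several decades and a fixed additive floor would drown the
#' low-impedance end. Deterministic given `seed`.
#'
#' @param params A [randles_params()] row.
#' @param frequency_hz Frequency grid in Hz (default [frequency_grid()]).
#' @param relative_sd Proportional noise standard deviation, `>= 0`
#'   (default 0.005, i.e. 0.5%).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @param label Optional sample label.
#' @return A spectrum tibble (see [eis_spectrum()]).
#' @examples
#' truth <- randles_params(313.2, 12.43e-6, 0.7199, 28.53e-6, 3785)
#' generate_spectrum(truth, relative_sd = 0.01, seed = 42)
#' @export
generate_spectrum <- function(params, frequency_hz = frequency_grid(),
                              relative_sd = 0.005, seed = NULL, label = "") {
  if (!is.finite(relative_sd) || relative_sd < 0) {
    rlang::abort("relative_sd must be >= 0")
  }
  clean <- evaluate_spectrum(params, frequency_hz, label = label)
  if (relative_sd == 0) return(clean)
  n <- nrow(clean)
  draw <- function() {
    matrix(stats::rnorm(2 * n, mean = 1, sd = relative_sd), ncol = 2)
  }
  fac <- if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
  eis_spectrum(clean$frequency_hz,
               clean$z_real_ohm * fac[, 1],
               clean$z_imag_ohm * fac[, 2],
               label = label)
}

# run expr under a local RNG seeded with `seed`, restoring global state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Reference Randles parameters for the Tau-441 dilution series
#'
#' Published equivalent-circuit parameters fitted to impedance sweeps of a
#' Tau-441 protein suspension at six concentrations (a blank of deionized
#' water plus a five-step 1:1 dilution series from a 218.34 nM stock),
#' together with the conductivity column derived from the polarization
#' resistance and the cell of [cell_geometry()]. These rows parameterize
#' the packaged synthetic fixtures ([generate_tau441_series()]).
#'
#' The blank row's solution resistance (1.228 mOhm) is physically
#' implausible for deionized water but is carried verbatim from the
#' published table; [generate_tau441_series()] notes this when the blank is
#' generated.
#'
#' @return A tibble with columns `label`, `molarity_nm`, `r_u`, `y0`,
#'   `alpha`, `w_d`, `r_p`, `conductivity_s_per_m` (the published derived
#'   value).
#' @export
tau441_params <- function() {
  tibble::tribble(
    ~label,       ~molarity_nm, ~r_u,     ~y0,       ~alpha,  ~w_d,     ~r_p,
    "blank",      0,            1.228e-3, 29.36e-12, 1.0,     23.53e-6, 11.39e3,
    "218.34 nM",  218.34,       313.2,    12.43e-6,  0.7199,  28.53e-6, 3.785e3,
    "109.15 nM",  109.15,       1.153e3,  13.68e-6,  0.6539,  33.99e-6, 2.925e3,
    "54.58 nM",   54.58,        1.178e3,  13.21e-6,  0.6959,  34.94e-6, 4.038e3,
    "27.29 nM",   27.29,        1.787e3,  7.768e-6,  0.7479,  24.28e-6, 8.381e3,
    "13.64 nM",   13.64,        2.682e3,  1.898e-6,  0.8698,  19.89e-6, 23.69
  ) |>
    dplyr::mutate(
      conductivity_s_per_m = c(2.12e-3, 6.37e-3, 8.24e-3, 5.97e-3, 2.88e-3, 1.02)
    )
}

#' Generate the packaged Tau-441 synthetic concentration series
#'
#' One synthetic spectrum per [tau441_params()] row on a common log-spaced
#' grid, labeled by concentration. With `relative_sd = 0` the spectra are
#' the exact Randles model evaluations; with noise they are seeded per row
#' (seed, seed + 1, ...) so the whole series is reproducible from one
#' integer.
#'
#' @inheritParams generate_spectrum
#' @param quiet Suppress the note about the blank row's implausible `r_u`.
#' @return The [tau441_params()] tibble with a `spectrum` list-column.
#' @examples
#' series <- generate_tau441_series(relative_sd = 0, quiet = TRUE)
#' series$spectrum[[2]]
#' @export
generate_tau441_series <- function(frequency_hz = frequency_grid(),
                                   relative_sd = 0.005, seed = NULL,
                                   quiet = FALSE) {
  rows <- tau441_params()
  if (!quiet) {
    rlang::inform(
      "note: blank-row r_u = 1.228e-3 ohm is carried verbatim from the published fit; it is physically implausible for deionized water",
      .frequency = "once", .frequency_id = "eisdep_blank_ru"
    )
  }
  seeds <- if (is.null(seed)) vector("list", nrow(rows)) else as.list(seed + seq_len(nrow(rows)) - 1)
  rows$spectrum <- purrr::pmap(
    list(rows$r_u, rows$y0, rows$alpha, rows$w_d, rows$r_p, rows$label, seeds),
    function(r_u, y0, alpha, w_d, r_p, label, s) {
      generate_spectrum(randles_params(r_u, y0, alpha, w_d, r_p),
                        frequency_hz = frequency_hz,
                        relative_sd = relative_sd, seed = s, label = label)
    }
  )
  rows
}
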