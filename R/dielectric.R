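#' Parallel-plate measurement cell geometry
#'
#' Geometry of a two-plate conductivity cell: electrode separation
#' (`thickness`, m), electrode cross-section (`area`, m^2), and the derived
#' cell constant `kappa = thickness / area` (1/m) that converts bulk
#' conductivity to measured resistance, `sigma = kappa / R`.
#'
#' The default values are the dimensions of the bipolar stainless-steel
#' cell used for the Tau-441 measurements the package emulates: 4.75 mm
#' plate separation, 1.97 cm^2 cross-section, giving kappa = 24.11 1/m.
#'
#' @param thickness Electrode separation L in m, `> 0`.
#' @param area Electrode cross-section A in m^2, `> 0`.
#' @return A one-row tibble of class `cell_geometry` with columns
#'   `thickness_m`, `area_m2`, `cell_constant_per_m`.
#' @examples
#' cell_geometry()               # the Tau-441 cell
#' cell_geometry(1e-3, 1e-4)     # kappa = 10 1/m
#' @export
cell_geometry <- function(thickness = 4.75e-3, area = 1.97e-4) {
  if (!is.finite(thickness) || thickness <= 0) rlang::abort("thickness must be > 0")
  if (!is.finite(area) || area <= 0) rlang::abort("area must be > 0")
  out <- tibble::tibble(
    thickness_m = thickness,
    area_m2 = area,
    cell_constant_per_m = thickness / area
  )
  class(out) <- c("cell_geometry", class(out))
  out
}

#' Suspension conductivity from a measured resistance
#'
#' For a parallel-plate cell, `sigma = L / (R * A) = kappa / R` (S/m). Which
#' fitted resistance to insert is a modeling choice: the solution
#' resistance `r_u` is the textbook bulk-electrolyte term, but published
#' conductivity tables for this cell are reproduced by the polarization
#' resistance `r_p` instead; [run_pipeline()] therefore takes an explicit
#' `resistance_source` switch and records which was used.
#'
#' @param resistance Resistance in ohm, `> 0`. Vectorized.
#' @param geometry A [cell_geometry()] row.
#' @return Conductivity in S/m.
#' @examples
#' conductivity_from_resistance(23.69, cell_geometry()) # 1.02 S/m
#' @export
conductivity_from_resistance <- function(resistance, geometry = cell_geometry()) {
  if (!all(is.finite(resistance)) || any(resistance <= 0)) {
    rlang::abort("resistance must be finite and > 0")
  }
  geometry$cell_constant_per_m / resistance
}

#' Complex relative permittivity spectrum from an impedance spectrum
#'
#' Treats the filled cell as a parallel-plate capacitor and converts each
#' measured impedance to relative permittivity and conductivity.
#'
#' In the default `"admittance"` mode the conversion is exact for that cell
#' model: with `Y = 1/Z`,
#' `sigma = Re(Y) * kappa`, `eps' = Im(Y) * kappa / (omega * eps0)`, and
#' `eps'' = sigma / (omega * eps0)`.
#'
#' `"literal"` mode instead applies the simplified per-component
#' formulas `eps' = kappa / (omega * eps0 * |Z_IM|)` and
#' `eps'' = kappa / (omega * eps0 * Z_R)`. These treat each impedance
#' component in isolation (exact only when the cell is a pure series or
#' pure parallel combination) and are provided for comparison with
#' published single-component treatments; points with `Z_IM = 0` are
#' flagged `undefined`, not dropped.
#'
#' @param spectrum A spectrum data frame (see [eis_spectrum()]).
#' @param geometry A [cell_geometry()] row.
#' @param mode `"admittance"` (exact, default) or `"literal"`.
#' @return A tibble of class `permittivity_spectrum` with columns
#'   `frequency_hz`, `eps_real`, `eps_imag`, `sigma_s_per_m`, `undefined`.
#'   The identity `eps_imag = sigma / (omega * eps0)` holds at every row.
#' @export
permittivity_from_impedance <- function(spectrum, geometry = cell_geometry(),
                                        mode = c("admittance", "literal")) {
  mode <- match.arg(mode)
  s <- as_eis_spectrum(spectrum)
  z <- spectrum_z(s)
  if (any(Mod(z) == 0)) rlang::abort("zero-magnitude impedance cannot be inverted")
  omega <- 2 * pi * s$frequency_hz
  kappa <- geometry$cell_constant_per_m

  if (mode == "admittance") {
    y <- 1 / z
    sigma <- Re(y) * kappa
    eps_real <- Im(y) * kappa / (omega * eps0)
    eps_imag <- sigma / (omega * eps0)
    undefined <- rep(FALSE, length(z))
  } else {
    undefined <- s$z_imag_ohm == 0
    eps_real <- ifelse(undefined, NA_real_,
                       kappa / (omega * eps0 * abs(s$z_imag_ohm)))
    eps_imag <- kappa / (omega * eps0 * s$z_real_ohm)
    sigma <- eps_imag * omega * eps0
  }
  out <- tibble::tibble(
    frequency_hz = s$frequency_hz,
    eps_real = eps_real,
    eps_imag = eps_imag,
    sigma_s_per_m = sigma,
    undefined = undefined
  )
  class(out) <- c("permittivity_spectrum", class(out))
  attr(out, "mode") <- mode
  attr(out, "label") <- spectrum_label(s)
  out
}

#' Complex permittivity vector of a permittivity spectrum
#'
#' Assembles `eps* = eps' - j * eps''` from the tabulated components.
#'
#' @param data A `permittivity_spectrum` tibble (or any data frame with
#'   `eps_real` and `eps_imag` columns).
#' @return A complex vector.
#' @export
complex_permittivity <- function(data) {
  complex(real = data$eps_real, imaginary = -data$eps_imag)
}

#' Frequency-independent dielectric model of a medium
#'
#' For a medium described only by its static relative permittivity and DC
#' conductivity, the complex relative permittivity is
#' `eps_m*(omega) = eps_r - j * sigma / (omega * eps0)`.
#'
#' @param frequency_hz Frequencies in Hz, `> 0`.
#' @param eps_r Static relative permittivity (dimensionless), `> 0`.
#' @param sigma DC conductivity in S/m, `>= 0`.
#' @return A complex vector, one value per frequency.
#' @examples
#' medium_permittivity(1e3, eps_r = 78.4, sigma = 1e-4) # dilute aqueous medium
#' @export
medium_permittivity <- function(frequency_hz, eps_r, sigma) {
  check_omega(2 * pi * frequency_hz)
  if (!is.finite(eps_r) || eps_r <= 0) rlang::abort("eps_r must be > 0")
  if (!is.finite(sigma) || sigma < 0) rlang::abort("sigma must be >= 0")
  complex(real = eps_r, imaginary = -sigma / (2 * pi * frequency_hz * eps0))
}

#' Clausius-Mossotti factor
#'
#' The complex Clausius-Mossotti (CM) factor of a homogeneous spherical
#' particle in a medium,
#' \deqn{f_{CM} = \frac{\varepsilon_p^* - \varepsilon_m^*}
#'                    {\varepsilon_p^* + 2\varepsilon_m^*},}
#' whose real part sets the sign of the dielectrophoretic force
#' (positive: toward high field gradient). `cm_factor_impedance()` is the
#' algebraically identical form written in terms of the particle and
#' medium impedances (`Z propto 1/(j omega eps0 eps*)` for a fixed
#' geometry): `f_CM = (Z_m* - Z_p*) / (Z_m* + 2 Z_p*)`.
#'
#' For physically admissible inputs (positive real permittivities,
#' non-negative conductivities) `Re(f_CM)` is bounded in `[-0.5, 1]`.
#'
#' @param eps_p,eps_m Complex relative permittivities of particle and
#'   medium. Vectorized.
#' @param z_p,z_m Complex impedances of particle and medium. Vectorized.
#' @return A complex vector of CM factors.
#' @examples
#' cm_factor_permittivity(2 - 1i, 1 - 0.5i)  # 0.25 + 0i
#' cm_factor_impedance(1 + 0i, 4 + 0i)       # 0.5
#' @export
cm_factor_permittivity <- function(eps_p, eps_m) {
  denom <- eps_p + 2 * eps_m
  if (any(Mod(denom) == 0)) {
    rlang::abort("degenerate CM denominator: eps_p + 2*eps_m = 0")
  }
  (eps_p - eps_m) / denom
}

#' @rdname cm_factor_permittivity
#' @export
cm_factor_impedance <- function(z_p, z_m) {
  denom <- z_m + 2 * z_p
  if (any(Mod(denom) == 0)) {
    rlang::abort("degenerate CM denominator: z_m + 2*z_p = 0")
  }
  (z_m - z_p) / denom
}

#' Maxwell-Wagner mixture model and its inversion
#'
#' Effective complex permittivity of a dilute suspension of spherical
#' particles at volume fraction `delta`:
#' \deqn{\varepsilon_{mix}^* = \varepsilon_m^*
#'   \frac{1 + 2\delta f_{CM}}{1 - \delta f_{CM}}.}
#' `invert_maxwell_wagner()` recovers the CM factor from a measured mixture
#' permittivity,
#' `f_CM = (eps_mix - eps_m) / (delta * (eps_mix + 2 * eps_m))`, the exact
#' algebraic inverse (round-trips to machine precision). At `delta = 0`
#' the mixture is the bare medium and `f_CM` is unidentifiable, so the
#' inversion rejects it.
#'
#' @param eps_m Complex relative permittivity of the medium. Vectorized.
#' @param f_cm Complex CM factor. Vectorized.
#' @param eps_mix Complex relative permittivity of the suspension.
#' @param delta Particle volume fraction, in `[0, 1)` (forward) or `(0, 1)`
#'   (inverse).
#' @return A complex vector.
#' @examples
#' maxwell_wagner_mixture(1 + 0i, 0.25 + 0i, 0.1)   # 1.076923
#' invert_maxwell_wagner(1.05 / 0.975 + 0i, 1 + 0i, 0.1) # 0.25
#' @export
maxwell_wagner_mixture <- function(eps_m, f_cm, delta) {
  if (!is.finite(delta) || delta < 0 || delta >= 1) {
    rlang::abort("volume fraction delta must lie in [0, 1)")
  }
  denom <- 1 - delta * f_cm
  if (any(Mod(denom) == 0)) rlang::abort("degenerate mixture: 1 - delta*f_cm = 0")
  eps_m * (1 + 2 * delta * f_cm) / denom
}

#' @rdname maxwell_wagner_mixture
#' @export
invert_maxwell_wagner <- function(eps_mix, eps_m, delta) {
  if (!is.finite(delta) || delta <= 0 || delta >= 1) {
    rlang::abort("volume fraction delta must lie in (0, 1) for the inversion")
  }
  denom <- eps_mix + 2 * eps_m
  if (any(Mod(denom) == 0)) rlang::abort("degenerate inversion: eps_mix + 2*eps_m = 0")
  (eps_mix - eps_m) / (delta * denom)
}

# Interpolate a complex permittivity spectrum on the log-frequency axis.
# Each component is interpolated geometrically (linear in log|x| vs log f)
# when its bracketing values share a sign, which is exact for power-law
# behavior such as the conduction term -sigma/(omega*eps0); otherwise it
# falls back to linear interpolation in log f.
interp_eps <- function(log_f_grid, eps, log_f) {
  interp1 <- function(x) {
    lin <- stats::approx(log_f_grid, x, xout = log_f, rule = 2)$y
    ok <- x != 0
    if (all(ok) && (all(x > 0) || all(x < 0))) {
      sign(x[1]) * exp(stats::approx(log_f_grid, log(abs(x)),
                                     xout = log_f, rule = 2)$y)
    } else {
      lin
    }
  }
  complex(real = interp1(Re(eps)), imaginary = interp1(Im(eps)))
}

#' Predict the dielectrophoretic response of a particle
#'
#' Computes the real part of the Clausius-Mossotti factor point-wise over a
#' frequency grid, partitions the grid into contiguous sign bands, refines
#' each sign change to a crossover frequency by bisection on log-frequency
#' (with the particle and medium permittivities interpolated log-linearly
#' between grid points, relative tolerance 1e-6), and recommends an
#' operating band: the widest positive-DEP band in log-frequency, ties
#' broken toward lower frequency where electrothermal side effects are
#' gentler. Values with `|Re f_CM| < zero_tol` are classified as zero.
#'
#' @param frequency_hz Strictly increasing grid of at least 2 frequencies.
#' @param eps_p Complex relative permittivity of the particle at each
#'   frequency (see [complex_permittivity()], [medium_permittivity()]).
#' @param eps_m Complex relative permittivity of the medium, same length.
#' @param zero_tol Magnitude below which `Re f_CM` counts as zero.
#' @return An object of class `dep_prediction`: list with `spectrum` (a
#'   tibble `frequency_hz`, `re_fcm`), `bands` (tibble `f_low`, `f_high`,
#'   `sign` in `{"positive","negative","zero"}`), `crossover_hz` (numeric),
#'   and `recommended_band` (length-2 numeric or NULL when no positive band
#'   exists). Has `tidy()` and `autoplot()` methods.
#' @examples
#' f <- frequency_grid(1e2, 1e8, 10)
#' ep <- medium_permittivity(f, 60, 0.05)   # conductive particle
#' em <- medium_permittivity(f, 80, 0.001)  # dilute aqueous medium
#' pred <- dep_response(f, ep, em)
#' pred$crossover_hz
#' @export
dep_response <- function(frequency_hz, eps_p, eps_m, zero_tol = 1e-12) {
  n <- length(frequency_hz)
  if (n < 2) rlang::abort("need at least 2 frequency points")
  if (any(diff(frequency_hz) <= 0) || any(frequency_hz <= 0)) {
    rlang::abort("frequencies must be positive and strictly increasing")
  }
  if (length(eps_p) != n || length(eps_m) != n) {
    rlang::abort("eps_p and eps_m must match the frequency grid length")
  }
  re_fcm <- Re(cm_factor_permittivity(eps_p, eps_m))
  sgn <- ifelse(abs(re_fcm) < zero_tol, 0L, sign(re_fcm))

  log_f <- log10(frequency_hz)
  refine <- function(lo, hi) {
    # bisection on log10(f) for Re fCM = 0 with interpolated permittivities
    g <- function(lf) {
      Re(cm_factor_permittivity(interp_eps(log_f, eps_p, lf),
                                interp_eps(log_f, eps_m, lf)))
    }
    a <- log_f[lo]; b <- log_f[hi]
    fa <- g(a)
    for (i in 1:200) {
      m <- (a + b) / 2
      fm <- g(m)
      if (fm == 0 || (b - a) < 1e-6 * abs(m) + 1e-12) break
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    10^((a + b) / 2)
  }

  # bracket between consecutive nonzero-classified points so that a grid
  # point falling exactly on a crossover still yields one crossover
  crossover <- numeric(0)
  nz <- which(sgn != 0)
  if (length(nz) >= 2) {
    for (k in seq_len(length(nz) - 1)) {
      i <- nz[k]; j <- nz[k + 1]
      if (sgn[i] != sgn[j]) crossover <- c(crossover, refine(i, j))
    }
  }

  # contiguous sign bands delimited by the refined crossovers
  edges <- c(frequency_hz[1], crossover, frequency_hz[n])
  band_sign <- character(length(edges) - 1)
  for (k in seq_along(band_sign)) {
    # classify by the grid points the band contains (their nonzero signs
    # agree by construction: bands are delimited by the crossovers)
    inside <- sgn[frequency_hz >= edges[k] & frequency_hz <= edges[k + 1]]
    nz <- inside[inside != 0]
    s_band <- if (length(nz) == 0) 0L else nz[1]
    band_sign[k] <- c("negative", "zero", "positive")[s_band + 2L]
  }
  bands <- tibble::tibble(
    f_low = edges[-length(edges)],
    f_high = edges[-1],
    sign = band_sign
  )

  pos <- dplyr::filter(bands, .data$sign == "positive")
  recommended <- NULL
  if (nrow(pos) > 0) {
    width <- log10(pos$f_high / pos$f_low)
    best <- which(width >= max(width) - 1e-12)[1] # ties -> lower frequency
    recommended <- c(pos$f_low[best], pos$f_high[best])
  }

  structure(
    list(
      spectrum = tibble::tibble(frequency_hz = frequency_hz, re_fcm = re_fcm),
      bands = bands,
      crossover_hz = crossover,
      recommended_band = recommended
    ),
    class = "dep_prediction"
  )
}

#' Closed-form DEP crossover frequency of a homogeneous lossy sphere
#'
#' For frequency-independent material properties the Maxwell-Wagner
#' relaxation gives a single real crossover at
#' \deqn{f_c = \frac{1}{2\pi\varepsilon_0}\sqrt{
#'   \frac{(\sigma_m-\sigma_p)(\sigma_p+2\sigma_m)}
#'        {(\varepsilon_p-\varepsilon_m)(\varepsilon_p+2\varepsilon_m)}}}
#' which exists iff the conductivity contrast and the permittivity contrast
#' have opposite signs. Serves as the analytic check on the bisection
#' solver in [dep_response()].
#'
#' @param sigma_p,sigma_m Particle and medium conductivities (S/m).
#' @param eps_p,eps_m Particle and medium relative permittivities (real).
#' @return The crossover frequency in Hz, or `NA_real_` when no real
#'   crossover exists.
#' @export
crossover_frequency_sphere <- function(sigma_p, sigma_m, eps_p, eps_m) {
  num <- (sigma_m - sigma_p) * (sigma_p + 2 * sigma_m)
  den <- (eps_p - eps_m) * (eps_p + 2 * eps_m)
  ratio <- num / den
  if (!is.finite(ratio) || ratio <= 0) return(NA_real_)
  sqrt(ratio) / (2 * pi * eps0)
}

#' @export
print.dep_prediction <- function(x, ...) {
  cat("DEP response prediction\n")
  cat(sprintf("  grid: %d points, %.4g Hz - %.4g Hz\n",
              nrow(x$spectrum), min(x$spectrum$frequency_hz),
              max(x$spectrum$frequency_hz)))
  if (length(x$crossover_hz) == 0) {
    cat("  no crossover frequency in the grid span\n")
  } else {
    cat("  crossover(s) at", paste(sprintf("%.6g Hz", x$crossover_hz),
                                   collapse = ", "), "\n")
  }
  if (is.null(x$recommended_band)) {
    cat("  no positive-DEP band\n")
  } else {
    cat(sprintf("  recommended positive-DEP band: %.4g Hz - %.4g Hz\n",
                x$recommended_band[1], x$recommended_band[2]))
  }
  invisible(x)
}

#' @rdname tidy.randles_fit
#' @export
tidy.dep_prediction <- function(x, ...) {
  rec <- if (is.null(x$recommended_band)) {
    rep(FALSE, nrow(x$bands))
  } else {
    x$bands$f_low == x$recommended_band[1] &
      x$bands$f_high == x$recommended_band[2]
  }
  dplyr::mutate(x$bands, recommended = rec)
}
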