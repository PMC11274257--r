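#' Vacuum permittivity (F/m)
#'
#' CODATA value of the electric constant \eqn{\varepsilon_0}, used in every
#' impedance-to-permittivity conversion in the package.
#'
#' @format A length-one numeric, 8.8541878128e-12 F/m.
#' @export
eps0 <- 8.8541878128e-12

#' Construct an EIS spectrum table
#'
#' An impedance spectrum is an ordinary tibble with one row per measured
#' frequency and columns `frequency_hz`, `z_real_ohm` and `z_imag_ohm`.
#' Every function in the package that consumes a spectrum accepts any data
#' frame with those three columns, so spectra compose freely with dplyr
#' verbs. This constructor validates and canonicalizes: rows are sorted by
#' ascending frequency and duplicate frequencies are rejected.
#'
#' The sign convention is the engineering `exp(+j*omega*t)` time dependence:
#' capacitive reactance has negative `z_imag_ohm`, and Nyquist plots show
#' `-z_imag_ohm` on the ordinate.
#'
#' @param frequency_hz Strictly positive frequencies in Hz (at least 2).
#' @param z_real_ohm Real part of the impedance at each frequency (ohm).
#' @param z_imag_ohm Imaginary part of the impedance at each frequency (ohm).
#' @param label Optional sample label (e.g. a concentration), stored as the
#'   `"label"` attribute and propagated to CSV provenance comments.
#' @return A tibble with columns `frequency_hz`, `z_real_ohm`, `z_imag_ohm`,
#'   sorted by frequency, with a `"label"` attribute.
#' @examples
#' eis_spectrum(c(1, 10, 100), c(5, 5, 5), c(0, 0, 0), label = "resistor")
#' @export
eis_spectrum <- function(frequency_hz, z_real_ohm, z_imag_ohm, label = "") {
  if (length(frequency_hz) < 2) {
    rlang::abort("an impedance spectrum needs at least 2 frequency points")
  }
  if (length(z_real_ohm) != length(frequency_hz) ||
      length(z_imag_ohm) != length(frequency_hz)) {
    rlang::abort("frequency_hz, z_real_ohm and z_imag_ohm must have equal length")
  }
  if (!all(is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    rlang::abort("all frequencies must be finite and > 0")
  }
  if (anyDuplicated(frequency_hz)) {
    rlang::abort("duplicate frequencies are not allowed in a spectrum")
  }
  ord <- order(frequency_hz)
  out <- tibble::tibble(
    frequency_hz = as.numeric(frequency_hz[ord]),
    z_real_ohm   = as.numeric(z_real_ohm[ord]),
    z_imag_ohm   = as.numeric(z_imag_ohm[ord])
  )
  attr(out, "label") <- as.character(label)
  out
}

#' @rdname eis_spectrum
#' @param data A data frame carrying the three spectrum columns.
#' @export
as_eis_spectrum <- function(data, label = spectrum_label(data)) {
  cols <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "not an impedance spectrum: missing column(s) ",
      paste(missing, collapse = ", ")
    ))
  }
  eis_spectrum(data$frequency_hz, data$z_real_ohm, data$z_imag_ohm,
               label = label %||% "")
}

#' @rdname eis_spectrum
#' @export
spectrum_label <- function(data) {
  lbl <- attr(data, "label", exact = TRUE)
  if (is.null(lbl)) "" else as.character(lbl)
}

#' Complex impedance vector of a spectrum
#'
#' @param data A spectrum data frame (see [eis_spectrum()]).
#' @return A complex vector `z_real_ohm + 1i * z_imag_ohm`.
#' @export
spectrum_z <- function(data) {
  complex(real = data$z_real_ohm, imaginary = data$z_imag_ohm)
}

#' Polar form of a complex impedance
#'
#' Converts rectangular impedance components to magnitude and phase,
#' `|Z| = sqrt(ZR^2 + ZIM^2)` and `phi = atan2(ZIM, ZR)`. The origin maps to
#' magnitude 0 and phase 0 by convention.
#'
#' @param z Complex impedance(s), or a numeric real part if `z_imag` given.
#' @param z_imag Optional numeric imaginary part (ohm).
#' @return A tibble with columns `magnitude_ohm` and `phase_rad`.
#' @examples
#' to_polar(3 + 4i) # magnitude 5, phase atan(4/3)
#' @export
to_polar <- function(z, z_imag = NULL) {
  if (!is.null(z_imag)) z <- complex(real = z, imaginary = z_imag)
  tibble::tibble(
    magnitude_ohm = Mod(z),
    phase_rad = ifelse(Mod(z) == 0, 0, Arg(z))
  )
}

#' Circuit-element impedances
#'
#' Complex impedance of the constituents of the Randles equivalent circuit,
#' each vectorized over angular frequency `omega` (rad/s):
#'
#' * `z_resistor()`: an ideal resistor, `Z = r` at all frequencies.
#' * `z_cpe()`: a constant-phase element, `Z = 1 / (y0 * (j*omega)^alpha)`
#'   (principal branch). `alpha = 1` is an ideal capacitor with capacitance
#'   `y0`; the limit `alpha -> 0` is a resistor `1/y0`.
#' * `z_warburg()`: the semi-infinite Warburg diffusion element,
#'   `Z = w_d * (j*omega)^(-1/2) = w_d * (1 - 1i) / sqrt(2*omega)`, a
#'   constant -45 degree phase line on a Nyquist plot.
#'
#' @param r Resistance (ohm), `r >= 0`.
#' @param y0 CPE coefficient (S s^alpha), `y0 > 0`.
#' @param alpha CPE exponent, `0 < alpha <= 1`.
#' @param w_d Warburg coefficient (ohm s^(-1/2)), `w_d >= 0`.
#' @param omega Angular frequency (rad/s); must be `> 0` for frequency-
#'   dependent elements.
#' @return A complex vector, one impedance per `omega`.
#' @examples
#' z_cpe(1e-6, 1, 1)        # ideal 1 uF capacitor at omega = 1: -1e6i
#' z_warburg(sqrt(2), 1)    # 1 - 1i
#' @name circuit_elements
NULL

#' @rdname circuit_elements
#' @export
z_resistor <- function(r, omega) {
  if (!is.finite(r) || r < 0) rlang::abort("resistance must be finite and >= 0")
  rep(complex(real = r, imaginary = 0), length(omega))
}

#' @rdname circuit_elements
#' @export
z_cpe <- function(y0, alpha, omega) {
  if (!is.finite(y0) || y0 <= 0) rlang::abort("CPE coefficient y0 must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    rlang::abort("CPE exponent alpha must lie in (0, 1]")
  }
  check_omega(omega)
  1 / (y0 * (1i * omega)^alpha)
}

#' @rdname circuit_elements
#' @export
z_warburg <- function(w_d, omega) {
  if (!is.finite(w_d) || w_d < 0) rlang::abort("Warburg coefficient w_d must be >= 0")
  check_omega(omega)
  w_d * (1i * omega)^(-0.5)
}

check_omega <- function(omega) {
  if (length(omega) == 0 || !all(is.finite(omega)) || any(omega <= 0)) {
    rlang::abort("angular frequency omega must be finite and > 0")
  }
  invisible(omega)
}

#' Parallel combination of impedances
#'
#' `1 / (1/a + 1/b)`, vectorized. Exported because composing elements by
#' hand is useful when exploring circuit variants in tests and examples.
#'
#' @param a,b Complex impedances.
#' @return Complex vector of the parallel combination.
#' @export
z_parallel <- function(a, b) 1 / (1 / a + 1 / b)

#' Randles equivalent-circuit parameters
#'
#' The five-element Randles circuit used throughout the package: solution
#' resistance `r_u` in series with a constant-phase element `(y0, alpha)`
#' in parallel with the series combination of the polarization
#' (charge-transfer) resistance `r_p` and a semi-infinite Warburg diffusion
#' element `w_d`:
#'
#' \deqn{Z(\omega) = R_u + \left[\frac{1}{Z_{CPE}} +
#'   \frac{1}{R_p + Z_W}\right]^{-1}}
#'
#' Parameters are stored as a one-row tibble so concentration series stack
#' with `dplyr::bind_rows()`.
#'
#' @param r_u Solution resistance (ohm), `>= 0`.
#' @param y0 CPE coefficient (S s^alpha), `> 0`.
#' @param alpha CPE exponent, in `(0, 1]`.
#' @param w_d Warburg coefficient (ohm s^(-1/2)), `>= 0`.
#' @param r_p Polarization resistance (ohm), `>= 0`.
#' @return A one-row tibble of class `randles_params` with those columns.
#' @examples
#' randles_params(r_u = 313.2, y0 = 12.43e-6, alpha = 0.7199,
#'                w_d = 28.53e-6, r_p = 3785)
#' @export
randles_params <- function(r_u, y0, alpha, w_d, r_p) {
  stopifnot(length(r_u) == 1, length(y0) == 1, length(alpha) == 1,
            length(w_d) == 1, length(r_p) == 1)
  if (!is.finite(r_u) || r_u < 0) rlang::abort("r_u must be >= 0")
  if (!is.finite(r_p) || r_p < 0) rlang::abort("r_p must be >= 0")
  if (!is.finite(y0) || y0 <= 0) rlang::abort("y0 must be > 0")
  if (!is.finite(w_d) || w_d < 0) rlang::abort("w_d must be >= 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    rlang::abort("alpha must lie in (0, 1]")
  }
  out <- tibble::tibble(r_u = as.numeric(r_u), y0 = as.numeric(y0),
                        alpha = as.numeric(alpha), w_d = as.numeric(w_d),
                        r_p = as.numeric(r_p))
  class(out) <- c("randles_params", class(out))
  out
}

#' @rdname randles_params
#' @param data A data frame or list with columns/elements `r_u`, `y0`,
#'   `alpha`, `w_d`, `r_p` (one row).
#' @export
as_randles_params <- function(data) {
  randles_params(data$r_u, data$y0, data$alpha, data$w_d, data$r_p)
}

#' Impedance of the Randles equivalent circuit
#'
#' Evaluates the canonical Randles topology (see [randles_params()]) at one
#' or more angular frequencies. At high frequency the CPE shorts the
#' faradaic branch and `Z -> r_u`; at low frequency (with `w_d = 0`) the
#' circuit tends to `r_u + r_p`.
#'
#' @param params A `randles_params` row (or anything [as_randles_params()]
#'   accepts).
#' @param omega Angular frequency (rad/s), `> 0`, vectorized.
#' @return Complex impedance vector.
#' @export
randles_impedance <- function(params, omega) {
  p <- as_randles_params(params)
  check_omega(omega)
  faradaic <- complex(real = p$r_p, imaginary = 0) + z_warburg(p$w_d, omega)
  p$r_u + z_parallel(z_cpe(p$y0, p$alpha, omega), faradaic)
}

#' Evaluate a Randles model over a frequency grid
#'
#' Element-wise [randles_impedance()] at `omega = 2*pi*frequency_hz`,
#' packaged as a spectrum tibble.
#'
#' @inheritParams randles_impedance
#' @param frequency_hz Strictly increasing positive frequencies (Hz).
#' @param label Optional label for the resulting spectrum.
#' @return A spectrum tibble (see [eis_spectrum()]).
#' @export
evaluate_spectrum <- function(params, frequency_hz, label = "") {
  if (length(frequency_hz) < 1) rlang::abort("frequency grid must be non-empty")
  z <- randles_impedance(params, 2 * pi * frequency_hz)
  eis_spectrum(frequency_hz, Re(z), Im(z), label = label)
}
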