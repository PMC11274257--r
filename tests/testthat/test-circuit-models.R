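test_that("polar conversion matches rectangular components", {
  expect_equal(to_polar(1 + 1i),
               tibble::tibble(magnitude_ohm = sqrt(2), phase_rad = pi / 4))
  expect_equal(to_polar(0 + 1i)$phase_rad, pi / 2)
  # hand computation: |3+4i| = 5, atan(4/3) = 0.927295218
  p <- to_polar(3, 4)
  expect_equal(p$magnitude_ohm, 5)
  expect_equal(p$phase_rad, 0.9272952180016122)
  # origin maps to (0, 0) by convention
  expect_equal(to_polar(0 + 0i), tibble::tibble(magnitude_ohm = 0, phase_rad = 0))
})

test_that("circuit elements have their defining limits", {
  omega <- 2 * pi * c(1, 1e3, 1e6)
  expect_equal(z_resistor(100, omega), rep(100 + 0i, 3))
  expect_equal(z_resistor(0, omega), rep(0 + 0i, 3))
  expect_error(z_resistor(-1, omega), "resistance")

  # alpha = 1 CPE is an ideal capacitor 1/(j omega C)
  expect_equal(z_cpe(1e-6, 1, 1), 0 - 1e6i)
  # principal-branch evaluation of (j)^(-1/2)
  expect_equal(z_cpe(1, 0.5, 1), sqrt(2) / 2 * (1 - 1i))
  expect_error(z_cpe(1e-6, 1, 0), "omega")
  expect_error(z_cpe(1e-6, 1.2, 1), "alpha")
  expect_error(z_cpe(-1, 0.5, 1), "y0")

  # semi-infinite Warburg: (1 - 1i)/sqrt(2 omega), -45 degree phase
  expect_equal(z_warburg(sqrt(2), 1), 1 - 1i)
  expect_equal(z_warburg(0, omega), rep(0 + 0i, 3))
  w <- z_warburg(3.3e-5, omega)
  expect_equal(Arg(w), rep(-pi / 4, 3))
  expect_equal(Re(w), -Im(w))
})

test_that("CPE with alpha = 1 agrees with an ideal capacitor everywhere", {
  withr::with_seed(42, {
    y0 <- 10^runif(100, -9, -3)
    omega <- 10^runif(100, -2, 8)
    expect_equal(z_cpe_vec <- mapply(function(y, w) z_cpe(y, 1, w), y0, omega),
                 1 / (1i * omega * y0))
  })
})

test_that("parallel and series composition are associative and commutative", {
  withr::with_seed(7, {
    for (i in 1:20) {
      z <- complex(real = runif(3, 1, 1e4), imaginary = runif(3, -1e4, 1e4))
      expect_equal(z_parallel(z[1], z[2]), z_parallel(z[2], z[1]))
      expect_equal(z_parallel(z_parallel(z[1], z[2]), z[3]),
                   z_parallel(z[1], z_parallel(z[2], z[3])))
      expect_equal(z[1] + z[2], z[2] + z[1])
    }
  })
})

test_that("Randles impedance has the canonical topology and limits", {
  # published blank-row parameters at 10 kHz; expected value frozen from an
  # independent high-precision evaluation of Ru + [CPE || (Rp + W)]
  p <- randles_params(1.228e-3, 29.36e-12, 1.0, 23.53e-6, 11.39e3)
  z <- randles_impedance(p, 2 * pi * 1e4)
  expect_equal(Re(z), 11384.974894368012, tolerance = 1e-12)
  expect_equal(Im(z), -239.21679872923865, tolerance = 1e-12)

  # high-frequency limit: CPE shorts the faradaic branch, Z -> r_u
  p2 <- randles_params(100, 1e-6, 0.8, 3e-5, 1000)
  f_char <- 1 / (2 * pi * (p2$r_p * p2$y0)^(1 / p2$alpha))
  z_hi <- randles_impedance(p2, 2 * pi * f_char * 1e12)
  expect_equal(Re(z_hi), p2$r_u, tolerance = 1e-3)

  # low-frequency resistive limit with no Warburg: Z -> r_u + r_p
  p3 <- randles_params(100, 1e-6, 1, 0, 1000)
  z_lo <- randles_impedance(p3, 1e-4 / (p3$r_p * p3$y0))
  expect_equal(Re(z_lo), 1100, tolerance = 1e-6)
})

test_that("real impedance decreases toward r_u beyond the CPE knee", {
  withr::with_seed(13, {
    for (i in 1:5) {
      p <- draw_reference_params()
      f_char <- 1 / (2 * pi * (p$r_p * p$y0)^(1 / p$alpha))
      omega <- 2 * pi * 10^seq(log10(f_char), log10(f_char) + 6, length.out = 40)
      zr <- Re(randles_impedance(p, omega))
      expect_true(all(diff(zr) <= 1e-9 * abs(zr[-1])))
      # 12 decades beyond the characteristic frequency, ZR is r_u to 0.1%
      zr_far <- Re(randles_impedance(p, 2 * pi * f_char * 1e12))
      expect_equal(zr_far, p$r_u, tolerance = 1e-3)
    }
  })
})

test_that("ideal-capacitor Randles Nyquist trace is a semicircle", {
  # with alpha = 1 and no Warburg, max(-ZIM) = r_p/2 at omega = 1/(r_p C)
  p <- randles_params(50, 2e-6, 1, 0, 5000)
  omega_apex <- 1 / (p$r_p * p$y0)
  f_apex <- omega_apex / (2 * pi)
  f <- frequency_grid(f_apex / 1e3, f_apex * 1e3, 200)
  s <- evaluate_spectrum(p, f)
  apex <- which.max(-s$z_imag_ohm)
  expect_equal(max(-s$z_imag_ohm), p$r_p / 2, tolerance = 1e-4)
  expect_equal(2 * pi * s$frequency_hz[apex], omega_apex, tolerance = 0.02)
})

test_that("evaluate_spectrum agrees with point-wise evaluation and preserves length", {
  p <- randles_params(313.2, 12.43e-6, 0.7199, 28.53e-6, 3785)
  f <- c(1, 10, 100, 1e4)
  s <- evaluate_spectrum(p, f, label = "x")
  expect_equal(nrow(s), 4)
  expect_equal(spectrum_label(s), "x")
  for (i in seq_along(f)) {
    z <- randles_impedance(p, 2 * pi * f[i])
    expect_identical(s$z_real_ohm[i], Re(z))
    expect_identical(s$z_imag_ohm[i], Im(z))
  }
  # resistor-only circuit: flat real part, zero imaginary part
  flat <- evaluate_spectrum(randles_params(200, 1e-30, 1, 0, 0), f)
  expect_equal(flat$z_real_ohm, rep(200, 4), tolerance = 1e-9)
  expect_equal(flat$z_imag_ohm, rep(0, 4), tolerance = 1e-9)
})

test_that("spectrum constructor validates and canonicalizes", {
  expect_error(eis_spectrum(1, 1, 1), "at least 2")
  expect_error(eis_spectrum(c(0, 1), c(1, 1), c(0, 0)), "> 0")
  expect_error(eis_spectrum(c(1, 1), c(1, 1), c(0, 0)), "duplicate")
  s <- eis_spectrum(c(10, 1), c(2, 1), c(-2, -1))
  expect_equal(s$frequency_hz, c(1, 10))
  expect_equal(s$z_real_ohm, c(1, 2))
  expect_error(as_eis_spectrum(data.frame(a = 1)), "missing column")
})
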