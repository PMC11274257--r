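geom <- cell_geometry() # 4.75 mm separation, 1.97 cm^2 cross-section

test_that("cell constant and conductivity follow the plate geometry", {
  expect_equal(geom$cell_constant_per_m, 4.75e-3 / 1.97e-4)
  # published derived conductivities, 3 significant figures
  expect_equal(signif(conductivity_from_resistance(23.69, geom), 3), 1.02)
  expect_equal(signif(conductivity_from_resistance(3.785e3, geom), 3), 6.37e-3)
  # resistance numerically equal to the cell constant gives exactly 1 S/m
  expect_equal(conductivity_from_resistance(geom$cell_constant_per_m, geom), 1)
  expect_error(conductivity_from_resistance(0, geom), "resistance")
  expect_error(cell_geometry(-1, 1), "thickness")
})

test_that("admittance-mode permittivity is exact for canonical cells", {
  f <- frequency_grid(10, 1e5, 5)
  # pure capacitor: sigma = 0, eps' = C * kappa / eps0 at all frequencies
  C <- 1e-9
  zc <- 1 / (1i * 2 * pi * f * C)
  s <- eis_spectrum(f, Re(zc), Im(zc))
  perm <- permittivity_from_impedance(s, geom)
  expect_equal(perm$sigma_s_per_m, rep(0, length(f)), tolerance = 1e-12)
  expect_equal(perm$eps_real,
               rep(C * geom$cell_constant_per_m / eps0, length(f)),
               tolerance = 1e-12)

  # pure resistor: eps' = 0 and sigma = kappa / R, consistent with the
  # geometry formula at every frequency, to machine precision
  R <- 755
  sr <- eis_spectrum(f, rep(R, length(f)), rep(0, length(f)))
  pr <- permittivity_from_impedance(sr, geom)
  expect_equal(pr$eps_real, rep(0, length(f)))
  expect_equal(pr$sigma_s_per_m,
               rep(conductivity_from_resistance(R, geom), length(f)))

  # parallel RC, hand evaluation of Y = 1/R + j omega C at 1 kHz:
  # sigma = kappa/R, eps' = C kappa / eps0, independent of frequency
  R <- 1e3; C <- 1e-9; f1 <- 1e3
  zrc <- 1 / (1 / R + 1i * 2 * pi * f1 * C)
  s2 <- eis_spectrum(c(f1, 2 * f1), rep(Re(zrc), 2), rep(Im(zrc), 2))
  p2 <- permittivity_from_impedance(s2, geom)
  expect_equal(p2$sigma_s_per_m[1], geom$cell_constant_per_m / R,
               tolerance = 1e-12)
  expect_equal(p2$eps_real[1], C * geom$cell_constant_per_m / eps0,
               tolerance = 1e-12)
})

test_that("eps'' = sigma/(omega eps0) identity holds on every grid row", {
  p <- randles_params(313.2, 12.43e-6, 0.7199, 28.53e-6, 3785)
  s <- evaluate_spectrum(p, frequency_grid(0.1, 1e6, 7))
  for (mode in c("admittance", "literal")) {
    perm <- permittivity_from_impedance(s, geom, mode = mode)
    omega <- 2 * pi * perm$frequency_hz
    expect_equal(perm$eps_imag, perm$sigma_s_per_m / (omega * eps0),
                 tolerance = 1e-12)
  }
})

test_that("literal mode flags zero-reactance points instead of dropping them", {
  f <- c(10, 100, 1000)
  s <- eis_spectrum(f, c(100, 100, 100), c(-50, 0, -50))
  perm <- permittivity_from_impedance(s, geom, mode = "literal")
  expect_equal(nrow(perm), 3)
  expect_identical(perm$undefined, c(FALSE, TRUE, FALSE))
  expect_true(is.na(perm$eps_real[2]))
  expect_false(anyNA(perm$eps_imag))
})

test_that("Clausius-Mossotti factor has its defining values and bounds", {
  expect_equal(cm_factor_permittivity(2 - 1i, 2 - 1i), 0 + 0i)
  # hand arithmetic: (1 - 0.5i)/(4 - 2i) = 0.25
  expect_equal(cm_factor_permittivity(2 - 1i, 1 - 0.5i), 0.25 + 0i)
  # bound cases: perfectly polarizable particle -> 1; void -> -0.5
  expect_equal(Re(cm_factor_permittivity(1e12 + 0i, 80 + 0i)), 1, tolerance = 1e-9)
  expect_equal(cm_factor_permittivity(0 + 0i, 80 + 0i), -0.5 + 0i)
  expect_error(cm_factor_permittivity(-2 + 0i, 1 + 0i), "degenerate")

  expect_equal(cm_factor_impedance(1 + 0i, 1 + 0i), 0 + 0i)
  expect_equal(cm_factor_impedance(1 + 0i, 4 + 0i), 0.5 + 0i)

  # physical bound -0.5 <= Re fCM <= 1 over random admissible spectra
  withr::with_seed(21, {
    f <- 10^runif(200, 0, 9)
    ep <- medium_permittivity(f, runif(1, 1, 100), runif(1, 0, 2))
    em <- medium_permittivity(f, runif(1, 1, 100), runif(1, 1e-6, 2))
    re <- Re(cm_factor_permittivity(ep, em))
    expect_true(all(re >= -0.5 - 1e-12 & re <= 1 + 1e-12))
  })
})

test_that("impedance and permittivity CM forms agree identically", {
  withr::with_seed(33, {
    for (i in 1:100) {
      eps_p <- complex(real = runif(1, 1, 100), imaginary = -runif(1, 0, 100))
      eps_m <- complex(real = runif(1, 1, 100), imaginary = -runif(1, 0, 100))
      kappa <- runif(1, 1, 100)
      omega <- 10^runif(1, 0, 8)
      z_p <- kappa / (1i * omega * eps0 * eps_p)
      z_m <- kappa / (1i * omega * eps0 * eps_m)
      a <- cm_factor_permittivity(eps_p, eps_m)
      expect_lt(Mod(cm_factor_impedance(z_p, z_m) - a), 1e-13 * Mod(a) + 1e-15)
    }
  })
})

test_that("Maxwell-Wagner mixture model round-trips exactly", {
  expect_equal(maxwell_wagner_mixture(5 - 2i, 0.3 + 0.1i, 0), 5 - 2i)
  expect_equal(maxwell_wagner_mixture(5 - 2i, 0 + 0i, 0.2), 5 - 2i)
  expect_equal(maxwell_wagner_mixture(1 + 0i, 0.25 + 0i, 0.1),
               1.05 / 0.975 + 0i)
  expect_equal(invert_maxwell_wagner(1.05 / 0.975 + 0i, 1 + 0i, 0.1),
               0.25 + 0i)
  expect_error(maxwell_wagner_mixture(1 + 0i, 0.2 + 0i, 1), "delta")
  expect_error(invert_maxwell_wagner(1 + 0i, 1 + 0i, 0), "delta")

  withr::with_seed(55, {
    for (i in 1:100) {
      em <- complex(real = runif(1, 1, 100), imaginary = -runif(1, 0, 100))
      fcm <- complex(real = runif(1, -0.5, 1), imaginary = runif(1, -0.5, 0.5))
      delta <- runif(1, 1e-4, 0.5)
      mix <- maxwell_wagner_mixture(em, fcm, delta)
      expect_equal(invert_maxwell_wagner(mix, em, delta), fcm,
                   tolerance = 1e-12)
    }
  })
})

test_that("DEP prediction finds bands, crossovers and the operating band", {
  # uniformly positive response: conductive particle in a dilute medium
  f <- frequency_grid(1e3, 1e6, 10)
  pred <- dep_response(f, medium_permittivity(f, 90, 0.1),
                       medium_permittivity(f, 80, 0.001))
  expect_length(pred$crossover_hz, 0)
  expect_equal(nrow(pred$bands), 1)
  expect_equal(pred$bands$sign, "positive")
  expect_equal(pred$recommended_band, c(1e3, 1e6), tolerance = 1e-9)

  # single Maxwell-Wagner relaxation: bisection matches the closed form
  q <- list(sigma_p = 0.05, sigma_m = 0.001, eps_p = 60, eps_m = 80)
  fc <- crossover_frequency_sphere(q$sigma_p, q$sigma_m, q$eps_p, q$eps_m)
  g <- frequency_grid(fc / 1e3, fc * 1e3, 10)
  pred2 <- dep_response(g, medium_permittivity(g, q$eps_p, q$sigma_p),
                        medium_permittivity(g, q$eps_m, q$sigma_m))
  expect_length(pred2$crossover_hz, 1)
  expect_lt(rel_err(pred2$crossover_hz, fc), 1e-3)
  expect_equal(pred2$bands$sign, c("positive", "negative"))
  expect_equal(pred2$recommended_band[2], pred2$crossover_hz)
  # crossovers lie strictly inside the grid span
  expect_true(all(pred2$crossover_hz > g[1] & pred2$crossover_hz < g[length(g)]))

  # no real crossover when both contrasts share a sign
  expect_true(is.na(crossover_frequency_sphere(0.01, 0.1, 50, 80)))

  expect_error(dep_response(1e3, 1 + 0i, 2 + 0i), "at least 2")
})

test_that("frequency limits of Re fCM match the conductivity and permittivity contrasts", {
  q <- list(sigma_p = 0.05, sigma_m = 0.001, eps_p = 60, eps_m = 80)
  fc <- crossover_frequency_sphere(q$sigma_p, q$sigma_m, q$eps_p, q$eps_m)
  g <- frequency_grid(fc / 1e4, fc * 1e4, 4) # > 3 decades past relaxation
  pred <- dep_response(g, medium_permittivity(g, q$eps_p, q$sigma_p),
                       medium_permittivity(g, q$eps_m, q$sigma_m))
  lo <- (q$sigma_p - q$sigma_m) / (q$sigma_p + 2 * q$sigma_m)
  hi <- (q$eps_p - q$eps_m) / (q$eps_p + 2 * q$eps_m)
  expect_equal(pred$spectrum$re_fcm[1], lo, tolerance = 5e-3)
  expect_equal(pred$spectrum$re_fcm[nrow(pred$spectrum)], hi, tolerance = 5e-3)
})

test_that("index-matched perturbation gives the first-order fCM = h/3 limit", {
  f <- frequency_grid(1e3, 1e5, 3)
  em <- medium_permittivity(f, 80, 0.01)
  for (h in c(1e-4, 1e-6)) {
    fcm <- cm_factor_permittivity(em * (1 + h), em)
    expect_equal(Re(fcm), rep(h / 3, length(f)), tolerance = 1e-3)
    # swapping particle and medium flips the sign to first order
    fcm_swap <- cm_factor_permittivity(em, em * (1 + h))
    expect_equal(Re(fcm_swap), -Re(fcm), tolerance = 10 * h)
  }
})
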