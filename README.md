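# eisdep

Equivalent-circuit analysis of electrochemical impedance spectroscopy
(EIS) sweeps, and prediction of the dielectrophoretic (DEP) response of
the suspended particle they characterize.

The package is aimed at bioelectrochemistry and microfluidics work where a
two-plate conductivity cell is used to characterize a particle suspension
— the motivating case is a nanomolar dilution series of Tau-441 protein in
deionized water — and the question downstream is *at which frequencies
will this particle experience positive DEP?*

## What it computes

**Circuit fitting.** A measured spectrum `Z*(ω) = Z_R + jZ_IM` is fitted
to the canonical Randles circuit

```
Z(ω) = R_u + [ 1/Z_CPE + 1/(R_p + Z_W) ]⁻¹
Z_CPE = 1/(Y₀ (jω)^α)          (constant-phase element)
Z_W   = W_d (jω)^(−1/2)        (semi-infinite Warburg diffusion)
```

by weighted complex nonlinear least squares (Levenberg–Marquardt, modulus
weighting `1/|Z|²` by default, positivity by log-parameterization).

**Conductivity.** For a parallel-plate cell with separation `L` and
cross-section `A`, `σ = κ/R` with cell constant `κ = L/A`.

**Permittivity.** Via the admittance `Y = 1/Z*`: `σ = Re(Y)·κ`,
`ε′ = Im(Y)·κ/(ωε₀)`, `ε″ = σ/(ωε₀)`.

**DEP response.** The real part of the Clausius–Mossotti factor

```
f_CM = (εp* − εm*) / (εp* + 2εm*)
```

computed over frequency, with sign bands, bisection-refined crossover
frequencies, and a recommended positive-DEP operating band. The
Maxwell–Wagner dilute-mixture model
`εmix* = εm*(1 + 2δ f_CM)/(1 − δ f_CM)` and its exact inverse are included.

A seeded synthetic-spectrum generator reproduces the study conditions
(six Randles parameter rows, blank through 218.34 nM, proportional
Gaussian noise on a 0.1 Hz–1 MHz log grid), since no raw spectra are
publicly deposited.

## Worked example

Simulate the stock-concentration sample, fit it, derive its conductivity,
and predict its DEP response against deionized water:

```r
library(eisdep)

truth <- as_randles_params(tau441_params()[2, ])   # 218.34 nM row
spec  <- generate_spectrum(truth, frequency_grid(0.1, 1e6, 10),
                           relative_sd = 0.005, seed = 42, label = "218.34 nM")
fit <- fit_randles(spec)
fit
#> Randles equivalent-circuit fit (modulus weighting)
#>   71 frequency points, 0.1 Hz - 1e+06 Hz
#>   r_u = 313.316 ohm, y0 = 1.24552e-05 S s^alpha, alpha = 0.7199,
#>   w_d = 1.97672 ohm s^-1/2, r_p = 3791.34 ohm
#>   residual norm 0.002032 after 14 iterations (converged)
```

At 0.5 % noise the fit recovers the generating values `r_u = 313.2`,
`y0 = 12.43e-6`, `alpha = 0.7199`, `r_p = 3785` to a fraction of a
percent. The Warburg coefficient is reported with an honest standard
error larger than its estimate (`tidy(fit)`), because a 2.9e-5 Ω·s^(−1/2)
diffusion tail under a 3.8 kΩ charge-transfer arc is invisible at this
noise level — on noiseless spectra it, too, is recovered to < 0.1 %.

```r
conductivity_from_resistance(fit$params$r_p, cell_geometry())
#> [1] 0.00636364            # S/m; published value for this row: 6.37e-3

perm <- permittivity_from_impedance(spec)
pred <- dep_response(perm$frequency_hz, complex_permittivity(perm),
                     medium_permittivity(perm$frequency_hz, 78.4, 5.5e-6))
pred
#> DEP response prediction
#>   grid: 71 points, 0.1 Hz - 1e+06 Hz
#>   no crossover frequency in the grid span
#>   recommended positive-DEP band: 0.1 Hz - 1e+06 Hz
```

The suspension is far more conductive than the deionized-water medium, so
`Re f_CM` is positive across the whole measured window: positive DEP,
no crossover below 1 MHz. `autoplot(fit)`, `plot_bode()`, and
`autoplot(pred)` give the Nyquist, Bode and CM-spectrum views;
`tidy()`/`glance()`/`augment()` return everything as tibbles.

A thin command-line front end over the same functions ships in
`inst/cli/eisdep.R` (subcommands `fixtures`, `simulate`, `fit`,
`conductivity`, `dep`, `run`).

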