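---
title: "From impedance spectra to a dielectrophoresis prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From impedance spectra to a dielectrophoresis prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eisdep)
library(dplyr)
```

eisdep chains four pieces of standard bioelectrochemistry into one tested
workflow: equivalent-circuit fitting of electrochemical impedance
spectroscopy (EIS) sweeps, conductivity derivation from parallel-plate cell
geometry, impedance-to-permittivity conversion, and a dielectrophoresis
(DEP) response prediction through the Clausius–Mossotti (CM) factor and the
Maxwell–Wagner mixture model. The motivating application is dielectric
characterization of protein suspensions — concretely, a nanomolar dilution
series of Tau-441, the 441-residue tau isoform implicated in Alzheimer's
disease — but every step is generic.

This vignette records the models, the assumptions behind them, and the
numerical and design choices a maintainer would want spelled out.

## The equivalent circuit

A small-signal AC sweep of an electrode cell yields a complex impedance
$Z^*(\omega) = Z_R + jZ_{IM}$ at each angular frequency
$\omega = 2\pi f$. We model the cell with the canonical Randles circuit:
the solution resistance $R_u$ in series with a double-layer element in
parallel with the faradaic branch,

$$Z(\omega) \;=\; R_u + \left[\frac{1}{Z_{CPE}(\omega)} +
  \frac{1}{R_p + Z_W(\omega)}\right]^{-1},$$

with three element models:

* **Constant-phase element (CPE)**, $Z_{CPE} = 1/\left(Y_0 (j\omega)^\alpha\right)$,
  the standard generalization of the double-layer capacitance to rough or
  distributed interfaces. $\alpha = 1$ is an ideal capacitor of capacitance
  $Y_0$; the package validates $0 < \alpha \le 1$ and never silently clips.
  Complex powers use the principal branch throughout.
* **Polarization (charge-transfer) resistance** $R_p$.
* **Semi-infinite Warburg diffusion element**,
  $Z_W = W_d (j\omega)^{-1/2} = W_d(1 - j)/\sqrt{2\omega}$, the constant
  $-45°$ diffusion tail.

Two conventions deserve a note. First, the Warburg parameterization:
published tables for this kind of fit sometimes label $W_d$ in ohms, but
values of order $10^{-5}$ are inconsistent with a pure resistance; we adopt
the common vendor convention of a CPE with exponent fixed at $1/2$, so
$W_d$ carries units $\Omega\,\mathrm{s}^{-1/2}$. Second, signs: the
$e^{+j\omega t}$ time dependence makes capacitive $Z_{IM}$ negative, and
Nyquist views plot $-Z_{IM}$ on the ordinate.

The reference parameter set shipped with the package (`tau441_params()`)
is a published six-row fit — a deionized-water blank plus five protein
concentrations from a 218.34 nM stock halved four times — with $R_u$ from
0.0012 Ω to 2.7 kΩ, $Y_0$ from 29 pF to 14 µF·s^(α−1), $\alpha$ from 0.65
to 1.0, $W_d$ around 2–3.5 × 10⁻⁵, and $R_p$ from 24 Ω to 24 kΩ. The
blank row's milliohm solution resistance is physically implausible for
deionized water; we carry it verbatim (the fixtures are faithful to the
source table) and emit a note when the series is generated.

## Fitting: weighted complex nonlinear least squares

`fit_randles()` minimizes

$$\sum_i w_i\left[(Z_{R,i}-\hat Z_{R,i})^2 + (Z_{IM,i}-\hat Z_{IM,i})^2\right]$$

by Levenberg–Marquardt (`minpack.lm::nls.lm`). Choices that matter:

* **Weighting.** The default is modulus weighting, $w_i = 1/|Z_i|^2$. An
  EIS sweep spans several decades in $|Z|$; unit weights would let the
  low-frequency points dominate the objective entirely. Unit and
  per-component proportional weightings are available; "proportional"
  weights each component by its own squared magnitude, guarded so a
  vanishing component falls back to the modulus rather than receiving
  infinite weight.
* **Parameterization.** $R_u, Y_0, W_d, R_p$ are fitted as logarithms
  (positivity by construction, and scale-free steps across their six
  decades of plausible magnitude); $\alpha$ is box-bounded to $(0, 1]$.
  The log-parameters are boxed to $\pm 65$ so no trial step can overflow
  `exp()`.
* **Initialization.** `initial_guess()` reads $R_u$ off the minimum real
  impedance (high-frequency intercept), $R_p$ off the real-axis span,
  $Y_0$ from the frequency of the $-Z_{IM}$ apex (where
  $\omega R_p C \approx 1$), $\alpha = 0.8$, and a Warburg coefficient
  sized to a tenth of the charge-transfer arc at the lowest frequency.
* **Convergence and polish.** The main pass runs to a relative objective
  change below $10^{-10}$ (at most 500 iterations) and is followed by a
  restart at machine-level tolerances. The polish matters because the
  problem is deliberately ill-conditioned: with $W_d \sim 3\times10^{-5}$
  under a kilo-ohm $R_p$, the Warburg term contributes as little as
  $10^{-6}$ of the total impedance, and resolving it to a fraction of a
  percent requires driving the residual essentially to the floating-point
  floor. On noiseless synthetic spectra (0.1 Hz–1 MHz, 10 points/decade)
  all five parameters are recovered to better than $10^{-4}$ relative —
  the test suite asserts 0.1 % over 50 random draws from the reference
  ranges.
* **Determinism.** No stochastic restarts: the result is a pure function
  of (spectrum, init, weighting). Non-convergence is reported via
  `converged = FALSE` with the best parameters found.

Standard errors come from the local quadratic approximation at the
optimum, delta-method-scaled back to the natural parameter scale; they are
reported by `tidy()` and are indicative, not propagated further (error
propagation into the DEP prediction is out of scope).

## Conductivity and the cell constant

For a parallel-plate cell of separation $L$ and cross-section $A$ the cell
constant is $\kappa = L/A$ and $\sigma = \kappa / R$. The default geometry
($L = 4.75\,\mathrm{mm}$, $A = 1.97\,\mathrm{cm}^2$, $\kappa = 24.11\,
\mathrm{m}^{-1}$) is the cell of the reference measurements; the stated
cross-section unit is read as m² (an evident typographical omission in the
source).

Which fitted resistance to insert is genuinely ambiguous in the source
material: the formula is stated with the solution resistance $R_u$, yet
every value in the published conductivity column is reproduced — exactly,
at the printed precision — by the polarization resistance $R_p$
($\kappa/23.69\,\Omega = 1.02$ S/m for the most dilute sample, and so on
for all six rows; $\kappa/313.2\,\Omega = 0.077$ S/m does not match any
printed value). `conductivity_from_resistance()` therefore takes an
explicit resistance, and the pipeline exposes `resistance_source = "rp"`
(default, reproducing the published table) or `"ru"` (the formula as
written), always logging which was used. Both paths are tested.

## Impedance to permittivity

Treating the filled cell as a parallel-plate capacitor, the exact
conversion goes through the admittance $Y = 1/Z^*$:

$$\sigma = \mathrm{Re}(Y)\,\kappa,\qquad
  \varepsilon' = \frac{\mathrm{Im}(Y)\,\kappa}{\omega\varepsilon_0},\qquad
  \varepsilon'' = \frac{\sigma}{\omega\varepsilon_0}.$$

This is the default (`mode = "admittance"`). A second mode,
`"literal"`, implements the simplified per-component relations
$\varepsilon' = \kappa/(\omega\varepsilon_0|Z_{IM}|)$ and
$\varepsilon'' = \kappa/(\omega\varepsilon_0 Z_R)$ that appear in
single-component treatments of the same conversion. Those are exact only
in degenerate circuits (a pure reactance or a pure resistance
respectively) and are dimensionally consistent only once $\kappa$ and
$\varepsilon_0$ are restored, which the implementation does; the mode
exists for comparison, is flagged approximate, and marks $Z_{IM}=0$ points
`undefined` rather than dropping them. In both modes the identity
$\varepsilon'' = \sigma/(\omega\varepsilon_0)$ holds row-by-row at machine
precision, and on a pure-resistor spectrum the admittance mode reproduces
`conductivity_from_resistance()` exactly.

## CM factor, mixture model, DEP prediction

The complex CM factor of a homogeneous sphere,
$f_{CM} = (\varepsilon_p^* - \varepsilon_m^*)/(\varepsilon_p^* +
2\varepsilon_m^*)$, is implemented in both its permittivity form and the
algebraically identical impedance form
$(Z_m^* - Z_p^*)/(Z_m^* + 2Z_p^*)$; the two agree to machine precision
and the suite asserts it on random pairs. For admissible inputs
$\mathrm{Re}(f_{CM}) \in [-0.5, 1]$, with the low- and high-frequency
limits set by the conductivity and permittivity contrasts respectively.

The Maxwell–Wagner dilute-mixture model
$\varepsilon_{mix}^* = \varepsilon_m^*(1 + 2\delta f_{CM})/(1 - \delta
f_{CM})$ and its exact algebraic inverse are provided; the inversion
requires a known volume fraction $\delta$ and rejects $\delta = 0$, where
$f_{CM}$ is unidentifiable. No volume fraction is published for the
reference suspensions, so the inversion path requires the user to supply
one — the package never guesses.

`dep_response()` evaluates $\mathrm{Re}\,f_{CM}$ on the grid, classifies
each point (positive / negative / zero, with $|\mathrm{Re}\,f_{CM}| <
10^{-12}$ counted as zero), and refines every sign change by bisection on
$\log_{10} f$ to $10^{-6}$ relative tolerance. Between grid points the
permittivity components are interpolated geometrically (linearly in
$\log|x|$ vs $\log f$) when the bracketing values share a sign: the
conduction term $-\sigma/(\omega\varepsilon_0)$ is a power law in
frequency, so geometric interpolation represents it exactly, and the
refined crossover matches the analytic lossy-sphere closed form

$$f_c = \frac{1}{2\pi\varepsilon_0}\sqrt{
  \frac{(\sigma_m-\sigma_p)(\sigma_p+2\sigma_m)}
       {(\varepsilon_p-\varepsilon_m)(\varepsilon_p+2\varepsilon_m)}}$$

to well under 0.1 % (asserted across 20 random material quadruples; a real
crossover exists precisely when the two contrasts have opposite signs).
Crossovers bracketed between the nearest *nonzero*-classified grid points,
so a grid point landing exactly on a root still yields one crossover. The
recommended operating band is the widest positive band in log-frequency,
ties broken toward lower frequency, where electrothermal side effects are
gentler. When only DC properties of the medium are known it is modeled as
frequency-independent,
$\varepsilon_m^*(\omega) = \varepsilon_m - j\sigma_m/(\omega\varepsilon_0)$
(`medium_permittivity()`).

A caution on scope: the positive-DEP claim published for Tau-441 rests on
a qualitative reading of Bode plots, and no raw spectra are deposited, so
that claim has no quantitative counterpart here. The package computes
$\mathrm{Re}\,f_{CM}$ from the dielectric data directly; the test suite
covers the DEP machinery with the property checks above plus an
end-to-end run of the scenario the claim implies (a suspension more
conductive than near-pure water shows uniformly positive DEP across
1 kHz–1 MHz).

## The synthetic-data generator

No raw spectra accompany the reference study, so the package generates
its own fixtures. `generate_spectrum()` evaluates the Randles model on a
log-spaced grid and multiplies each impedance component independently by
$1 + \mathcal{N}(0, s^2)$ with $s$ = `relative_sd` (default 0.5 %, a
typical potentiostat spec over the mid-frequency range). Noise is
proportional, not additive, because $|Z|$ spans decades; the empirical
per-point deviation is verified against $s$ by Monte Carlo in the suite.
Draws are seeded and leave the caller's RNG stream untouched.

The default grid, 0.1 Hz–1 MHz at 10 points/decade (61 points), sits
inside the union of the frequency ranges quoted for the reference
instrument and is wide enough to expose both the charge-transfer
semicircle and the Warburg tail for every reference row.

What the generator does **not** emulate: instrument drift, inductive
wiring artifacts at high frequency, harmonic-excitation nonlinearity,
electrode fouling between samples, or vendor file formats. Passing the
round-trip tests therefore demonstrates correctness of the estimation
chain under the model's own assumptions — it does not certify performance
on real sweeps whose error structure departs from proportional Gaussian
noise.

## Problem sizes and other numerical choices

The shipped checks use the sizes a desktop analysis would: 50 random
parameter sets for the noiseless recovery study (all five parameters
within 0.1 %), 20 seeds at 1 % noise for the noisy study (median $R_u$,
$R_p$ error well under 5 %), 100 random pairs/triples for the CM identity
and Maxwell–Wagner round trip, 20 quadruples for the crossover oracle.
Degenerate inputs are rejected loudly: non-positive frequencies, zero
resistance in the conductivity formula, $\delta$ outside its domain,
CM denominators at zero. The fitting window is a **required**
configuration field: descriptions of the reference experiment disagree
about the measured range (1 kHz–10 MHz in one place, 0.001 Hz–100 MHz in
another), and silently picking one would change fitted parameters, so the
pipeline refuses to default it.

Serial-dilution arithmetic is kept exact (`serial_dilution(218.34, 2, 4)`
gives 13.64625 nM for the last member), while the fixture labels carry
the published, per-step-rounded values (13.64 nM); the two are
deliberately not conflated. Similarly the stock molarity is computed, not
stored: 0.01 mg/mL at 45.8 kDa is 218.34 nM to two decimals.

## Known limitations

* Fixed Randles topology; no model selection, no finite-length Warburg or
  transmission-line variants, no Kramers–Kronig validity testing.
* Fit uncertainties are local quadratic approximations and are not
  propagated into conductivity or the DEP prediction.
* The DEP prediction is the sign and crossover structure of
  $\mathrm{Re}\,f_{CM}$ only — no force magnitudes, electrode field
  modeling, or competing electrothermal/ACEO effects.
* Single-shell (homogeneous sphere) particle model only.
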