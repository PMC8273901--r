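---
title: "Modelling oxygen-dependent complex DNA damage with oxfix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen-dependent complex DNA damage with oxfix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxfix)
```

## The problem

Molecular oxygen strongly enhances the biological effect of ionising
radiation: DNA radicals produced during irradiation are either restored
by chemical repair (reduction by thiols) or "fixed" by oxygen into
non-restorable peroxides, on millisecond timescales.  The competition is
won by oxygen at low linear energy transfer (LET) — fast electrons and
high-energy protons — and becomes irrelevant at high LET, where damage
clusters are already too complex for chemical repair to matter.  For
treatment planning one wants this effect as a closed-form yield model,
not as a microdosimetric simulation: given a particle's kinetic energy
and the local oxygen tension, how many complex double-strand breaks
(DSBc, per cell, per giga-base pair, per Gy) are induced?

`oxfix` implements such a model end to end: the point model, a fitting
bootstrap that calibrates it against tabulated yields, spectral
integration for polyenergetic beams, and a depth-resolved spread-out
Bragg peak (SOBP) demonstrator.

## The point model

### Chemical repair and its saturation form

The fraction of DNA radicals removed by chemical repair before fixation
is modelled empirically as

$$p_R(y, [\mathrm{O}_2]) = 1 - \frac{[\mathrm{O}_2] + K}{[\mathrm{O}_2] + M(y)K},
\qquad
M(y) = M_0 - \frac{M_0 - 1}{1 + (q/y)^r},$$

with $y = (z_\mathrm{eff}/\beta)^2$ the squared ratio of effective
charge to speed.  $K$ (percent O~2~) is the half-effect oxygen
concentration, $M_0 \ge 1$ the maximum repair factor.  Slow, high-LET
particles (large $y$) drive $M \to 1$ and the oxygen effect vanishes;
in the ultrarelativistic limit $M$ tends to the closed form
`stewart_M_inf()`.  At fixed kinematics, the unrepaired fraction is a
three-parameter rational (Möbius) function of oxygen,
$x \mapsto (ax + b)/(x + c)$ — `stewart_to_rational()` performs that
reduction exactly, and the equivalence is verified to $10^{-12}$
relative in the test suite.

The effective charge is not part of the repair model itself; we adopt
the standard Barkas screening rule
$z_\mathrm{eff} = z\,(1 - e^{-125\,\beta\,z^{-2/3}})$ for ions and
$z_\mathrm{eff} = 1$ for electrons, the convention normally used behind
$(z_\mathrm{eff}/\beta)^2$.

### Energy dependence and the combined surface

At a fixed oxygen level the yield of complex damage versus kinetic
energy is a smooth switch between a high-LET value at low energy and a
low-LET plateau at high energy,

$$\mathrm{DSB}_c(E) = (dsb_0 - dsb_\infty)
\left[\tfrac{1}{\pi}\arctan\tfrac{E_0 - E}{\Gamma} + \tfrac12\right]
+ dsb_\infty,$$

with midpoint $E_0$ and width $\Gamma$ in MeV.  Letting all four
parameters saturate in oxygen through rational functions
$g_i(p) = (a_i p + b_i)/(p + c_i)$ gives the central object of the
package, the twelve-coefficient surface

$$F_d(E, p) = |g_4(p) - g_3(p)|
\left[\tfrac{1}{\pi}\arctan\tfrac{g_1(p) - E}{g_2(p)} + \tfrac12\right]
+ g_3(p),$$

an analytical shorthand, not a mechanism.  The bracket lies strictly in
$(0,1)$, so $F_d$ is always bounded by the two branches.  The absolute
value is kept exactly as written; the *fitter* additionally constrains
$g_4(p) \ge g_3(p)$ on the fitted oxygen grid (flagging, never
clipping, a violation), which resolves the sign ambiguity without
changing the evaluation.  Damage-based oxygen enhancement ratios follow
as $\mathrm{OER}_d = F_d(E, p) / F_d(E, 0)$, referenced to full hypoxia.

```{r point}
m <- fd_model_preset("proton")
fd_eval(m, c(0.1, 1, 10, 100), 20)   # DSBc / cell / Gbp / Gy
oer_point(m, 100, c(0.1, 1, 10, 20))
```

### Units

Oxygen is handled internally in percent (100% = pure oxygen); partial
pressures in Torr are converted with 7.6 Torr per percent (760 Torr
atmosphere), so atmospheric 20% is 152 Torr.  The published variants of
the saturation variable (percent, Torr, and a passing mention of molar
concentration) are reconciled by standardising on percent; the molar
reading is not implemented.

## Fitting the surface

`fit_fd()` bootstraps the twelve coefficients from a yield table in
three stages, each a Levenberg–Marquardt minimisation (`minpack.lm`):

1. the arctangent model is fitted per oxygen level (`fit_arctan()`);
2. each $g_i$ is fitted to the stage-1 parameters versus oxygen;
3. all twelve coefficients are refined jointly against every record.

Choices that matter:

* **Positivity by parameterization.**  $\Gamma$, the $c_i$ and the yield
  asymptotes are fitted on log scales ($E_0$ and $\Gamma$ on a log10
  axis, matching the decade span of the energy grids), keeping the
  minimisation unconstrained.  The model is still evaluated in linear
  MeV.
* **Deterministic initialisation with a width multi-start.**  Stage 1
  starts from the yield extrema, the mid-yield crossing energy, and a
  handful of candidate widths (the central 10–90% yield band and
  fractions of the midpoint).  The arctangent model has a known
  degenerate valley — a vanishing midpoint with a broad width mimics
  the transition through its heavy $1/E$ tail — and a single broad
  start can fall into it on noisy data; the multi-start is cheap,
  deterministic, and the lowest objective wins.
* **Weights.**  Unweighted by default; a per-record `sigma` column is
  used as inverse-variance weights.
* **Order invariance.**  Records are sorted internally, so permuting
  the input yields a bit-identical result.
* **Never worse than the start.**  If the joint refinement fails to
  improve the staged initialisation, the staged model is returned with
  `converged = FALSE`.

On noise-free synthetic tables (8 oxygen levels × 40 log-spaced
energies) the fit recovers all twelve generating coefficients to
machine-level accuracy, and `residual_stats()` recovers an injected
noise level from its residual standard deviation (population divisor).
Both properties are exercised in the test suite and recomputed by
`scripts/acceptance.R`.

```{r fit}
tab <- generate_yield_table(synth_config(m, noise_sigma = 0.2, seed = 1))
fit <- fit_fd(tab)
residual_stats(fit)[c("std", "min", "max")]
```

## Polyenergetic beams

For a differential fluence spectrum $\psi(E)$ (particles cm^-2^
MeV^-1^) and mass stopping power $S/\rho$ (MeV cm^2^ g^-1^), dose and
damage in a thin voxel are

$$D = k\!\int\! \psi\,\frac{S}{\rho}\,dE,\qquad
M_d = k\!\int\! F_d(E,p)\,\psi\,\frac{S}{\rho}\,dE,
\qquad k = 1.602\times10^{-10}\ \mathrm{Gy\,g\,MeV^{-1}},$$

evaluated by the trapezoidal rule on the caller's grid — spectra arrive
pre-binned from transport codes, and hidden re-gridding would be a
silent source of error; a `refine` flag exists for convergence studies,
and the suite checks agreement with a 100×-refined midpoint oracle to
better than $10^{-3}$ relative.  Grid values are read as point samples
of the density at bin centres, not histogram integrals.  Spectrum-level
OER~d~ ratios cancel the fluence normalisation.

Because the electron damage response is virtually flat above a few tens
of keV, photon/electron dose grids can skip the integral entirely:
`voxel_damage_map()` implements the median-energy approximation
$M_d = D \circ F_d(P, E_m)$ as a Hadamard product over pre-aligned
dose and oxygen grids.  Spatial resampling between grids is
deliberately out of scope (it belongs to the treatment-planning system);
a shape check replaces it.

## The SOBP demonstrator

The package ships a desk-scale stand-in for a Monte Carlo proton
scenario: a 10 cm spread-out Bragg peak with maximal nominal energy
180 MeV in water, depth-resolved on a 1 mm grid over 30 cm.  Transport
is closed analytically:

* Bragg–Kleeman range–energy rule $R = \alpha E^p$ with water defaults
  $\alpha = 0.0022$ cm MeV^-p^, $p = 1.77$;
* Gaussian range straggling $\sigma_R = 0.012\,R^{0.935}$ cm, truncated
  at $\pm 4\sigma$;
* exponential loss of primaries to nuclear interactions with
  attenuation length $\lambda = 100$ cm (about 1% per cm, the usual
  magnitude quoted for therapeutic protons).

`depth_spectrum()` maps each beam's straggled residual-range
distribution through the Bragg–Kleeman inverse onto a fixed 0.25 MeV
energy grid (fixed for reproducibility of the quadrature); protons past
their range simply leave the spectrum, which reproduces the Bragg peak
without further modelling.  Only primary protons are transported:
secondary fragments are excluded by design, and the mixed-field
spectral API remains available for user-supplied secondary spectra.
This is a known deviation from full Monte Carlo scenarios and the main
caveat when comparing depth-OER profiles against published figures.

Pencil-beam weights come from the closed-form power-law solution: the
continuous weight density $w(R) \propto (R_\mathrm{distal} - R)^{-1/p}$
makes the plateau of pristine peaks of the form $(R - z)^{1/p - 1}$
exactly flat, and bin-integrating it gives discrete weights with the
distal beam heaviest.  Straggling breaks the exact solution, so when
the achieved flatness (measured between the straggling-smeared plateau
edges, two $\sigma_R$ inside each end) misses the ±2% default
tolerance, a non-negative least-squares refinement against the actual
straggled dose engine — polished toward minimax flatness by
Lawson-style reweighting, best iterate kept — replaces it.  An
unattainable tolerance (e.g. a single beam asked to flatten a 5 cm
plateau) is flagged in the result, never raised as an error.

`depth_oer_profile()` then walks the depth grid and evaluates dose,
damage and OER~d~ per oxygen level; `sobp_oer_summary()` condenses the
result into the numbers of interest: the OER~d~ decline across the
high-dose plateau (the spectrum softens with depth, admixing high-LET,
oxygen-insensitive damage) and the sharper drop just beyond the Bragg
peak, where only the slowest protons survive — measured at the first
depth where the dose has fallen below 5% of the plateau mean, a region
where almost no dose is deposited.  Both numbers are recomputed from
scratch by `scripts/acceptance.R`.

```{r sobp, eval = FALSE}
plan <- sobp_plan(n_beams = 20, max_energy = 180, modulation = 10)
prof <- depth_oer_profile(plan, fd_model_preset("proton"),
                          O2_levels = c(0, 0.1, 10, 20))
sobp_oer_summary(prof, O2 = 10)
```

## The synthetic generator

No public damage-yield tables are redistributable with the package, so
`generate_yield_table()` emulates what a microdosimetric Monte Carlo
export looks like: yields of 5–30 DSBc cell^-1^ Gbp^-1^ Gy^-1^, a
low-LET plateau at high energy, a high-LET rise at low energy,
saturating oxygen dependence, and optional additive Gaussian noise
(truncated at $10^{-6}$ to keep yields positive).  Defaults are 40
log-spaced energies over the species' validity window and 8 oxygen
levels from anoxia to 50% with the saturation knee resolved.

The preset truth surfaces (`fd_model_preset()`) place the proton
low-LET plateau near 8 in anoxia, the high-LET maximum near 28, the
transition near 1 MeV, and the oxygen half-saturation of every $g_i$
at 0.3% O~2~ — commensurate with the ~0.26% half-effect concentration
$K$ of the chemical-repair competition, and fast enough that yields at
20% and 50% oxygen differ by well under 1%, as observed for real yield
surfaces.  These are fixture values chosen once for realism, not fitted
constants.

What the generator does *not* emulate: the actual sampling noise
structure of a Monte Carlo damage code (we use i.i.d. Gaussian noise,
sufficient for calibrating the fitter), correlations across energies,
or secondary-particle contamination.  A passing round trip therefore
demonstrates identifiability of the surface from clean tabulated
yields, not agreement with any external simulation; fitting real
microdosimetric exports is done through the neutral CSV bridge
(`read_yield_table()`, with `oxygen_torr` converted on read).

All randomness flows through the seed in `synth_config()`; the global
RNG state is saved and restored, so generation is reproducible and
side-effect free.

## Numerical choices and degenerate inputs

* Evaluation outside a model's fitted energy/oxygen window warns and
  extrapolates (the closed form is globally defined; only the fit is
  range-limited).
* Length-1 spectra are treated as monoenergetic deltas whose value is
  the total fluence.
* Flat yield slices (dynamic range below 5% of the mean) raise a
  "transition not identifiable" error rather than returning arbitrary
  parameters; fewer than 2 oxygen levels or 5 distinct energies are
  rejected up front.
* Model JSON files serialize at 17 significant digits and round-trip
  bit-exactly; the same holds for the CSV writers.
* LM tolerances are set to machine level (`ftol = ptol = 1e-15`) with
  generous iteration caps; fits of this size take milliseconds.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: 320-record yield tables, 200-replicate fitter
calibrations, 146–500-point spectra, and a 20-beam SOBP on a 1 mm ×
30 cm depth grid.  These sizes were chosen so the full pipeline
executes in seconds while leaving every estimate comfortably inside
its stochastic tolerance.

## Limitations

* Only the complex-damage aggregate DSB~c~ is modelled — no SSB/base
  damage subcategories, no enzymatic repair, no cell survival, and no
  RBE endpoints.
* The SOBP demonstrator is primary-proton, central-axis only; no
  lateral dose, no secondaries, no treatment-planning I/O.
* Downstream OER values are point estimates; fit uncertainty is not
  propagated through the spectral integrals.
* Published reference values obtained by fitting external
  microdosimetric simulations (and digitised experimental spectra) can
  only be reproduced by supplying those inputs through the CSV bridge;
  the package deliberately ships no copy of them.
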