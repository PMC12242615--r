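---
title: "Methods: NRTL-SAC solubility modeling and multistart estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NRTL-SAC solubility modeling and multistart estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrtlsac)
```

## The model

`nrtlsac` implements a semi-predictive solubility workflow for small organic
molecules, built from three pieces.

**Activity coefficients.** The NRTL-SAC model describes every molecule by
four non-negative *conceptual segment numbers*: hydrophilic $X$ (surface
able to donate/accept hydrogen bonds), polar-attractive $Y^-$
(electron-pair donor character), polar-repulsive $Y^+$ (electron-pair
acceptor character) and hydrophobic $Z$. The activity coefficient of
component $I$ in a liquid mixture is

$$\ln\gamma_I = \ln\gamma_I^R + \ln\gamma_I^C,$$

where the residual part weighs segment-level local-composition activity
coefficients $\Gamma_m$ (the multicomponent NRTL expression applied in
segment space, with the mixture's segment fractions) against the same
quantity evaluated at the pure component's own segment composition,

$$\ln\gamma_I^R = \sum_m r_{m,I}\left[\ln\Gamma_m^{lc} -
\ln\Gamma_m^{lc,I}\right],$$

and the combinatorial part is the Flory–Huggins size correction with
segment-number-weighted volume fractions
$\varphi_I = r_I x_I / \sum_J r_J x_J$:

$$\ln\gamma_I^C = 1 + \ln\frac{\varphi_I}{x_I} - r_I\sum_J
\frac{\varphi_J}{r_J}.$$

The five parameterized segment pairs carry fixed, temperature-independent
constants $\tau_{ij}$, $\alpha_{ij}$ (with $G_{ij} = e^{-\alpha_{ij}
\tau_{ij}}$); `nrtl_interactions()` holds them and allows per-pair
overrides. The pair $Y^-/Y^+$ and the diagonal are not parameterized and
take $\tau = 0$, $G = 1$. A temperature dependence of $\tau$ is deliberately
not provided.

**Solid–liquid equilibrium.** Saturation is modeled by the simplified SLE
relation

$$\ln x_{sat} = \frac{\Delta H_{fus}}{R}\left(\frac{1}{T_{mp}} -
\frac{1}{T}\right) - \ln\gamma_{sat},$$

which neglects the $\Delta C_p$ sensible-heat terms of the full expansion
(their contribution is small relative to the fusion term over the modest
temperature spans of solvent screening). Only this simplified form is
implemented. $R = 8.314$ J/mol/K exactly, so results are bit-stable across
machines; $\Delta H_{fus}$ is carried in kJ/mol at every interface and
converted internally.

**Estimation.** Given a small solubility dataset (typically four solvents
at three temperatures — twelve points), the solute's segment numbers and,
where not measured, its melting properties are estimated by minimizing

$$SSE = \tfrac12 \sum (x^{expt} - x^{model})^2$$

subject to box bounds: $r_m \in [0, 5]$, $\Delta H_{fus} \in [1, 1000]$
kJ/mol, $T_{mp} \in [273.15, 500]$ K.

## Numerical choices

* **Segment-space sums.** Every term of the local-composition expression is
  weighted by a segment fraction, so segments absent from every molecule
  drop out of all sums automatically; no special-casing is required, and
  $\Gamma_m$ remains well defined for a segment present only in the (dilute)
  solute. Dilute limits are evaluated at a documented mole-fraction floor of
  $10^{-12}$ rather than symbolically. At $x_I = 0$ the combinatorial ratio
  $\varphi_I/x_I$ is evaluated analytically as $r_I/\sum_J r_J x_J$.
* **SLE solver.** Because $\gamma_{sat}$ depends on $x_{sat}$, the SLE
  relation is a fixed-point problem. It is solved by damped successive
  substitution (start at the ideal solubility, damping 0.5, tolerance
  $10^{-10}$ on the log-space residual, at most 500 iterations) with a
  bisection fallback on the residual over $x \in (10^{-12}, 1]$ whenever
  substitution fails to contract. Converged points satisfy
  $|\ln x_{sat} - \ln x_{ideal} + \ln\gamma(x_{sat})| \le 10^{-10}$; this is
  asserted in the returned record. Temperatures above $T_{mp}$ are treated
  as out of domain (no solid phase), not extrapolated. Solubilities whose
  true value lies below the $10^{-12}$ floor are reported as non-converged
  rather than silently clamped.
* **Bound handling.** The simplex optimizer is unconstrained, so bounds are
  imposed through the smooth surjection
  $\theta_i = lb_i + (ub_i - lb_i)\sin^2 u_i$; its inverse is used to map
  start points. This keeps every candidate inside the physical box without
  penalty cliffs at the boundary (bound-hugging optima appear as the
  banding visible in landscape plots).
* **Multistart search.** Start points are uniform on the box under a
  recorded seed, drawn prefix-stably (the first $k$ of $n$ starts equal a
  $k$-start sample), which makes the best objective provably non-increasing
  in the number of starts. Each local search is Nelder–Mead
  (`stats::optim`, `reltol` $10^{-12}$, at most 2000 iterations per round)
  restarted from its own endpoint until the objective stops improving —
  the standard guard against premature simplex collapse — so each start's
  final value is a deterministic function of its start point. Ties are
  broken by first occurrence. The default is 1000 starts; the bundled
  verification runs use 200, which reproduce the generating curves of the
  synthetic fixture to well below 1% at every design point.
* **Failed model points.** A candidate parameter vector can push a design
  point out of domain ($T > T_{mp}$) or below the representable floor; such
  points contribute a constant $10^6$ penalty so the objective stays finite
  and the simplex keeps moving. Plateaus of this penalty are visible as the
  topmost bands of the multistart landscape.

## The synthetic-data generator

No experimental solubility table ships with the package, so all testing is
against `simulate_solubility()`, which emulates the structure of a minimal
screening study:

* a panel of four synthetic solvents (`make_solvent_library()`), one
  dominated by each conceptual segment, mirroring the design principle that
  a minimal panel should span hydrophilic, polar and hydrophobic character;
* three temperatures, 293.15/303.15/313.15 K — twelve records per solute;
* a generating solute (`default_theta_true()`: $r = (0.8, 0.2, 0.1, 1.5)$,
  $\Delta H_{fus} = 42$ kJ/mol, $T_{mp} = 415$ K), typical of small-molecule
  intermediates;
* multiplicative lognormal noise,
  $x^{exp} = x^{true} e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$
  with $\sigma = 0.05$ by default, because solubilities span orders of
  magnitude and measurement error scales with the value;
* optionally one *degrading* solvent whose records are biased low
  (default $\times 0.5$) and flagged `exclude = 1`, emulating a
  solute/solvent pair where decomposition corrupts the measurement. Flagged
  records are dropped from both the fit and the bracketed RMSLE by default
  (`exclude_fit = FALSE` switches to evaluation-only exclusion).

What the generator does *not* emulate: kinetic degradation profiles,
protocol-specific error structure (gravimetric vs HPLC), solvate or
polymorph formation, and mixed solvents. Passing tests therefore
demonstrate the correctness and internal consistency of the machinery on
data that obey the model family, not predictive accuracy on real
measurements.

## Scale of the objective, and what RMSLE can tell you

The printed estimation objective is on mole fractions. When a solute's
solubility spans several decades across the panel (the synthetic fixture
spans roughly $10^{-5}$ to $5\times10^{-2}$), an $x$-scale SSE gives the
low-solubility solvents almost no weight: their *log*-scale errors are then
essentially unconstrained, and fitted RMSLE values of order 1–6 coexist
with SSE values of order $10^{-9}$–$10^{-4}$. This is a property of the
objective, not a defect of the optimizer, and the same signature appears in
published NRTL-SAC parameterizations of wide-dynamic-range solutes. For
workflows where log-scale accuracy matters (e.g. ranking solvents for a
poorly soluble compound), `nrtlsac_fit(..., log_residuals = TRUE)` switches
the objective to $\ln x$ residuals, which is also the maximum-likelihood
scale for the generator's lognormal noise; the package's noise-consistency
test uses it for exactly that reason.

## Free vs fixed melting properties

When calorimetry gives a clean melting point, fix it
(`fix = list(t_mp = ...)`) and estimate the four segment numbers and
$\Delta H_{fus}$; this is the configuration used for the bundled
verification runs. Melting-property estimation from solubility data alone
(leaving `t_mp` free) is supported and is the only option when
decomposition near the melting point defeats DSC, but with twelve points
and six free parameters the raw parameters may be only weakly identified —
recovery should be judged on predicted solubility curves, not on individual
parameter values. The bundled published parameter set
(`adavosertib_parameters()`, `adavosertib_thermo()`) illustrates both
configurations: two compounds carry fitted melting temperatures, four carry
measured ones.

## Verification problem sizes

The packaged checks run the residual-term oracle on a 99-point composition
grid for all five segment pairs, Gibbs–Duhem consistency on 20 random
binary systems (central differences, $h = 10^{-5}$), the SLE solver against
a high-precision bisection oracle on 50 random solute/solvent/temperature
triples, a 200-start noiseless recovery fit, a 50-start degrading-solvent
fit, and forward prediction of all six bundled solutes over the synthetic
panel (72 curve points). `scripts/acceptance.R` re-runs all of these from
scratch against the installed package and writes the resulting quantities
to JSON.

## Known limitations

* Solvent segment parameters for real solvents are user input: the package
  ships only a template, because published solvent parameter tables are the
  property of the original model literature and must be transcribed by the
  user (`read_solvent_library()` validates them).
* Electrolyte extensions, temperature-dependent $\tau$, mixed solvents,
  solid phases other than the pure stable solid, and uncertainty
  quantification beyond the multistart trace are out of scope.
* The $10^{-12}$ mole-fraction floor bounds the representable solubility
  range; candidates below it are reported as failures, which is the correct
  behavior inside the penalized objective but means extremely insoluble
  systems cannot be solved to equilibrium.
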