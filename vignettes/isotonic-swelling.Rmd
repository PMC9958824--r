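---
title: "Isotonic swelling of neurons: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotonic swelling of neurons: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoswell)
```

## The model

Brain tissue is idealised as two well-stirred compartments of fixed total
volume $V = 1$ l: interstitial (extracellular) space with volume fraction
$\tilde\alpha$ (physiological value $\alpha = 0.25$) and the neuronal
interior, separated by a movable semi-permeable membrane. The state
variables are the extracellular volume and the extracellular concentration
of each permeant species; the intracellular values follow from conservation
of total volume and of the per-species particle numbers. Solutions are
ideal (no activity coefficients), the system is closed (no sources, sinks
or buffering), and the membrane potential is neglected in the energy
balance — it stores only a vanishing fraction of the energy held in the
concentration gradients, and as a consequence of the gradients it cannot
shift the equilibria themselves.

Five species are modelled by default (`physiological_ions()`): Na⁺, K⁺,
Cl⁻, HCO₃⁻ and one impermeant monovalent anion species A⁻ representing
charged metabolites and macromolecules. A⁻ is a *single* species with two
non-exchanging pools, 10 mM outside and 134 mM inside; its confinement is
what blocks complete mixing at fixed volume. Divalent ions are excluded by
default: their physiological concentrations (< 2 mM) contribute negligibly
to the energy budget and they are handled by separate pumps. The `valence`
field is nevertheless generic, so user tables may include them — the Donnan
solver handles arbitrary integer valences, but only monovalent tables are
validated against reference values.

### The co-transport mixing rule

Water crosses the neuronal membrane stoichiometrically with solute
(neurons lack functional aquaporins), so each species $K$ moves with a
fixed solvent-to-solute ratio $a_K$, equivalently a constant *transport
concentration* $c_K = 1/a_K$ — the moles of $K$ per litre of co-moving
water, negative when ion and water move oppositely, zero for impermeants.
Writing $w = \tilde\alpha/\alpha$ and $y = (1-\tilde\alpha)/(1-\alpha)$ for
the relative volume changes, integrating the rule gives hyperbolic
concentration–volume laws,

$$K_o = c_K - \frac{c_K - K_o^*}{w}, \qquad
  K_i = c_K - \frac{c_K - K_i^*}{y},$$

with impermeants following pure volume rescaling ($K_o^*/w$, $K_i^*/y$).
An immediate consequence is that every extracellular concentration is
linear in $1/w$, so any two species trace a straight line against each
other with slope equal to the ratio of their physiological gradients
(`interion_slope()`); this is the model's main testable prediction for
ion-concentration time courses.

### Choosing the endpoint: full equilibrium

The path endpoint is the volume at which the impermeant-anion
concentrations equalise, $A_o^*/w = A_i^*(1-\alpha)/(1-w\alpha)$, solved in
closed form as $w_e = A_o^*/(A_i^*(1-\alpha) + \alpha A_o^*)$
(`solve_full_equilibrium()`; inputs with the impermeant pool dominating
*outside* have no shrinkage solution in $(0,1]$ and are rejected with an
explicit error). There, nothing blocks complete mixing: every permeant
species reaches its volume-weighted mean $K_e = \alpha K_o^* +
(1-\alpha)K_i^*$ and all Nernst potentials vanish. Back-substituting the
endpoint into the mixing rule fixes the transport plan
$c_K = (K_o^* - w_e K_e)/(1 - w_e)$, which is automatically isotonic
($\sum c_K$ equals the initial total concentration) and electro-neutral
($\sum z_K c_K = 0$). Both endpoint formulas (outer- and inner-compartment)
give identical $c_K$ by particle conservation; the test suite checks this
to 1e−12 on randomized tables. Given such a plan, *all* intermediate
states are isotonic and electro-neutral — the suite verifies this
numerically on 1000-point volume grids to below 1e−9 mM rather than
re-deriving the formal proof.

### Donnan equilibria

For comparison, `donnan_equilibrium()` computes the passive equilibrium at
any fixed volume: one ratio $\rho$ with $K_i = K_o\,\rho^{-z}$ for every
permeant species, per-species totals fixed, impermeants rescaled by volume,
and the outside compartment electro-neutral (the inside then follows from
global charge conservation). The Donnan potential is $(RT/F)\ln\rho$,
reported inside-minus-outside; with the anion excess inside, $\rho < 1$ and
the potential is negative (≈ −18 mV at the physiological volume). The
Donnan state is *not* isotonic except exactly at $w_e$, where it coincides
with the full-equilibrium endpoint of the isotonic path; the osmotic
imbalance changes sign there, which is also where the potential's polarity
reverses along the volume axis.

## Energetics

The Gibbs energy retrieved by reversibly transferring species $K$ is
$\Delta G = RT\!\int \ln(K_o/K_i)\, d(K_oV_o)$, with the closed form

$$\frac{\Delta G}{RT} = V_o^*K_o^*\ln K_o^* - wV_o^*K^\circ\ln K^\circ
 + V_i^*K_i^*\ln K_i^* - yV_i^*K^\circ\ln K^\circ
 + V_o^*(c_K - K_o^*)\ln w + V_i^*(c_K - K_i^*)\ln y.$$

The first four terms are the drop in chemical potential energy; the last
two are minus the osmotic (pressure–volume) work the species does in
displacing the membrane, $RT\!\int K\,dV$ over both compartments. The
package evaluates all three pieces separately (`mixing_work_closed()`,
`osmotic_work()`) and the suite asserts the word equation
*mixing = chemical drop − osmotic work* term by term. Per species the
osmotic works are large — K⁺ and A⁻, whose high-concentration compartment
swells, do osmotic work; Na⁺ and Cl⁻ receive it, which keeps their
gradients high and enhances their work of mixing — but on the isotonic path
the per-species contributions cancel exactly in the total, because the
energy moving water into the neurons is supplied by the co-transported
ions' gradients.

Two reference scenarios complete the comparison: complete mixing at
constant volume with the impermeants made permeant
(`isochoric_complete_mixing()`), which reaches the same final
concentrations and therefore the same total work with a different
per-species split; and mixing to the Donnan equilibrium at an arbitrary
volume (`work_to_donnan()`), for which a per-volume transport plan is
recomputed from the endpoint conditions. `find_equal_work_volume()` locates
the volume at which the isotonic path has released as much energy as the
fixed-volume Donnan transition.

## Numerical choices

* **Units.** Concentrations are mM (numerically mol m⁻³); volumes are
  fractions of the fixed 1-litre tissue volume; energies are J per litre of
  tissue (mM × J mol⁻¹ × 10⁻³). All logarithms are natural. Defaults:
  R = 8.3145 J mol⁻¹ K⁻¹, T = 310 K, F = 96485 C mol⁻¹, water molarity
  55.6 M, 133.322 Pa/mmHg.
* **Public coordinate.** The extracellular volume fraction $\tilde\alpha$
  (not $w$) is the argument of every sweep function, matching how volume
  data are reported; $w = \tilde\alpha/\alpha$ internally.
* **Donnan root finding.** The outside electro-neutrality residual is
  strictly increasing in $\rho$ (each term $z_K K_o(\rho)$ is), so the root
  is unique; Brent's method on $\log\rho$ over $[\log 10^{-8}, \log 10^8]$
  with tolerance 1e−15 recovers it to ~1e−14. A 10⁶-point log-grid search
  serves as the brute-force oracle in the tests.
* **Validity of the path.** The hyperbolae cross zero at
  $w_0 = (c_K - K_o^*)/c_K$ (outer) or the corresponding $y_0$ (inner);
  `validity_range()` takes the largest crossing over species. On the
  default plan this is Cl⁻ at $\tilde\alpha \approx 0.0174$, a hair before
  Na⁺ at 0.0172 — both consistent with the loss of physical solutions
  below ≈ 0.02. Out-of-range requests raise an error naming the depleting
  species; silent clamping would corrupt the conservation audits. States
  between the validity bound and the equilibrium volume are allowed (they
  carry a `below_equilibrium` attribute) since the curves are conventionally
  plotted through that segment.
* **The $c_K \to 0$ limit.** For impermeants, $a_K = 1/c_K$ is undefined,
  but the energy formulas only need the products $C/a_K = V_o^*(c_K-K_o^*)$
  and $D/a_K = V_i^*(c_K-K_i^*)$, which are finite at $c_K = 0$; evaluated
  there, the closed form cancels to exactly zero mixing work and the
  osmotic terms reduce analytically to the pure-rescaling integrals. No
  numerical limit is taken. Boundary states with a concentration exactly
  zero use the $x\ln x \to 0$ limit; negative concentrations error.
* **Quadrature oracle.** `mixing_work_numeric()` integrates
  $RT\,\alpha\,c_K \ln(K_o/K_i)\,dw$ by composite trapezoid with 10⁵ panels
  by default — the integrand is smooth and monotone on the path, so the
  trapezoid error is far below the 1e−6 relative agreement the suite
  demands, and halving the step provably shrinks it. It is an independent
  check of the closed form, not the production route.
* **Equal-work volume.** Bisection/Brent on $\tilde\alpha$ to machine
  tolerance; the returned volume satisfies the work equation to < 1e−9 J/l.
* **Audit tolerances.** 1e−9 mM absolute for states the model computes
  (round-off scale for ~300 mM quantities), 0.1 mM when auditing states
  rebuilt from rounded printed tables.
* **Problem sizes.** The suite runs 1000-point path audits, 10⁵–10⁶-step
  quadratures, a 10⁶-point Donnan grid oracle and a few dozen randomized
  tables; the whole suite completes in seconds on one core.

## Configuration, fixtures and reports

Scenarios load from YAML/JSON (`load_scenario()`): an ion table, $\alpha$,
temperature, optional transport-concentration overrides and a sweep grid.
Configurations are audited for electro-neutrality and isotonicity *before*
any computation (tolerance 1e−6 mM, so a deliberate 1 mM imbalance fails);
the packaged fixture `physiological.yaml` reproduces the default table
exactly. The extracellular A⁻ pool is treated as impermeant everywhere —
nothing in the model's scope motivates letting it cross the membrane, and
an exchanging A⁻ would simply merge into the permeant anion budget.
`run_report()` writes deterministic CSV/JSON tables (concentrations to
0.01 mM, energies to 0.1 J/l, no timestamps in data files; a `.log.json`
sidecar carries the config hash and constants), and
`inst/cli/isoswell.R` exposes the same commands from the shell. Plotting
(`plot.swell_model()`) is a convenience; the data tables are the canonical
artifact.

Transport-plan overrides support exploring alternative isotonic paths: for
example `swell_model(c_override = c(Na = 179, K = -27))` shifts 20 mM of
cation transport from K⁺ to Na⁺. The plan stays isotonic and
electro-neutral, but extracellular Na⁺ now depletes at
$\tilde\alpha \approx 0.043$, before the impermeant anions can equalise, and
the truncated path retrieves strictly less work than the full-equilibrium
plan. Because such truncated paths end wherever their first species
depletes, the package asserts only the inequality (less work than the
optimal plan), not a specific endpoint value.

## What the checks do and do not show

All reference values are desk-scale consequences of the printed
physiological table, so the tests validate the implementation exactly
against its own mathematics (closed forms vs independent quadrature and
grid searches, conservation theorems on fine grids) and against the
published table-level anchors. They do *not* validate the model against
experimental ion or volume measurements: real tissue has glia (unmodelled;
arguments exist for lumping them with either compartment), ion buffering
and CO₂/pH chemistry (HCO₃⁻ totals are not conserved in ischemia),
divalents, a membrane potential, and kinetics. The model is an equilibrium
description without a time scale — it applies to processes slow enough for
chemical potentials to equilibrate but fast enough that total volume and
particle numbers are conserved, on the order of minutes for ischemic
swelling. Within that envelope its falsifiable predictions are the linear
inter-ion relations and the isotonicity of the swelling path itself.
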