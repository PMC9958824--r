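# isoswell

An equilibrium-thermodynamic model of cytotoxic neuronal swelling — the
early, blood-brain-barrier-independent cell swelling seen during energy
deprivation, ischemia and spreading depolarization — for biophysicists and
modellers of brain ion homeostasis.

Brain tissue is treated as two compartments of fixed total volume (1 l):
interstitial space (volume fraction α = 0.25) and the neuronal interior,
separated by a movable semi-permeable membrane. Four permeant monovalent
species (Na⁺, K⁺, Cl⁻, HCO₃⁻) and one impermeant anion species A⁻ (charged
metabolites and macromolecules, 10 mM outside / 134 mM inside) start from an
electro-neutral, isotonic physiological state (304 mM on both sides). When
the Na⁺/K⁺ pump fails, the ions mix.

The usual assumption is that mixing runs toward a **Donnan equilibrium**, at
which all permeant species share one Nernst (Donnan) potential but the total
solute concentration is far higher inside than outside (a ~171 mM imbalance,
i.e. hundreds of mmHg of osmotic pressure). Neurons, however, lack
functional aquaporins: they move water stoichiometrically with ions through
co-transporters such as KCC2. `isoswell` implements the alternative
**isotonic path**: each species K is co-transported with water at a constant
concentration c_K (mM of ion per litre of co-moving water), chosen so that
the path ends at the volume ω where the impermeant-anion concentrations
equalise and *all* permeant gradients vanish. Every intermediate state is
then isotonic and electro-neutral.

The core relations, with w = α̃/α and y = (1−α̃)/(1−α) the relative volume
changes of the outer and inner compartment:

* concentration–volume laws: `Ko = c_K − (c_K − Ko*)/w`,
  `Ki = c_K − (c_K − Ki*)/y` (hyperbolae in the volumes; impermeants follow
  pure rescaling `Ko*/w`, `Ki*/y`);
* transport concentrations from the endpoints:
  `c_K = (Ko* − w_e K_e)/(1 − w_e)` with
  `K_e = α Ko* + (1−α) Ki*`;
* work of mixing (Gibbs energy retrieved, J per litre of tissue):
  `ΔG/RT = Vo*Ko*ln Ko* − w Vo*K°ln K° + Vi*Ki*ln Ki* − y Vi*K°ln K° +
  Vo*(c_K−Ko*)ln w + Vi*(c_K−Ki*)ln y`, whose last two terms are the
  (negative of the) osmotic pressure–volume work;
* Donnan equilibria at any volume: a single ratio ρ with
  `Ki = Ko ρ^(−z)`, solved from outside electro-neutrality, Donnan
  potential `(RT/F) ln ρ`.

## Worked example

```r
library(isoswell)
m <- swell_model()   # physiological ion table, alpha = 0.25, 310 K
m
#> Isotonic two-compartment swelling model
#>   5 ion species, alpha = 0.25, T = 310 K
#>   Full equilibrium: w_e = 0.0971, omega = 0.0243, y = 1.3010
#>   Path valid down to alpha_tilde = 0.0174 (Cl depletes)
#>   Transport concentrations c_K (mM):
#>    Na     K    Cl  HCO3     A
#> 159.0  -7.0 121.5  30.5   0.0
```

At full equilibrium the extracellular space has shrunk to 9.7 % of its
initial volume (2.4 % of the tissue) and the neurons have swollen by 30 %.
The transport plan says Na⁺ and Cl⁻ ride into the neurons with the water at
high concentration, while K⁺'s slightly negative c_K means its net transport
opposes the water flow; the plan totals 304 mM (isotonic) with zero net
charge. One litre of co-moving water carries 304 mmol of ions, i.e. ≈183 H₂O
per ion, or 458 H₂O per Cl⁻ if all water used one carrier —
`water_per_ion(m)`.

```r
donnan_equilibrium(m, 0.25)
#> Donnan equilibrium at alpha_tilde = 0.2500
#>   rho = 0.506376, Donnan potential = -18.18 mV
#>  species valence conc_out conc_in
#>       Na       1    26.57   52.48
#>        K       1    61.23  120.92
#>       Cl      -1    54.38   27.54
#>     HCO3      -1    23.42   11.86
#>        A      -1    10.00  134.00
#> Totals: outside 175.61 mM, inside 346.80 mM
#>   Inside - outside total: 171.2 mM
```

The Donnan state at the physiological volume carries a 171 mM solute excess
inside — via `vant_hoff_pressure(171)`, an osmotic load of ≈0.44 MPa. The
isotonic path avoids this entirely:

```r
isotonic_energy(m)
#> Energy breakdown (isotonic scenario, alpha_tilde = 0.0243)
#>  species mixing_J_per_l osmotic_J_per_l
#>       Na          138.5           -58.3
#>        K            8.6            58.3
#>       Cl          109.4           -45.0
#>     HCO3           13.3            -8.1
#>        A            0.0            53.1
#> Totals: mixing 269.8 J/l, osmotic -0.0 J/l
```

Mixing along the full path yields 269.8 J per litre of tissue — identical to
complete isochoric mixing (`isochoric_complete_mixing(m)`), but distributed
differently: the swelling transfers osmotic work from K⁺ and the impermeant
anions to Na⁺ and Cl⁻, whose gradients are thereby kept high while they mix.
Stopping at a Donnan equilibrium at constant volume instead releases only
197 J/l (`work_to_donnan(m, 0.25)`), an amount the isotonic path has already
matched once the extracellular space has halved
(`find_equal_work_volume(m)` ≈ 0.116).

`predict(m, alpha_tilde)` and `plot(m)` give the concentration–volume
curves, `residuals(m)`/`audit_path(m)` verify that every intermediate state
stays isotonic, electro-neutral and particle-conserving to < 1e−9 mM, and
`run_report()` (or the CLI `inst/cli/isoswell.R`) writes the standard
tables and figure data as CSV/JSON. Scenarios, including transport-plan
overrides, load from YAML/JSON via `load_scenario()`; see
`inst/extdata/physiological.yaml`.

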