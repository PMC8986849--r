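# prekin

Binding and exchange kinetics of paramagnetic metallohost–guest systems
from **paramagnetic relaxation enhancement (PRE) NMR**.

Paramagnetic hosts — e.g. a manganese(III) porphyrin cage that threads and
binds viologen guests — broaden their own NMR resonances so severely that
the standard toolbox (EXSY, titration by chemical shift) fails. The PRE of
the *free* guest and of a reporter solvent is still measurable, and it
carries both the thermodynamics and the kinetics of the host–guest
equilibrium. `prekin` implements the complete inference chain from raw
relaxation decays to association constants, residence times, dissociation
rate constants and activation parameters, for practitioners of
supramolecular, biophysical or medicinal NMR.

## The model

Observed relaxation rates (either channel, R1 or R2) split into a
diamagnetic baseline and a paramagnetic contribution,

```
R_obs = R_0 + R_p
```

and the paramagnetic part into inner-sphere (binding) and outer-sphere
(distant, non-binding) terms:

```
R_p = f / (tau_M + T_M) + R_os
```

where `f` is the bound mole fraction of the observed species, `tau_M` the
mean residence time of the guest on the host, `T_M` the relaxation time of
the bound state, and `R_os` is measured empirically with a cavity-blocked
rotaxane control. In the slow-to-intermediate exchange regime `tau_M`
dominates (`T_M` negligible), so after outer-sphere correction

```
R_inner = f / tau_M      =>      tau_M = f / R_inner,   kd_obs = 1 / tau_M
```

Three diagnostics must hold before this simplification is trusted:
`R_p` increases with temperature, `R_p` is field-independent, and
`R2_p ≈ R1_p` ([`diagnose_regime()`]). Dissociation rate constants,
corrected for an apparent reaction order in guest concentration, feed an
Eyring regression `ln(k/T) ~ 1/T` for `ΔH‡` and `ΔS‡`; threading rates
follow from `k_on = Ka · k_d` and `ΔG‡ = −RT ln(k_on h / kB T)`.

The association constant comes from a solvent-reporter titration: the bulk
chloroform rate falls from `R_empty` to `R_sat` as guest displaces the
reporter from the cavity, linearly in the exact 1:1 occupancy
([`fit_titration()`]).

## Worked example

A full synthetic study with known ground truth (`Ka = 4796 M⁻¹`,
`ΔH‡ = 8.35 kcal/mol`, `ΔS‡ = −17.57 cal/(K mol)`, order 0.3, 1% intensity
noise) analysed end to end:

```r
library(prekin)
gt <- ground_truth(noise_sigma = 0.01, T_M1 = 0, T_M2 = 0, seed = 11)
study <- simulate_study(gt, seed = 11)
report <- run_pipeline(study)
print(report)
#> <pre_study_report>
#>   diagnostics verdict: tau_M_dominated
#>   binding: log10(Ka) = 3.709 +/- 0.030, dG = -5.06 kcal/mol
#>   threading evidence: ratios 174.55 / 123.44 -> TRUE
#>   guest reaction order n = 0.309 +/- 0.004
#>   dissociation: dH+ = 8.32, dS+ = -17.69, dG+(298.1 K) = 13.59 kcal/mol
#>   threading: k_on = 3.47e+06 M^-1 s^-1, dG+ = 8.53 kcal/mol
```

The recovered `log10(Ka) = 3.709` (truth 3.681), `ΔH‡ = 8.32` and
`ΔS‡ = −17.69` sit within the reported uncertainties of the generating
values; the diagnostics verdict confirms the residence-time-dominated
regime, and the threading-evidence ratios (`R_obs/R_os ≫ 1`) show that
inner-sphere exchange — hence guest threading — is occurring.
`render_tables(report, "out/")` writes the binding, activation and
threading summary tables as CSV plus a JSON report.

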