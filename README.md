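# adipoflux

Quantitative bookkeeping of catabolic substrate fluxes in plate-cultured brown
adipocytes.

Brown adipocytes dissipate chemical energy as heat. In plate-based
extracellular-flux assays their activation is read out as oxygen consumption
(OCR) and extracellular acidification, while supernatant assays supply
metabolite release rates. Interpreting those readouts quantitatively requires
explicit stoichiometric bookkeeping: ECAR is *not* glycolytic flux (carbonic
acid and exported fatty acids acidify too), glucose uptake is *not* glycolytic
supply (glycogen contributes), and glycerol/FFA release only constrains — not
equals — lipolysis. `adipoflux` implements that bookkeeping as a tested
pipeline for researchers running respirometry on adipocytes (or any highly
lipolytic cell model).

## The model

All rates are areal fluxes in nmol·h⁻¹·cm⁻². For each condition (genotype ×
treatment) the package derives, per well:

- **CO₂ production** from respiration, `J_CO2 = RQ · J_O2`, with RQ = 0.7 for
  fat oxidation (a table-calibrated alternative of 0.62 is provided);
- **proton production sources**: carbonic acid `J_H,CO2 = 0.65 · J_O2` (net
  H⁺/O₂ for palmitate, 0.65 = (16/23) × hydrated fraction 0.934, overall
  pKa 6.093 at 37 °C), plus one H⁺ per exported lactate and per exported FFA;
- **β-oxidation upper bound** `J_FFA,ox = J_O2 / 23` (23 mol O₂ per mol
  palmitate; energetic mode `J_O2 · 431/9800` agrees within 1.2 %);
- **re-esterification (futile cycle)**
  `J_reest = 3·J_glycerol − (J_FFA,release + J_FFA,ox)`, signed, flagged when
  below zero;
- **TAG hydrolysis**
  `J_TAG = (J_FFA,release + J_FFA,ox + J_reest)/3`, which reduces
  algebraically to glycerol release;
- **glycogen mobilization** `J_glycogen = J_lactate/2 − J_glucose,uptake`
  (lower bound on glycolytic demand), independently measurable as the slope
  of a glycogen time course in 162 g/mol anhydroglucose units.

Respirometry traces are segmented around oligomycin / isoproterenol / FCCP /
antimycin A injections into phase means and classical respiration components
(coupled, non-mitochondrial, iso-induced, maximal), including the
oligomycin-sensitivity contrast of the adrenergic response that distinguishes
UCP1-dependent from ATP-dependent thermogenesis.

A seeded synthetic plate generator (`synthetic_truth()`,
`simulate_experiment()`) produces traces, metabolite rates and glycogen time
courses with known ground truth at the magnitudes of the bundled reference
dataset (`reference_fluxes()`), so the whole pipeline is testable end to end
and supports parameter-recovery experiments.

## Worked example

```r
library(adipoflux)

truth <- synthetic_truth(seed = 42)        # reference magnitudes, 10% well noise
sim   <- simulate_experiment(truth)        # traces + metabolites + glycogen
fit   <- flux_model(assemble_wells(sim))   # segment, derive per well, aggregate
fit
#> Substrate-flux bookkeeping fit: 48 wells, 8 conditions
#>   FFA oxidation mode: stoichiometric; CO2 per O2: 0.7 (rq)
#>   below-zero re-esterification in: KO:oligo_basal, KO:oligo_iso

round(coef(fit)[c("WT:basal", "WT:iso"),
      c("glycerol_release", "ffa_release", "ffa_oxidized",
        "ffa_reesterified", "tag_hydrolyzed", "o2_consumption")], 1)
#>          glycerol_release ffa_release ffa_oxidized ffa_reesterified
#> WT:basal              7.1        15.7          2.1              3.6
#> WT:iso               28.6        66.2          6.8             12.6
#>          tag_hydrolyzed o2_consumption
#> WT:basal            7.1           47.7
#> WT:iso             28.6          157.0

compare_conditions(fit, "tag_hydrolyzed", c("WT", "basal"), c("WT", "iso"))$fold
#> [1] 4.01       # ~4-fold lipolysis increase on adrenergic stimulation

recovery_report(truth, fit)
#>           quantity n_conditions        bias       rmse   rel_rmse
#> 1 glycerol_release            8  0.40685717 0.90933922 0.02725082
#> 2      ffa_release            8 -1.04462521 2.01099368 0.05313093
#> 3   o2_consumption            8 -2.15560158 4.70102353 0.04143192
#> 4   glucose_uptake            4  0.02225238 0.07254524 0.02303640
#> 5  lactate_release            8 -1.52731496 4.58211163 0.04311629
```

Reading the numbers: stimulated WT wells hydrolyze ~28.6 nmol TAG·h⁻¹·cm⁻²
(a four-fold rise over basal), oxidize at most ~7 nmol FFA·h⁻¹·cm⁻² of the
~86 nmol liberated (< 10 %), and re-esterify ~13 — the futile cycle. With six
wells per condition and 10 % well-level noise, measured rates are recovered
to ~2–5 % relative RMSE. In the Ucp1-KO oligomycin blocks the re-esterified
flux drops below zero (flagged, displayed as `<0`), reflecting a
β-oxidation bound taken at its maximum.

`residuals(fit)` gives the unexplained part of measured proton production
after the CO₂ + lactate + FFA decomposition; `summary(fit)` prints the full
condition table, and `write_flux_table()` exports it as TSV (display
convention, `<0` cells) or JSON (numeric + flags).

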