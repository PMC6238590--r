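---
title: "Substrate-flux bookkeeping in brown adipocytes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-flux bookkeeping in brown adipocytes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoflux)
```

## The problem

Plate respirometry of brown adipocytes yields two instrument readouts —
oxygen consumption rate (OCR) and proton production rate (PPR, the
buffer-corrected acidification rate) — around a standard injection protocol
(oligomycin, isoproterenol, FCCP, antimycin A). Supernatant assays add
glycerol, free fatty acid (FFA) and lactate release, and a radiotracer assay
adds glucose uptake. None of these is, by itself, the flux a physiologist
wants: glycolysis, lipolysis, β-oxidation, futile FFA cycling and glycogen
mobilization all have to be *derived* by stoichiometric bookkeeping.
`adipoflux` implements that bookkeeping with explicit, overridable constants
and a synthetic-data path that makes every derivation testable against known
ground truth.

The canonical unit throughout is the areal rate nmol·h⁻¹·cm⁻²; per-cell,
per-µg-protein and mass bases are views obtained through `convert_rate()`
with the culture geometry (89 µg protein and 82,916 pg DNA ≙ 13,819 cells
per cm², at 6 pg DNA per cell).

## Model and assumptions

**Respiration components.** Traces are segmented into inter-injection phase
means (`segment_phases()`), discarding the first post-injection cycle as a
mixing transient (`skip_first = 1`; averaging rules are an assay-practice
choice, not an instrument mandate). Components follow the classical
definitions: non-mitochondrial = post-antimycin A; coupled = drop upon
oligomycin relative to the phase immediately before it; iso-induced = rise
over the phase immediately before the isoproterenol injection; maximal =
post-FCCP. The protocol order is data, not hard-coded, because the
oligomycin-sensitivity experiment needs both injection orders. Negative
derived components are preserved with QC flags, never clamped — with one
deliberate exception: `oligo_sensitivity()` contracts to a fraction in
[0, 1], so it clamps and *reports* the clamp via an attribute. A clamped
zero is informative: it means the adrenergic response under oligomycin was
at least as large as the free response, the signature of ATP-synthesis-independent
(UCP1-mediated) thermogenesis.

**Acidification.** Three sources are modeled. (1) Respiratory CO₂ hydrates
to carbonic acid and dissociates; the equilibrium fraction follows
Henderson–Hasselbalch with the overall pKa 6.093 of CO₂ in water at 37 °C.
The *net* H⁺ per O₂ is fixed at 0.65 for complete palmitate oxidation.
We do **not** recompute this coefficient from medium pH: at pH 7.4 the
equilibrium hydrated fraction is 0.953, which with the palmitate
stoichiometry 16/23 would give 0.663. The fixed 0.65 corresponds to a
realized hydrated fraction of 0.934 ((16/23) × 0.934 ≈ 0.65), i.e. dissolved
CO₂ is not completely hydrated on assay timescales. Both routes are exposed
(`hydrated_fraction()`, `h_per_o2_from_parts()`, the `h_per_o2` argument of
`ppr_from_co2()`); the default reproduces the fixed coefficient.
(2) Lactate and (3) exported FFAs dissociate quantitatively at physiological
pH and contribute one H⁺ each. Only *exported* FFAs acidify — oxidized and
re-esterified FFAs never leave the cell. This is equilibrium bookkeeping;
carbonic-anhydrase kinetics and buffering dynamics are out of scope.

**CO₂ per O₂.** The default respiratory quotient is 0.7 (pure fat
oxidation). The package also offers a "calibrated" factor of 0.62
(`co2_mode = "calibrated"`), because in the bundled reference table the
CO₂/OCR ratio is 0.613–0.625 in every condition — a uniform multiplicative
treatment whose basis is not documented in the source. The default stays at
the stated 0.7; the calibrated mode exists to reproduce the reference CO₂
rows.

**Lipid fluxes.** The β-oxidation bound assumes exclusive palmitate
oxidation. Its default mode is stoichiometric (OCR/23), which reproduces
the reference table's stimulated-state values exactly; the energetic mode
(OCR × 431 µJ·nmol⁻¹ O₂ ÷ 9.8 µJ·pmol⁻¹) is retained as an alternative and
agrees within 1.2 %. Re-esterification is
`3·glycerol − (FFA released + FFA oxidized)`; because the oxidation term is
an upper bound, the result can be negative, and it is kept signed with a
`below_zero` flag (reference tables print such cells as "<0"). TAG
hydrolysis is the three-chain sum divided by 3, which composed with the
re-esterification formula reduces *exactly* to glycerol release — this
algebraic identity is the primary oracle for both operations in the test
suite.

**Glycogen.** Glucose demand is lactate/2 — an intentional lower bound that
ignores oxidized pyruvate. Demand minus measured uptake is the inferred
mobilization of internal stores. Independently, a glycogen content time
course gives a flux as its least-squares slope, converted with 162 g/mol
(the anhydroglucose residue in glycogen, not free glucose's 180; the
conversion is the package's choice, stated here because sources rarely
specify it).

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `pka_co2` | 6.093 | — | overall pKa of aqueous CO₂ at 37 °C |
| `rq_palmitate` | 0.7 | mol CO₂ / mol O₂ | pure fat oxidation |
| `h_per_o2_net` | 0.65 | mol H⁺ / mol O₂ | (16/23) × 0.934 realized hydration |
| `o2_per_palmitate` | 23 | mol/mol | complete palmitate combustion |
| `caloric_equiv_o2` / `gibbs_palmitate` | 431 / 9.8 | µJ/nmol, µJ/pmol | energetic oxidation bound |
| `lactate_per_glucose` | 2 | mol/mol | glycolytic yield |
| `dna_per_cell` | 6 | pg | cell-count conversion |
| `mw_tripalmitin` | 807.3 | g/mol | mass views of lipolysis |
| `mw_anhydroglucose` | 162 | g/mol | glycogen → glucose units |
| `area_cm2` | 0.106 | cm² | XF-96 well growth area; always configurable |
| `skip_first` | 1 | cycles | post-injection mixing transient |

All constants are overridable from a YAML run configuration
(`read_run_config()`), which rejects unknown keys so typos cannot silently
revert to defaults.

A documentation note on the mass conversions: 28.2 nmol·h⁻¹·cm⁻² × 807.3
g/mol gives 22.77 µg·h⁻¹·cm⁻², whereas reference texts print 22.9 (implying
~812 g/mol); we keep the tabulated tripalmitin mass and document the ~0.6 %
discrepancy rather than back-fitting the molar mass. Display rounding is one
decimal, half away from zero; chained rounding artifacts (65.45 → "65.5")
are tolerated at printed precision in comparisons, not reproduced.

## What the synthetic generator emulates — and what it does not

`synthetic_truth()` defaults to the bundled reference magnitudes
(`reference_fluxes()`): WT and Ucp1-KO brown adipocytes in four treatment
blocks (basal, isoproterenol, oligomycin, oligomycin + isoproterenol), six
wells per condition, 10 % multiplicative lognormal well noise (a typical
plate CV; multipliers are unit-mean, `exp(N(−σ²/2, σ))`, so estimators stay
unbiased), and 2 pmol·min⁻¹ additive trace jitter. Quantities the reference
does not pin down are fixed once at realistic values: maximal (FCCP)
respiration at 1.25 × the larger of basal and stimulated OCR,
non-mitochondrial respiration at 5 nmol·h⁻¹·cm⁻² (~10 % of basal), an
initial glycogen store of 13.8 µg·cm⁻² (~1 ng per cell at the reference
cell density), and glycogen fluxes of 0 (basal) and −54 nmol
glucose-units·h⁻¹·cm⁻² (stimulated, glucose-free medium).

Traces are piecewise-constant at phase-true levels, generated in both
injection orders (isoproterenol-first and oligomycin-first) with a
four-injection protocol of four 6-min cycles per phase. PPR traces are
generated *from the acidification model itself* (net H⁺/O₂ on the phase OCR
plus the block's lactate and FFA release), so decomposition residuals
isolate pipeline defects rather than model misspecification; an
`unexplained_ppr` term can be injected to exercise residual reporting.

Deliberately **not** simulated: instrument drift, edge-well effects,
CO₂-incubator artifacts, FCCP dose–response shape, within-phase kinetics,
correlated noise between the respirometry and supernatant plates (the two
are drawn independently and paired by well order). Passing recovery tests
therefore demonstrates the correctness of the bookkeeping and its
statistical behavior under idealized plate noise — not robustness to
systematic instrument artifacts in real data.

## Numerical choices and degenerate inputs

- Aggregation is per-well derivation first, then mean ± SD (sample SD,
  n − 1). The reference table's derived rows are mutually inconsistent with
  its measured rows by ~1–2 % in exactly the way per-replicate computation
  predicts, which motivated this order; with identical wells the two orders
  agree exactly, a property the tests assert.
- Missing cells (e.g. glucose uptake under oligomycin) stay absent (`NA`,
  n = 0), never zero.
- Phase segmentation errors name the offending phase; a phase emptied by
  `skip_first` is an error, not a silent `NaN`.
- `oligo_sensitivity()` is undefined (error) for a non-positive free
  response; `ffa_glycerol_ratio()` for zero glycerol; glycogen slopes need
  two distinct time points.
- Negative measured rates are rejected at the door (readers report row and
  column); negative *derived* rates are data and carry flags.
- Tests compare reference-derived cells at group-mean level with ≤ 2 %
  relative tolerance where the source averaged per replicate, and exactly
  where the algebra is exact.

## Problem sizes

The test suite and examples run entirely on generated data: typically 2–6
wells per condition (up to 48 in the noise-scaling property test, verified
at 3/12/48 wells against the expected 1/√n shrinkage), 20-point traces, and
1,000-draw property loops for the algebraic identities — a few seconds in
total on one core.

## Known limitations

- Palmitate/tripalmitin is the sole reference lipid species; no acyl-chain
  resolution.
- The glycogen flux from figure-level time courses is scenario-dependent
  (medium glucose changes its sign in the source data); the simulator's
  −54 default represents the glucose-free stimulated scenario only.
- No inferential statistics between genotypes are computed beyond
  mean ± SD — the bookkeeping, not hypothesis testing, is the scope.
- The re-esterification rate inherits the β-oxidation *bound*, so it is
  itself bound-like: conditions with low respiration can legitimately go
  below zero, which is reported, not resolved.
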