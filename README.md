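# hspcompat

Desk-scale drug–polymer compatibility screening by group-contribution
Hansen solubility parameters, plus the formulation analytics of a
polymer-micelle solubilization study.

**Who it is for:** formulation scientists and cheminformaticians who want
a reproducible implementation of the classical pre-formulation screen —
Hoftyzer–van Krevelen group contributions → Hansen solubility parameters
(HSPs) → Flory–Huggins interaction parameter — together with the
measurement-side arithmetic (loading capacity/efficiency, stability,
redispersion, dosing) needed to confront the prediction with experiment.

## The model

A molecule is decomposed into functional groups (from a SMILES string via
the ChemmineR/OpenBabel backend, or from curated explicit counts). With
group counts *nᵢ*, molar attraction constants *F_di*, *F_pi*
(MPa^0.5·cm³/mol), hydrogen-bond energies *E_hi* (J/mol) and Fedors
volume increments *Vᵢ* (cm³/mol):

```
V  = Σ nᵢ Vᵢ                      (Fedors molar volume)
δd = Σ nᵢ F_di / V
δp = Σ nᵢ F_pi / V                (orthodox √Σ F_pi²/V available as an option)
δh = √( Σ nᵢ E_hi / V )
δtotal = √(δd² + δp² + δh²)       [MPa^0.5]

χ_dp = V_drug (δ_drug − δ_polymer)² / (R T)     (Hildebrand–Scatchard)
```

Small χ predicts compatibility; candidates are ranked by ascending χ and
the prediction is scored against an observed solubilizer order with a
pair-enumerated Kendall tau.

## Worked example

The bundled study: the RET agonist BT44 (C28H27F4N3O4S, 577.59 g/mol)
screened against poly(2-oxazoline) repeat units with methyl, n-propyl,
n-butyl and n-pentyl side chains.

```r
library(hspcompat)
mols <- pox_screen_molecules()
rank_candidates(mols$BT44, mols[c("pMeOx", "pPrOx", "pBuOx", "pPentOx")])
#>  drug_id polymer_id delta_diff    chi hansen_dist rank
#>     BT44      pPrOx      0.478 0.0341        3.50    1
#>     BT44      pBuOx      2.120 0.6699        2.78    2
#>     BT44    pPentOx      3.298 1.6217        3.35    3
#>     BT44      pMeOx      5.673 4.7982       10.27    4
```

χ ≈ 0.03 for pPrOx predicts near-athermal mixing (best solubilizer);
the hydrophilic pMeOx (χ ≈ 4.8) is predicted to be a poor one. The
formulation data say otherwise:

```r
recs <- read_formulation_csv(system.file("extdata",
        "bt44_formulations.csv", package = "hspcompat"))
rep <- run_formulation_report(recs,
        predicted_order = c("pPrOx", "pBuOx", "pPentOx"))
rep$observed_order   # "pPentOx" "pBuOx" "pPrOx"  (best LC 47/19/0.5 wt %)
rep$rank_agreement   # -1: the prediction is exactly reversed
```

The numbered drivers under `analysis/` run the full workflow and narrate
the results: `01_compatibility_screen.R` (HSP profiles and the χ screen,
written to `results/screen/`), `02_formulation_analytics.R` (LC/LE,
stability retention 19 → 7 wt % giving 0.36, complete precipitation of
the low-feed series at day 1, redispersion recovery 94 %/100 % in
saline/cell-culture media, dosing: 50 mg/kg at 10 mL/kg needs 5 g/L
against 19.3 g/L achievable) and `03_synthetic_benchmark.R` (seeded
generator recovery: 100 % rank recovery at χ = {0.1, 0.7, 1.5}, cv 2 %,
200 replicates; median decay-rate estimate 5.002 d against a truth of
5 d).

See `vignettes/compatibility-screening.Rmd` for the methods account,
including the polar-summation convention, the provenance of the
estimated SO2 table row and the limits of the synthetic generator.

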