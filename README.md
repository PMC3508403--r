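# benthicN

Inference of benthic nitrogen-loss rates from ¹⁵N isotope-pairing
incubation experiments, for biogeochemists working on sediments under
oxygen minimum zones.

Marine sediments remove fixed nitrogen by two anaerobic pathways:
canonical denitrification, which pairs two N atoms from the same NOₓ
pool, and anammox (NH₄⁺ + NO₂⁻ → N₂), which combines one reduced and one
oxidized atom. After adding a ¹⁵N-labelled substrate, the isotopologue
production rates p²⁹N₂ and p³⁰N₂ separate the pathways through their
binomial pairing statistics: at nitrate labelling fraction *F*,

- denitrification: p³⁰ = D·F², p²⁹ = 2F(1−F)·D
- anammox: p²⁹ = A·F (no ³⁰N₂ from a labelled NOₓ pool)

`benthicN` implements the full chain:

1. **isotope signals** — excess ²⁹N₂/³⁰N₂ above the air-equilibrium
   ratios; OLS production slopes with a significance (p < 0.05) and
   initial-delay filter; unit bridges to volumetric (slurry) and areal
   (core) rates.
2. **pairing engine** — A = p²⁹/F(NH₄) from the ammonium experiment;
   D = p³⁰/F², A = (p²⁹ − 2p³⁰(1−F)/F)/F from the nitrate experiment;
   inversion of the unknown nitrate labelling fraction F\* from the
   quadratic `A·F² − (p²⁹ + 2p³⁰)·F + 2p³⁰ = 0` under the constraint
   A(Ex1) = A(Ex2); excess (intracellularly stored) ¹⁴NO₃⁻ from the
   F\*-to-nominal gap; revised isotope pairing (rIPT) for intact cores,
   `f = (2−ra)/((1−ra)(R²⁹+2))`, total = 2·p³⁰/(f²(1−ra)); depth
   integration to areal fluxes.
3. **water column & budgets** — the Redfield-referenced deficit
   N\* = NH₄ + NO₂ + NO₃ − 16·PO₄ + 2.9 and basin-scale annual N-loss in
   Tg N yr⁻¹.
4. **gene quantification** — anammox share of total *nirS* copies with
   below-detection handling and delta-method uncertainty; cell-specific
   rates.
5. **simulator** — forward models of both slurry experiments and the
   intact-core design with known truth attached to every series, so every
   stage is testable by parameter recovery.

## Worked example

Recover a known intracellular nitrate store from a simulated
nitrate-tracer slurry (noiseless, so recovery is exact):

```r
library(benthicN)

scn <- slurry_scenario(true_D = 68, true_A = 5, intracellular_14no3 = 95,
                       seed = 42, noise_sd_ratio = 0)
s2 <- simulate_slurry_ex2(scn)
tr <- attr(s2, "truth")

ex  <- excess_relative_to_air(s2)
p29 <- volumetric_rate(production_slope(ex$time_h, ex$excess29)$slope, s2)
p30 <- volumetric_rate(production_slope(ex$time_h, ex$excess30)$slope, s2)

fstar <- infer_fstar(p29, p30, a_target = 2 * scn$true_A, tr$f_nominal)
fstar$value
#> [1] 0.7585569
denit_ex2(p30, fstar)
#> [1] 136
excess_nitrate(tr$conc15_no3, fstar, tr$f_nominal,
               slurry_to_sediment_factor(s2))
#> [1] 95
```

The nominal labelling fraction from tracer and dissolved pools is 0.92,
but the inversion finds the true fraction 0.76 — the gap quantifies the
95 nmol cm⁻³ of unlabelled nitrate released from intracellular stores
when the slurry was mixed. Denitrification comes back at
136 nmol N cm⁻³ d⁻¹ (N-atom units, i.e. 2 × `true_D`).

## Analysis workflow

Numbered scripts under `analysis/` run the whole study end-to-end and
write their tables to `results/`:

```sh
Rscript analysis/01_simulate_incubations.R   # 4-station transect, 2% ratio noise
Rscript analysis/02_production_slopes.R      # filtered per-channel slopes
Rscript analysis/03_slurry_ipt.R             # pathway rates, F*, excess NO3-, areal fluxes
Rscript analysis/04_core_nloss.R             # rIPT core totals, partitioned
Rscript analysis/05_watercolumn_budget.R     # N* profile, basin budgets
Rscript analysis/06_gene_fractions.R         # nirS shares, cell-specific rates
```

Stage 3 prints, per station, the 0–2 cm depth-integrated denitrification
and anammox fluxes (mmol N m⁻² d⁻¹) and the anammox fraction ra, which
rises from ~7% at the shallow end of the transect to ~38% at the deep
end; stage 4 corrects the intact-core totals with those fractions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main computation from scratch at the given seed:
it simulates the four-station transect study, runs the complete inference
chain (excess → filtered slopes → pairing inversion → depth integration →
rIPT cores), computes the N\* profile and basin budgets from the bundled
profile and the pipeline's own mean benthic flux, and summarizes the
*nirS* gene fractions, then writes the results JSON to `--out`.

## Bundled data

Small plain-text tables under `inst/extdata/` (see the README there):
the measured excess-nitrate table, a synthetic water-column nutrient
profile, and a qPCR *nirS* table in which two stations carry published
copy numbers and two are synthetic fill — files and rows are labelled
accordingly.
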