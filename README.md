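# mustflux

Constraint-based metabolic modeling for strain design: model quality
control, flux balance analysis (FBA), flux variability analysis (FVA),
and the MUST stage of the OptForce procedure, in plain R.

`mustflux` targets the workflow used to engineer *Corynebacterium
glutamicum* overproducers from a genome-scale metabolic model (GEM): load
a model from tabular reaction/metabolite lists or an SBML subset, verify
its reconstruction quality (elemental and charge balance, biomass
molecular weight, Gibbs-energy-constrained directionality), simulate
growth and knockout phenotypes under experimental uptake rates, and
compare wild-type flux spans — delimited by ¹³C-tracer flux bounds —
against forced-overproduction flux spans to classify the genetic
interventions a production target requires.

## The model and the statistics it computes

A metabolic model is a stoichiometric matrix **S** (metabolites ×
reactions) with flux bounds and boolean gene–protein–reaction (GPR)
rules. The package solves, with its own bounded-variable simplex:

* **FBA** — maximize `v_obj` subject to `S v = 0`, `lb ≤ v ≤ ub`
  (biomass is the default objective; substrate uptakes are fixed as
  equalities when experimental rates are given).
* **Parsimonious resolution** — FBA optima are degenerate; every
  reported flux vector first fixes the objective at its optimum and then
  minimizes `Σ|v|`, which removes futile cycles and makes single flux
  values reproducible. FVA at the optimum flags any still-degenerate
  fluxes.
* **FVA / flux spans** — per-reaction `[min, max]` of `v_r` under a
  constraint set; with no objective cut this is the "flux span" used by
  the MUST analysis.
* **MUST sets** — with wild-type spans `[wt_min, wt_max]` (under ¹³C
  bounds) and overproducer spans `[ov_min, ov_max]` (production forced to
  ≥ 98 % of its theoretical maximum, biomass ≥ 1 % of its own), a
  reaction is **MustU** if `ov_min > wt_max + ε`, **MustL** if
  `ov_max < wt_min − ε`, and **MustX** (knockout) if additionally its
  overproducer span is pinned to zero.

Everything is testable offline: the package generates toy models with
analytically known optima and a mass- and charge-balanced ~80-reaction
mini central-carbon model of the *C. glutamicum* type (EMP, oxidative
PPP, TCA with NADP-dependent isocitrate dehydrogenase, anaplerosis,
glutamate/proline/lysine branches including the PutA cycle, biomass
draining exactly 1 g of precursors per gDCW).

## Worked example

```r
library(mustflux)

model <- make_minicore_model()          # 56 genes, 74 metabolites, 82 reactions
check_biomass_weight(model)             # 0.9999862  (g per gDCW)

# growth on glucose at 4 mmol/gDCW/h, alternate optima resolved
cfg <- scenario_config(carbon_source = "EX_glc__D_e", uptake_rate = 4)
wt  <- run_growth_scenario(model, cfg)
wt$growth_rate                          # 0.6161746  (1/h)

# oxidative PPP flux per 100 glucose, wild type vs pgi knockout
100 * wt$distribution$fluxes[["G6PDH2r"]] / 4      # 43.23
dpgi <- run_growth_scenario(model, scenario_config(
  carbon_source = "EX_glc__D_e", uptake_rate = 4, deletions = "pgi"))
100 * dpgi$distribution$fluxes[["G6PDH2r"]] / 4    # 90.67

# NADPH accounting (mol per mol glucose)
acc <- cofactor_production(model, dpgi$distribution, "nadph_c")
sum(acc$production[c("G6PDH2r", "GND")]) / 4       # 1.813  from the PPP

# lysine strain design: MUST sets against 13C-style wild-type bounds
lys <- run_design_case(model, "lysine")
design_genes(lys, "must_up")
#  "lysC" "asd" "dapA" "dapB" "ddh" "lysA" "pyc" "zwf" "gnd" "tkt" "tal" ...
design_genes(lys, "must_down")
#  "hom" "acn" "icd" ...
```

The deletion of `pgi` reroutes glucose 6-phosphate through the oxidative
pentose phosphate pathway (43 → 91 per 100 glucose here), roughly
doubling PPP NADPH formation while the NADP-isocitrate dehydrogenase
contribution stays put — the classic redox rebalancing seen in
glucose-6-phosphate-isomerase-deficient strains. The lysine case
classifies the whole aspartate-to-lysine route plus pyruvate carboxylase
and the oxidative PPP as required up-regulations, and homoserine
dehydrogenase, aconitase and isocitrate dehydrogenase as required
down-regulations.

A thin command-line runner covering validation, FBA/FVA, knockouts,
robustness scans, MUST analysis, scenario files and fixture generation is
installed at `inst/scripts/mustflux`.

## Using a genome-scale model

`read_model_tables()` reads any model in the documented tabular dialect
(columns `id, name, equation, gpr, lb, ub, subsystem[,
delta_r_g_prime]` and `id, name, formula, charge, compartment`; a
column-remapping option adapts foreign spreadsheet layouts), and
`read_sbml_subset()` reads the SBML Level 3 FBC subset. To run the
genome-scale *C. glutamicum* analyses, export the published iCW773
supplementary spreadsheets to delimited text and install them as
`inst/extdata/icw773/reactions.tsv`, `metabolites.tsv` and
`c13_bounds.tsv`; the acceptance tests pick them up from there.

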