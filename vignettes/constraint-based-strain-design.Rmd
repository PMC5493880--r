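---
title: "Constraint-based strain design with mustflux: models, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based strain design with mustflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mustflux)
```

## The modeling framework

`mustflux` works with stoichiometric models: a set of metabolites with
chemical formulas and charges, a set of reactions with signed
stoichiometric coefficients (mmol per unit flux), flux bounds
(mmol/gDCW/h; the biomass pseudo-reaction in 1/h), and boolean
gene–protein–reaction (GPR) rules in which `and` joins complex subunits
and `or` joins isoenzymes. The central assumption is the steady state of
internal metabolism, `S v = 0`: intracellular pools neither accumulate
nor drain on the timescale of balanced growth. Exchange pseudo-reactions
(`a_e <=> ∅`, negative flux = uptake) are the only places where mass
crosses the system boundary, and the extracellular metabolite row is
retained so the balance stays exact.

Flux balance analysis (FBA) maximizes one flux — by convention the
biomass reaction, whose precursor drains are scaled so one unit of flux
consumes 1 g of biomass constituents per gDCW — subject to the steady
state and the bounds. When a scenario supplies an experimental uptake
rate, the corresponding exchange flux is fixed as an equality rather than
capped; this reproduces the practice of pinning measured glucose and
oxygen consumption, and a `uptake_mode = "bound"` switch reverts to the
cap. Freely transported small species (CO2, water, ammonium, phosphate,
sulfite/sulfate, protons) keep wide-open exchanges.

## Alternate optima and why every reported flux is parsimonious

An FBA optimum is almost never a unique flux vector: parallel pathways
and futile cycles span a face of optimal solutions, so a "predicted flux
distribution" is only meaningful under a selection rule. The package
therefore never reports raw vertex solutions. `simulate_deletion()`,
`run_growth_scenario()` and friends fix the objective at its optimum
(relaxed by a relative `1e-6` so the equality is numerically attainable)
and minimize the sum of absolute fluxes via the standard forward/reverse
split. This selects a representative without futile cycling; remaining
degeneracy (stoichiometrically identical twin routes) is real, and
`check_uniqueness = TRUE` flags such fluxes by FVA at the optimum — a
flux whose residual range exceeds `1e-5` is marked degenerate in
reports. The relaxation means fluxes downstream of the objective agree
with identities such as "PPP flux = uptake − biomass G6P drain" to about
five decimal places, not machine precision; tests and comparisons use
tolerances of `1e-4`–`1e-5` accordingly.

## The LP core

All computations reduce to bounded linear programs
`optimize c'v s.t. S v = 0, lb ≤ v ≤ ub`, because objectives, uptake
settings, production floors, and FVA cuts all act on single fluxes. The
package ships its own dense bounded-variable two-phase simplex
(`lp_solve`): nonbasic variables rest on a bound or, at the start, at the
all-zero flux point (a valid generalized start since the right-hand side
is zero); phase 1 drives artificial variables out; pricing is Dantzig
with an automatic switch to Bland's rule after degenerate stalling, which
guarantees termination. Tolerances: feasibility `1e-9`, reduced-cost
optimality `1e-7`, bound magnitudes ≥ `1e30` treated as infinite, and the
conventional `1000 mmol/gDCW/h` sentinel for "unbounded" reactions. The
test suite checks this solver against an exhaustive basic-solution
enumeration oracle (every vertex of a bounded LP has `n − rank(S)`
variables at a bound) on all toy fixtures, and against an external
constraint-based implementation through the SBML interface.

## Reconstruction quality control

* **Mass/charge balance** — per reaction, the stoichiometry-weighted sum
  of elemental counts and charges must vanish. Exchange, demand/sink and
  biomass reactions intentionally create or destroy mass and are exempt;
  generic residue elements (R, X) are tolerated where they cancel.
* **Biomass weight** — the net mass drained by the biomass reaction,
  from formula-derived molecular weights (IUPAC atomic weights bundled in
  code), should be 1 g/gDCW; growth-associated ATP hydrolysis cancels in
  the net sum, which the suite asserts as an invariance property.
* **Directionality** — a reaction with transformed Gibbs energy ≤ −30
  kJ/mol is set irreversible forward, ≥ +30 irreversible backward,
  reversible otherwise. The 30 kJ/mol cutoff is a configurable default
  (`t_irr`): published reconstructions rarely state the magnitude they
  used, so it is surfaced as a parameter rather than asserted as a fact,
  and reactions lacking a Gibbs energy annotation are left untouched and
  listed.

## The MUST stage of OptForce

Strain-design calls come from comparing two flux spaces on the same
network:

* the **wild-type space**, delimited by experimental ¹³C-tracer flux
  intervals imposed as bounds (no biomass-optimality cut — the measured
  bounds themselves define the space; a biomass floor can be added by
  flag), and
* the **overproducer space**, delimited by a floor on the target
  transport flux at 98 % of its theoretical maximum and a floor on
  biomass at 1 % of its own maximum, both computed with the substrate
  uptake fixed.

Flux spans are FVA at objective fraction 0 in each space. Classification
uses an absolute overlap tolerance `ε = 1e-6`; gaps under `1e-3` are kept
but annotated "weak". MustX (knockout) is implemented as the zero-forced
sub-case of MustL, so that swapping the two spaces exactly swaps MustU
and MustL — an antisymmetry the suite tests on randomized interval
pairs, together with the monotonicity that widening any span can only
declassify. Reversible reactions are classified on net flux; a
split-direction mode exists but is off by default, since the published
interval tables are net-flux intervals.

## The synthetic data generators

Three tiers stand in for external inputs so every stage runs offline:

* `make_chain_model()` — substrate → n conversions → product, optimum =
  uptake; each conversion carries a single-gene GPR.
* `make_branched_model()` — two stoichiometrically identical routes and
  an NAD-coupled side branch, exercising FVA degeneracy and cofactor
  accounting with documented truths (route ranges `(0, 10)`, cofactor
  turnover 10).
* `make_minicore_model()` — an 82-reaction, 74-metabolite central-carbon
  model of the *C. glutamicum* type with real formulas and charges
  throughout (glucose C6H12O6, pyruvate C3H3O3 charge −1, full
  NAD(P)/adenylate bookkeeping, lumped respiration at P/O = 2). It
  contains EMP glycolysis with fructose-1,6-bisphosphatase for
  gluconeogenesis, the oxidative PPP yielding 2 NADPH per glucose
  6-phosphate routed in, non-oxidative PPP, full TCA with NADP-dependent
  isocitrate dehydrogenase, the glyoxylate shunt, pyruvate carboxylase
  and PEP carboxykinase, glutamate dehydrogenase, the proline route
  (proB → proA → spontaneous cyclization → proC) opposed by the
  bifunctional PutA (proline dehydrogenase + P5C dehydrogenase), the
  lysine branch with the ddh shortcut, threonine/valine/alanine drains,
  acetate and lactate catabolism, and dead-end glycerol/xylose exchanges
  so that growth on those substrates requires the heterologous pathway
  additions (`glycerol_ecoli`: 3 reactions; `xylose_ecoli`: 2 reactions;
  `pdo_ecoli` and `isobutanol_kivd_adhA` for the non-native products).
  Biomass coefficients are scaled at generation time so the precursor
  drain is exactly 1 g/gDCW (then rounded to 4 decimals), with 35
  mmol/gDCW growth-associated ATP hydrolysis; the spontaneous
  glutamate-5-semialdehyde cyclization carries an empty GPR, so no gene
  deletion can touch it. Default glucose uptake is 4 mmol/gDCW/h and
  maintenance ATP 2 mmol/gDCW/h — typical minimal-medium magnitudes. The
  fixture's md5 digest is pinned in the tests so a refactor cannot
  silently change the truth values.

`make_c13_constraints()` emulates ¹³C-derived bound tables: for each
central branch-point reaction (and the measured growth rate) the interval
is `center ± max(width_fraction·|v|, 0.5)`; the 0.5 mmol/gDCW/h floor
models measurement resolution, and the center jitter (up to half of
`width_fraction·|v|`, seeded, restored RNG state) keeps the true flux
strictly inside every interval. The wild-type reference state pins PEP
carboxykinase at 0.3 mmol/gDCW/h on top of the parsimonious optimum,
because labeling studies consistently observe simultaneous pyruvate
carboxylase/PEP carboxykinase cycling that pure parsimony would zero
out.

What the mini-core does **not** emulate: compartments beyond
cytosol/extracellular, cofactor promiscuity, kinetic or regulatory
effects, measurement error structure beyond interval width, and the
~15-fold larger reaction inventory of a genome-scale model. Passing
tests on it therefore validate the machinery — balances, LP correctness,
classification logic, recovery of planted interventions — not the
numerical flux values of any real strain; genome-scale numbers require
the published model tables, which the readers accept in tabular or SBML
form.

## Design choices that were genuinely open

* **Scan objective for the aconitase robustness study.** The published
  description pins the aconitase flux at 1.0–5.0× its native value but
  does not state the re-solved objective. We scan with an explicit
  objective argument; the bundled proline case study maximizes proline
  export with a biomass floor (0.3/h on the mini-core) against the
  wild-type biomass-optimal reference. This choice makes the scan answer
  the engineering question ("what does more aconitase do to the
  producer?") and, because an LP value function of a right-hand side is
  concave, guarantees the unimodal shape the case study asserts; on the
  mini-core the proline optimum sits at an interior multiplier (1.5×).
* **Wild-type span constraints.** Only the ¹³C bounds (which include the
  measured growth rate) delimit the wild-type space; no optimality cut is
  added, matching the stated use of the tracer data as the bounds of
  flux variability.
* **Empty GPRs under deletion.** Reactions with no gene association are
  never disabled — spontaneous chemistry and orphan reactions cannot be
  knocked out.
* **Deleting unknown genes** warns and proceeds, so one scenario script
  can serve several models.
* **Tabular dialect details.** Both `met[c]` and `met_c` compartment
  spellings are accepted (supplementary spreadsheets and SBML ids
  disagree); output always uses `met_c`. The delimiter is auto-detected
  from the header (tab preferred on ties). A one-sided equation is legal
  only in the single-metabolite exchange/sink form; a multi-metabolite
  equation missing a side is rejected as malformed. An `objective`
  column and a column-remapping option let foreign layouts load without
  code changes.

## Known limitations

The simplex is dense and unfactorized (a fresh solve per iteration),
sized for models up to a few thousand reactions rather than
multi-compartment eukaryotic reconstructions; FVA over all reactions of
an 82-reaction model takes seconds, a genome-scale model minutes. MUST
analysis classifies single reactions only — the second OptForce stage
(minimal intervention-set search) and OptKnock-style bilevel designs are
out of scope, as are MOMA, loop-law thermodynamic FBA and flux sampling.
The SBML writer/reader covers the FBC-style subset used by
constraint-based tools, not full SBML (events, rules and initial
assignments are rejected by name). Problem sizes in the tests and the
acceptance script are the fixture sizes quoted above.
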