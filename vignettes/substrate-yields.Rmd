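---
title: "Comparing glucose, ethanol and acetate as feedstocks for acetyl-CoA-derived products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing glucose, ethanol and acetate as feedstocks for acetyl-CoA-derived products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetoflux)
```

## The scientific question

Acetyl-CoA is the hub from which poly(3-hydroxybutyrate) (PHB),
3-hydroxypropionate (3HP), phloroglucinol (PG) and many other products are
drawn in engineered *E. coli*. How much product a feedstock can support is
set by stoichiometry long before kinetics matters: glucose loses a third of
its carbon as CO2 on the way to acetyl-CoA, acetate must spend ATP on
activation, while ethanol reaches acetyl-CoA with full carbon retention
*and* two NADH per molecule. `acetoflux` turns that comparison into a small,
fully balanced, exactly solvable model, and adds the bookkeeping needed to
relate measured fermentations and metabolite panels back to those limits.

## The model

The curated network deliberately mirrors the granularity at which the
substrate comparison is usually argued:

* lumped EMP glycolysis: glucose → 2 pyruvate + 2 ATP + 2 NADH;
* pyruvate dehydrogenase: pyruvate + CoA → acetyl-CoA + CO2 + NADH;
* lumped TCA cycle: acetyl-CoA → 2 CO2 + 3 NAD(P)H + FADH2 + GTP;
* assimilation routes: AdhE (ethanol → acetyl-CoA, 2 NADH, two steps),
  ExaABC (ethanol → acetate with one cytochrome-c-level electron pair and
  one NADH, then activation), ACS (acetate + 2 ATP-equivalents) or Pta-AckA
  (1 ATP);
* product pathways: PhaA/PhaB/PhaC (2 acetyl-CoA + NADPH → C4H6O2 repeat
  unit), ACC + MCR (3HP), ACC + PhlD (PG);
* energetics: oxidative phosphorylation at policy-defined P/O ratios, GTP
  equivalence, a reversible NADH/NADPH pool exchange, and exchange
  reactions for substrate, product, CO2 and surplus ATP.

Per-enzyme expansion of glycolysis and the TCA cycle is a non-goal: the
aggregate coefficients are the quantities the comparison reasons with, and
finer resolution would not move any yield.

### The acid-equivalent cofactor convention

CoA thioesters carry the elemental formula of their free acid (acetyl-CoA
as C2H4O2, malonyl-CoA as C3H4O4, ...), so the CoA moiety cancels; CoA
itself, NAD(P)H, FADH2, cytochrome-level pairs and ATP are carbon-free
pseudo-species carrying an explicit transferable-electron count (2 per
reduced redox pair, 0 otherwise). Two consequences:

1. **Balance checking is carbon + electrons.** Every conversion reaction is
   checked for *exact* (rational-arithmetic, zero-tolerance) carbon and
   degree-of-reduction balance; hydrogen and oxygen flow through implicit
   water and protons, which the lumped stoichiometry omits, and charge is
   tracked but not balanced. Exchange and energetic reactions are exempt.
2. **Mass yields exclude carriers.** Formula weights enter only through
   the true substrate and product species, using pinned IUPAC 2021
   conventional atomic weights.

The degree of reduction is γ = 4C + H − 2O − 3N + 5P + 6S − charge
(CO2/H2O/NH3/H3PO4/H2SO4 reference states). The builtin networks contain no
nitrogen species, so the nitrogen convention only affects user extensions.

## The yield calculation

`max_yield()` solves: maximize product-exchange flux subject to steady
state on **every** species, substrate uptake fixed to 1, irreversible
fluxes ≥ 0, and net ATP ≥ the maintenance demand. Two numerical choices
matter:

* **Exact rational simplex.** No LP library ships with sensible tolerances
  for 10 × 20 problems whose answers are printed to three figures, so the
  solver does two-phase simplex with Bland's rule entirely in exact
  rational arithmetic. There is no feasibility or optimality tolerance to
  tune; a yield of 16/45 mol/mol is returned as exactly 16/45. The
  independent cross-check, `brute_force_max_yield()`, enumerates basic
  solutions of the same polytope with exact elimination (after a
  floating-point pre-filter) and must agree to 1e−9 in the test suite — in
  practice it agrees exactly.
* **Parsimonious tie-break.** Among alternate optima a second LP stage
  minimizes total flux at the fixed optimal yield. This is the
  field-standard pFBA convention; it makes the reported flux vector and net
  stoichiometry deterministic and never changes the yield itself.

There is deliberately no biomass demand — the result is a product-only
stoichiometric ceiling — and ATP coupling is one-way: reducing power buys
ATP at the P/O rates, but ATP can never buy electrons back.

```{r yields}
res <- max_yield(builtin_network("ethanol", "phb"))
res
overall_stoichiometry(res, builtin_network("ethanol", "phb"))
```

Mass yields use the PHB *repeat unit* C4H6O2 (86.09 g/mol), i.e. the water
lost on polymerization is included; this is the convention under which the
ethanol ceiling computes to 0.5 × 86.09 / 46.07 ≈ 0.934 g/g.

### The cofactor policy

`cofactor_policy()` holds every energetic assumption in one place:

| parameter | default | meaning |
|---|---|---|
| `po_nadh` | 2.5 | mol ATP per NAD(P)H oxidized |
| `po_fadh2` | 1.5 | mol ATP per FADH2 |
| `po_cytc` | 1.0 | mol ATP per cytochrome-c-level pair (ExaABC entry) |
| `gtp_as_atp` | TRUE | TCA substrate-level GTP counts as ATP |
| `nadph_pooling` | "free" | NADH ↔ NADPH interconvert 1:1 |
| `maintenance_atp` | 0 | ATP demand per unit uptake |

The 2.5/1.5 pair with GTP-as-ATP is the standard aerobic textbook
convention (32 ATP per glucose) and is the unique simple choice consistent
with all three per-gram ATP densities the package reproduces; source
reports of such comparisons rarely state their P/O assumptions, so the
defaults are documented here as a convention, not as anyone's measured
values. The ExaABC cytochrome-level equivalence (1.0) is likewise a
configurable convention — quinoprotein energetics are genuinely uncertain.

Under `nadph_pooling = "strict"` the pool exchange is removed. Because the
lumped TCA emits pooled NAD(P)H (recorded on the NADH side), strict mode
leaves the builtin product pathways without an NADPH source and their
yields collapse to 0 — the mode exists as the conservative bound (strict ≤
free is a tested invariant) and becomes informative in user networks that
declare mechanistic NADPH producers.

### Acetate arithmetic, worked

One PHB monomer needs 2 acetyl-CoA + 1 NADPH. Via ACS each activation costs
2 ATP-equivalents, so the monomer deficit is 4 ATP + 2.5 ATP-equivalents of
reducing power = 6.5; each *extra* acetate burned through the TCA nets
3 × 2.5 + 1.5 + 1 − 2 = 8 ATP. Hence 6.5/8 extra acetate per monomer and a
ceiling of 1/(2 + 6.5/8) ≈ 0.356 mol/mol ≈ 0.510 g/g. The LP reproduces
this closed form exactly, which is one of the frozen unit tests. Which
activation route a given comparison assumed is often unstated; both are
provided and the choice is an explicit `acetate_route` flag.

## Complete-oxidation energetics

`atp_per_mol()` maximizes the net ATP drain with CO2 export *constrained*
equal to substrate carbon — complete oxidation is a constraint, not an
objective. Net ATP may be negative (acetate at zero P/O returns −1) and is
reported as such, so the energy-negative regime of a policy is visible
rather than clamped. `atp_per_gram()` divides by the substrate formula
weight, giving the per-gram energy densities (ethanol ≈ 0.326 >
glucose ≈ 0.178 > acetate ≈ 0.133 mol ATP/g under the defaults).

## Fermentation arithmetic

The time-course tools implement the conventions used when reducing flask
and fed-batch data by hand:

* consumption is C(t0) − C(t1) plus the cumulative fed amount over the
  interval, against a constant broth volume (feeds are recorded in
  g/L-equivalents); volume changes from feeding are ignored because only
  aggregate consumption is reported in this kind of experiment;
* apparent negative consumption (abiotic loss, noise) clamps to 0 with a
  warning rather than erroring;
* yields are mean-ratio quantities: total product over total consumption,
  at full precision, with display rounding (2–3 significant figures for
  yields, integer percentages) left to the caller;
* interval endpoints must be sampled times — no interpolation — which makes
  consumption exactly additive over adjacent intervals.

## Metabolite panels

Fold changes are ratios of cell means (not means of replicate-wise ratios):
this matches mean ± SEM presentation and needs no replicate pairing. SEM
uses the sample (n − 1) standard deviation. The dispersion of a ratio is
propagated on the log scale to first order. Undetectable values are treated
as missing — never as zero — and a cell is undetectable only when *all*
replicates are, since no limit of detection is modeled; a fold change with
an undetectable denominator is flagged undefined rather than inflated. No
hypothesis-testing or multiple-comparison machinery is attached: the
statistic of interest is the ratio itself. The normalization behind
"relative amount" panels (per-OD, per-CDW, internal standard) is routinely
unstated upstream; the module operates on whatever normalized intensities
it is given, and ratios are invariant to any global rescaling.

## What the synthetic data emulates — and what it does not

`simulate_fermentation()` integrates logistic growth with Luedeking–Piret
product formation and yield-coupled substrate drain (deSolve, `lsoda`,
rtol 1e−10), with instantaneous feeds and a hard stop of growth and
production at S = 0. This is a *test harness*, chosen as the simplest model
able to mimic both growth-associated PHB accumulation in a flask and a
fed-batch plateau; no kinetic model is being fit or claimed. Gaussian noise
(truncated at 0) on observed concentrations emulates HPLC-type error;
lognormal replicate noise in `simulate_panel()` emulates LC-MS-type
multiplicative error.

The default flask emulation (`phb_flask_params()`) uses μmax = 0.2/h,
X: 0.05 → 3.3 g/L over 54 h on 10 g/L substrate, purely growth-associated
product at α = 0.95 g/g (so polymer is roughly half of total dry weight)
and drain at the stoichiometric ceiling y_ps = 0.935 g/g, with y_xs
back-calculated so the realized overall yield is exactly the configured
truth (0.32 g/g by default). With β = 0 the realized yield is exact at
*every* sampling time, independent of integrator error, which is what makes
the end-to-end recovery tests sharp (noise-free recovery to 1e−9; with
0.1 g/L noise, a median bias below 0.005 g/g across 100 seeds).

Not emulated, by design: substrate toxicity and growth inhibition, diauxic
glucose/byproduct switching, by-product formation (e.g. formate), pH/DO
control, and volume changes. Passing the recovery tests therefore shows the
*arithmetic pipeline* is unbiased under the stated error model — it says
nothing about those biological effects in real cultures.

## Problem sizes and runtime choices

The builtin LPs are ~10–16 species by ~14–18 reactions and solve in
milliseconds. The enumeration oracle visits every column subset of the
reduced steady-state system; the test suite runs it on all 18 builtin
substrate/product/route networks and on 50 randomized conservative
networks (1–3 internal species), sizes at which exhaustive exact
enumeration stays in the tens of seconds. The statistical property checks
use 100 seeded fermentations and 1000 seeded panels — large enough for
median-bias assertions at the tested tolerances, small enough to keep the
whole suite under a minute.

## Known limitations

* The model is a curated lumped network, not a genome-scale
  reconstruction; there is no thermodynamic feasibility check, no proton or
  charge balance, and no biomass/growth coupling.
* Theoretical yields for CO2-fixing malonyl-CoA products can exceed 100%
  carbon recovery on electron-rich substrates (flagged via `co2_fixed`);
  this is a property of the stoichiometric ceiling, not a prediction that
  such fixation is kinetically accessible.
* The Pta-AckA reaction is modeled irreversibly in the activation
  direction; acetate overflow is out of scope.
* Exact rational arithmetic guards against tolerance artifacts but bounds
  coefficients to ~2^52; absurdly scaled user models will be rejected
  rather than silently rounded.
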