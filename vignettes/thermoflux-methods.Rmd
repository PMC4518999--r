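---
title: "Constraint-based modelling of a thermophilic ethanologen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling of a thermophilic ethanologen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model and its assumptions

*Thermoanaerobacterium saccharolyticum* is a thermophilic anaerobe that
ferments the sugars of lignocellulose to ethanol, acetate, lactate, CO~2~
and H~2~, and is a platform organism for engineered ethanol production.
`thermoflux` analyses its fermentative metabolism with flux balance
analysis (FBA): given a stoichiometric matrix $S$ (metabolites × reactions),
a flux vector $v$ is feasible when

$$ S v = 0, \qquad lb \le v \le ub, $$

and FBA maximizes one flux — normally the biomass pseudo-reaction — over
this polytope. Steady state and linearity are the only physics in the
model: no kinetics, no regulation, no thermodynamic potentials. Flux units
are mmol gDW^-1^ h^-1^ throughout; the biomass flux is the specific growth
rate in h^-1^. Exchange reactions are written `met[e] ->`, so positive
flux is secretion and negative flux is uptake; glucose uptake is reported
as the magnitude $|v_{EX\_glc}|$ in all yield computations. Default bounds
are ±1000 for reversible and [0, 1000] for irreversible reactions.

Because the optimal face of an FBA problem is usually degenerate,
`solveFBA()` returns one arbitrary optimal vertex and every scientific
claim in the package is phrased through `fluxVariability()` (per-reaction
min/max at a stated fraction of the optimum), `productionEnvelope()` or
`couplingStrength()`, which are degeneracy-proof because each bound is
itself an LP optimum.

## The core fermentation network

`buildCoreModel()` constructs a ~40-reaction curated skeleton of central
fermentative metabolism. Six reactions — GLNS, GLUDy, GLUSy, LDH_L, PTAr
and HFS — enter verbatim from the curated reconstruction table, including
their locus-tag gene rules (HFS, the ferredoxin hydrogenase, requires all
four genes Tsac_1550–Tsac_1553 of the *hfs* operon). The remaining
stoichiometries are lumped choices, fixed in one table in the source and
documented here:

* **Glycolysis (GLYC)**: glucose → 2 pyruvate + 2 ATP + 2 NADH.
* **POR**: pyruvate + CoA + Fd~ox~ → acetyl-CoA + CO~2~ + Fd~red~.
  Ferredoxin is modelled as an Fd~red~/Fd~ox~ pair carrying two electrons,
  so one H~2~ is one NADH-equivalent.
* **Ethanol branch**: acetaldehyde and alcohol dehydrogenase steps, two
  NADH per ethanol from acetyl-CoA.
* **Acetate branch**: PTAr then acetate kinase (+1 ATP per acetate).
* **Hydrogenases**: HFS and ECH interconvert Fd~red~ and H~2~; the
  bifurcating hydrogenase (BIFH2) couples Fd~red~ and NADH
  (Fd~red~ + NADH + 3 H^+^ ⇌ 2 H~2~), and NADH2 is the plain NADH
  hydrogenase. Written direction = H~2~ production.
* **RNF** (ferredoxin:NAD oxidoreductase) is irreversible toward NADH.
  This is the exergonic direction, and keeping the reverse closed excludes
  thermodynamically impossible cycles (e.g. an ATP-generating loop through
  an energy-conserving hydrogenase) from the unconstrained network.
* **Transhydrogenase (THD)** supplies NADPH from NADH; the
  α-ketoglutarate branch (AKGS) condenses pyruvate and acetyl-CoA.
* **Biomass** consumes 4 pyruvate, 1 acetyl-CoA, 60 ATP, 18 NADPH, 0.6
  glutamate and 0.2 glutamine per unit growth. Nitrogen enters biomass
  exclusively through glutamate and glutamine, so deleting glutamate
  dehydrogenase forces the ATP-consuming GLNS+GLUS assimilation route —
  the mechanism behind the marginal ethanol gain of the triple knockout.
  The glutamine:glutamate demand ratio (0.2:0.6) and the NADPH coefficient
  are documented parameters: the NADPH demand exceeds the electron
  surplus stranded by the biomass carbon drain, which makes a small
  acetate flux the optimal electron donor in the electron-centred strain
  and keeps every engineered strain viable.
* **Pyruvate efflux** is a small overflow valve. It gives the carbon-
  centred knockout strain its residual flexibility (hydrogen venting
  traded against ethanol), which is why its growth envelope is coupled
  but visibly wider than the electron-centred strain's.
* **ATP maintenance** has a lower bound of 2 mmol gDW^-1^ h^-1^.

The glucose uptake bound defaults to 10 mmol gDW^-1^ h^-1^; it is a
configuration parameter of `buildCoreModel()` and of the reproduction
drivers. Gene ids for reactions without a published locus tag are `g_*`
placeholders, marked as such, so gene-level deletion logic stays testable
without asserting real genome coordinates. One token-level normalization:
the printed hydrogenase formula writes the proton as lowercase `h[c]`
while every other row uses `H[c]`; the constructor uses `H[c]`
consistently.

## The hydrogenase constraint set

Left unconstrained, the hydrogenase complement lets the network vent
unlimited reducing equivalents as H~2~ and run acetate overflow far beyond
anything observed. `applyHydrogenaseConstraints()` implements the
top-down constraint set that reproduces observed physiology: the
energy-conserving hydrogenase (ECH) is blocked; BIFH2 and NADH2 are
restricted to the hydrogen-uptake direction (the H~2~-producing direction
of each written formula is zeroed); and total hydrogen export is capped at
a yield of 0.9 mol H~2~ per mol glucose. The cap is deliberately a
coupling constraint

$$ v_{EX\_h2} \;\le\; 0.9\,|v_{EX\_glc}| $$

carried in the model's `extraConstraints` and dualized inside every LP —
not a fixed bound — so it scales with uptake. It is applied to the glucose
exchange only. Applying the set twice equals applying it once.

## Strains and growth coupling

`strainModel()` builds the engineered strains: `ldh_pta` (carbon-centred:
lactate dehydrogenase + phosphotransacetylase), `ldh_hfs`
(electron-centred: lactate dehydrogenase + ferredoxin hydrogenase) and
`ldh_hfs_glud` (additionally glutamate dehydrogenase). The scalar coupling
statistic is

```{r}
couplingStrength(model, "EX_etoh", fraction = 0.99)
```

the guaranteed minimum ethanol flux over all states with growth at or
above 99% of that strain's optimum — a single LP. On the constrained core
model the wild type keeps a wide ethanol range at optimal growth (the
lactate/ethanol swap is stoichiometrically neutral), the carbon-centred
strain is coupled but retains an H~2~-versus-ethanol trade, and the
electron-centred strain pins ethanol tightly: with both lactate and the
ferredoxin hydrogenase gone, every stranded electron pair must end up in
ethanol. These are exactly the properties asserted by the test suite
(range ratio ≥ 0.5 for WT, > 0 minimum with ratio ≤ 0.2 for `ldh_hfs`,
and the strict coupling ordering at 99% of optimum).

## Knockout design: bilevel program and selection rule

`optKnock()` searches for at most $K$ reaction deletions maximizing
ethanol formation by a growth-maximizing mutant. The bilevel program is
collapsed to one MILP by strong duality: primal feasibility of the mutant
flux state, dual feasibility of the growth LP, and equality of the primal
and dual objectives enforce inner optimality exactly, with binary $y_j$
gating each candidate's bounds ($lb_j y_j \le v_j \le ub_j y_j$). The
bilinear dual-bound terms $\mu_j y_j$ are linearized with big-M products;
primal bounds are first tightened by a fraction-0 flux variability pass,
which both shrinks the big-M constants and keeps the relaxation tight.
Candidates whose single deletion already kills growth are fixed active
before the MILP is built, and blocked reactions (zero bounds) are not
meaningful knockouts and are dropped.

One design decision deserves emphasis. The classic objective — the
*maximum* product flux among growth-optimal states — cannot distinguish a
knockout that merely removes stoichiometrically equivalent alternate
optima from leaving it open: closing the lactate branch never changes the
maximum, only the minimum. Worse, any deletion that slightly lowers the
growth optimum (such as glutamate dehydrogenase) *raises* the classic
objective, so under pure max-selection the lactate knockout would never be
chosen at $K = 2$. Since the scientific question is growth *coupling* —
what the mutant is guaranteed to secrete — the default selection ranks
designs by the guaranteed minimum product at the inner optimum. Candidate
designs are generated by the duality MILP (with a small cardinality bonus
so product-equivalent supersets are not enumerated first), pooled over the
near-optimal band with exclusion cuts, scored by two additional LPs each,
and ranked by guaranteed minimum, then maximum, then cardinality, then
lexicographic ids. `objective = "max_at_optimum"` restores the classic
behaviour. Both the maximum and the guaranteed minimum are reported on
every design, and `exhaustiveDesignSearch()` — plain enumeration of all
candidate subsets with the same ranking — is the independent oracle the
MILP is tested against.

On the constrained core model the pipeline returns the lactate +
ferredoxin-hydrogenase pair at $K = 2$ and additionally glutamate
dehydrogenase at $K = 3$, with a marginal (~0.3%) gain in the guaranteed
ethanol floor for the triple, traded against growth through one extra ATP
per assimilated ammonium (`ammoniumAssimilationAtpCost()` documents the
stoichiometric accounting: the route through glutamine synthetase +
glutamate synthase nets akg + NH~4~ + NADPH + ATP → glutamate).

## Gap filling

`gapFill()` restores biomass flux to a draft network by activating a
minimum-cardinality set of universe reactions: one binary per universe
reaction gates its bounds inside the combined steady-state system, with
growth constrained to at least `min_growth` (default 10^-3^ h^-1^, a
deliberately permissive threshold for "can grow at all"). The objective is
unweighted cardinality; an optional per-reaction cost vector is accepted.
Reversible universe reactions are gated by a single binary on both bounds —
for a cardinality objective this is equivalent to direction-split binaries
and keeps the MILP smaller. Reported growth is re-derived by plain FBA on
draft + additions, and the tests verify minimality by brute force over all
proper subsets of each repair.

## Synthetic test substrates

The generators stand in for a full genome-scale reconstruction in all
tests, with ground truth derivable by hand:

* `generateLinearPathway()` — an uptake-limited chain whose optimum is the
  bottleneck bound.
* `generateCoupledToy()` — a ~12-reaction network with the redox structure
  behind electron-centred design: catabolism strands a reduced cofactor
  that is re-oxidized either by a venting sink (no product) or by a
  product-forming sink that also consumes biomass precursor. Per substrate
  the catabolic lump yields 2 precursor + 1 reduced cofactor + 2 ATP, so
  with the vent open growth is 2 per substrate and the coupled minimum is
  0, and with the vent deleted growth halves while the product floor
  equals the uptake bound.
* `degradeModel()` — removes growth-essential reactions (found by
  single-knockout testing) and builds a repair universe of the removed
  reactions plus mass-balanced decoys over fresh dead-end metabolites,
  which can never carry steady-state flux and therefore can never
  substitute for a removal.

Seeds fully determine each bundle. What the toys do *not* emulate:
realistic genome-scale redundancy (isoenzymes, parallel pathways),
biomass compositions with dozens of precursors, or blocked-reaction
clutter. Passing tests on these substrates demonstrates solver and
algorithm correctness, not predictive fidelity for a particular organism;
the curated core model carries the organism-specific claims, and those are
stated only as the qualitative coupling properties above.

## Numerical choices

The LP core is a dense bounded-variable two-phase primal simplex
(implemented in C++), refactorizing the basis every iteration — at the
problem sizes involved (tens to a few hundred rows) this is cheap and
numerically uneventful. Pricing is Dantzig with a Bland fallback after
3(n+m) iterations to guarantee termination on the highly degenerate
fermentation polytopes; the ratio test is a Harris two-pass with a 10^-7^
bound relaxation, trading transient bound violations below that level for
well-conditioned pivots. The entering threshold on reduced costs is
10^-7^; feasibility is enforced to 10^-9^ and reported values are compared
at 10^-6^, two orders below the smallest meaningful flux differences in
the analyses. MILPs are solved by depth-first branch-and-bound on the
binaries with most-fractional branching and rounding-nearest child order;
dual variables in the duality coupling are capped at 100 (ample for growth
objectives of order one, and checked empirically by the oracle-agreement
tests). Phase planes default to 50 points per axis; "optimal" cells are
compared at 10^-6^ absolute tolerance; infeasible cells serialize as `NA`
tokens. All TSV/JSON outputs round to 9 significant digits so identical
configurations produce byte-identical files.

Test problem sizes are chosen to keep the full suite comfortably
reproducible on a laptop: 200 seeded random networks (≤ 6 reactions each)
for the vertex-enumeration oracle, 50 seeded degrade-and-repair bundles
for gap filling, and toy-scale bilevel instances for every
MILP-versus-enumeration comparison, alongside the two core-model design
searches.

## Known limitations

* The core model is a curated skeleton (~40 reactions), not the published
  genome-scale reconstruction; its statistics (reaction, metabolite and
  gene counts) are its own, and the loaders simply report whatever a
  supplied full reconstruction contains.
* The bifurcating ferredoxin:NAD oxidoreductase stoichiometry is not
  uniquely fixed by the literature the model draws on; the default
  (electron-confurcating, 2 H~2~ per Fd~red~ + NADH) is configurable in
  the constructor table rather than asserted as measured.
* The hydrogen yield cap applies to the glucose exchange only; growth on
  other sugars would need its own calibration.
* Knockouts are reaction-level; gene-level design via
  `reactionsDisabledByGenes()` is available but not the reproduction path.
* No parsimonious or dynamic FBA, no thermodynamic (ΔG) constraints, no
  regulatory layer.
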