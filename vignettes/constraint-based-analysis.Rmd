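---
title: "Constraint-based analysis with gemfba: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis with gemfba}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemfba)
```

## The modelling framework

A genome-scale metabolic model (GEM) is a stoichiometric reconstruction:
metabolites, reactions with flux bounds, gene-protein-reaction (GPR)
rules, and a biomass pseudo-reaction. Flux balance analysis (FBA) treats
the cell as a steady-state flow network and solves the linear program

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

where $S$ is the metabolites-by-reactions stoichiometric matrix and $v$
the flux vector in mmol gDW$^{-1}$ h$^{-1}$. The objective is usually the
biomass reaction, whose flux is the growth rate $\mu$. All bounds,
fluxes and reaction extents in this package carry that one unit; SBML
output declares `extentUnits`/`timeUnits` accordingly (extent
mmol gDW$^{-1}$, time h, compartment volumes fl). When the biomass
reaction drains a net molecular weight close to 1 g mmol$^{-1}$
(see `biomass_weight()`), $\mu$ in mmol gDW$^{-1}$ h$^{-1}$ is numerically
comparable to an experimental rate in h$^{-1}$ — the reason the audit
reports this quantity.

Only the optimal *objective value* of an FBA problem is unique.
The flux vector returned is one vertex of the optimal face; quantities
read off it (e.g. the CO$_2$ or ATP rate at a production optimum) can
shift between alternative optima and are documented as vertex-dependent
wherever they are reported.

## The linear-programming core

No LP solver is available in this package's dependency universe, and the
LP *is* the analysis, so `gemfba` carries its own: a dense two-phase
primal simplex on bounded variables (`lp_simplex()`), with Bland's rule
throughout so cycling is impossible, a pivot tolerance of $10^{-9}$, and
re-factorisation of the basis at every step. This is deliberately the
textbook algorithm: at the network sizes this package targets (tens of
reactions) robustness and auditability dominate speed. Three independent
lines of evidence back it:

* a brute-force oracle in the test suite enumerates every vertex of the
  flux polytope on networks with $\le 8$ reactions and must agree with
  the simplex to $10^{-6}$ on dozens of seeded random instances;
* rank-deficient equality systems (stoichiometric matrices always
  contain conserved moieties) are exercised explicitly — artificial
  variables for dependent rows simply remain basic at zero;
* the SBML files the package writes are re-solved with an external
  constraint-based toolchain in a cross-check test, which must reproduce
  the same optima.

Mixed-integer problems (below) are solved by depth-first branch and
bound over the LP relaxation (`milp_solve()`), branching on the most
fractional binary. The binaries in every formulation used here number at
most a handful, so exhaustive search is cheap and exact.

## Loopless FVA

Flux variability analysis (FVA) minimises and maximises each reaction
over the feasible region. Plain FVA admits thermodynamically impossible
circulations around internal cycles — reactions that, combined, convert
nothing but can carry arbitrary flux up to their bounds. The loopless
variant adds the loop law. We implement the nullspace formulation: for
every loop-capable internal reaction $i$ a binary $a_i$ fixes the flux
direction, a pseudo-potential $G_i$ is forced to the opposite sign
($G_i \le -1$ when forward, $G_i \ge 1$ when backward, big-M 1000), and
$N^\top G = 0$ where $N$ is an SVD basis of the nullspace of $S$
restricted to internal reactions. A reaction counts as *internal* iff it
moves no species across the system boundary; exchanges, demands, sinks
and the biomass drain are excluded. Only reactions with non-zero support
in $N$ receive binaries, which keeps the MILP tiny.

A design decision worth recording: a CycleFreeFlux-style LP
post-processing fallback was considered for speed and deliberately *not*
implemented. The MILP is exact, and at the model sizes in scope it
solves in milliseconds; carrying a second, approximate code path would
add surface without adding capability. The `loopless` flag on `fva()`
and `pinned_reactions()` still lets users compare against plain FVA.

The test oracle for looplessness is independent of the MILP: it
enumerates all $2^k$ direction patterns of the loop-capable reactions,
keeps those admitting a potential vector (an LP feasibility check), runs
sign-restricted plain FVA under each, and aggregates.

## The quality audit

**Pseudo-reaction detection** uses the union of two signals — id prefixes
(`EX_`, `DM_`, `SK_`, `sink_`) and SBO terms (exchange 0000627, demand
0000628, sink 0000632, biomass 0000629) — because deposited models vary
in which convention they follow.

**Balance audit.** Element residuals are products minus reactants summed
over `parse_formula()` tallies; atomic masses come from an embedded
IUPAC 2021 table (six significant figures; glucose weighs 180.156).
Missing formulas or charges make a reaction *unverifiable*, never
silently balanced: "imbalanced" and "cannot be checked" are different
findings, and the generic-moiety pseudo-elements R/X force the same
verdict. Element residuals are compared at $10^{-6}$ (coefficients may
be fractional), charge residuals at zero (charges are integers).

**Stoichiometric consistency.** A model is consistent when all
metabolites can carry a strictly positive conserved mass $m$ with
$S_{\mathrm{int}}^\top m = 0$. The usual formulation maximises the
*number* of metabolites above a threshold $\varepsilon = 10^{-4}$ via a
MILP. We avoid the integer program entirely: the feasible set is a
convex cone, so if metabolite sets $A$ and $B$ can each carry positive
mass then $A \cup B$ can simultaneously (add the certificates). A single
LP — maximise $\sum_i z_i$ subject to $z_i \le \min(m_i, \varepsilon)$ —
therefore computes the exact metabolite-fraction metric.

**Energy-generating cycles (EGCs).** Thirteen energy/redox carriers are
scanned: ATP, CTP, GTP, UTP, ITP, NADH, NADPH, FMNH$_2$, FADH$_2$,
menaquinol-8, 2-demethylmenaquinol-8, acetyl-CoA and L-glutamate. All
exchange fluxes are closed, the carrier's canonical dissipation reaction
(ATP hydrolysis, NAD(P)H reoxidation, quinol oxidation with two protons,
acetyl-CoA hydrolysis, glutamate deamination to 2-oxoglutarate) is added
*one at a time* and maximised; any positive optimum certifies a
thermodynamically impossible charging cycle, and the flux-carrying
reactions are reported as its support. The dissipation stoichiometries
are a design choice (the convention leaves them implicit); protons are
balanced in the carrier's own compartment, and a cytosol–periplasm
proton shuttle is added for three-compartment models so proton-motive
cycles are not masked. Carriers absent from a model are skipped with a
warning rather than failing the scan.

## Media semantics

A medium is data — a YAML file mapping exchange ids to uptake
magnitudes — applied by closing every exchange and opening exactly the
listed ones at $-$magnitude, with a uniform default magnitude of 10
mmol gDW$^{-1}$ h$^{-1}$ for every component including ions. Secretion
bounds are never touched. Oxygen is governed by an explicit
aerobic/anaerobic switch that overrides the component list. Whether
aerobic oxygen uptake should be $-10$ or effectively unbounded is a
genuinely open convention; we resolve it by making the oxygen magnitude
a medium component, so each medium states its own aeration. Growth rates
below $10^{-6}$ are reported as 0. The shipped LB file is labelled an
*approximation* (complex media have no exact chemical definition) and is
excluded from any numerical tie-out.

## The synthetic world

The generators are first-class, tested code — the stated world every
property is verified in, not tuning knobs.

`make_linear_chain()` is the minimal flow network: uptake bound 10 by
default, unit stoichiometry, so the maximal growth rate *is* the uptake
bound by flow conservation.

`make_glutamate_core()` emulates glutamate production from glucose in a
~28-reaction carbon core: PTS uptake (consuming PEP), a lumped
Embden–Meyerhof glycolysis (G6P $\to$ 2 PEP, +1 ATP, +2 NADH), pyruvate
kinase, pyruvate dehydrogenase, *both* anaplerotic carboxylases (PEP
carboxylase free, pyruvate carboxylase at one ATP), citrate synthase,
aconitase, NADP-isocitrate dehydrogenase, NADPH-glutamate dehydrogenase,
a respiratory lump, ATP maintenance, glutamate export, and a biomass
drain. Fixed numerical choices of this world:

* biomass consumes L-glutamate with coefficient **0.0149** (the
  convention for this organism's growth function) plus **40** ATP per
  unit growth — 40 mmol gDW$^{-1}$ is a standard growth-associated
  maintenance figure for bacteria;
* the respiratory lump uses a **P/O ratio of 2.5** ATP per NADH, the
  textbook value for a proton-translocating chain;
* glucose uptake is bounded at **10**, the community default; the
  core's native medium supplies oxygen in excess (magnitude 1000) so
  carbon, not aeration, limits the optima — otherwise the analytic
  solutions below would not be closed-form.

Every internal reaction is elementally and charge balanced with real
molecular formulas, so the audit runs on these models unmodified and a
defect-free generator output doubles as the audit's negative control.
With glucose uptake $g = 10$, each glucose yields two C3 units, each
glutamate consumes two (one via acetyl-CoA, one via anaplerosis), and
NADPH made by isocitrate dehydrogenase exactly covers glutamate
dehydrogenase. Hence maximal production is $p(0) = 10$; fixing growth
$\mu$ diverts glutamate into biomass giving the exact line
$p(\mu) = 10 - 0.0149\,\mu$; ATP yield is $8.5$ per glucose, so
$\mu_{\max} = 85/40 = 2.125$. The only degeneracy at a fixed production
optimum is the anaplerotic split — PEP carboxylase versus pyruvate
kinase + pyruvate carboxylase, an internal nullspace vector whose
all-forward sign pattern the loop law correctly *permits* — which is why
the pinned-reaction extraction finds everything pinned except PC, PPC
and PYK, and why knocking out pyruvate carboxylase leaves production
untouched while removing both routes abolishes it.

`plant_defect()` introduces exactly one detector's defect at a time:
a one-hydrogen formula perturbation (imbalance), a produced-but-never-
consumed or consumed-but-never-produced metabolite (dead end / orphan),
a cost-free ATP-charging reaction (EGC), or a reversed duplicate
reaction (thermodynamic loop). One honest subtlety: perturbing a
metabolite's formula imbalances *every* audited reaction it touches, and
two perturbations meeting in one reaction cancel there; the planter
therefore records the exact affected set in the `"planted"` attribute,
and that set is what detectors are held to.

What this world does **not** emulate: genome scale (three orders of
magnitude more reactions), annotation sparsity and identifier noise,
rich alternative-optima structure, thermodynamically subtle quinone
loops, and biomass equations with dozens of precursors. A green test
suite establishes the correctness of the machinery on networks where
ground truth is provable — it does not certify performance or numerical
behaviour on deposited genome-scale models, which additionally require
an industrial LP solver.

## Numerical conventions

* simplex pivot/optimality tolerance $10^{-9}$; phase-1 feasibility
  threshold $10^{-7}$ on the artificial-variable sum;
* FVA clamps the occasional $\mu$-level inversion (min exceeding max by
  solver noise) to the midpoint;
* pinned reactions use the combined closeness predicate
  $|\max - \min| \le \text{abs} + \text{rel}\cdot\max(|\max|,|\min|)$
  with defaults rel $10^{-5}$, abs $10^{-8}$ — the two stated tolerances
  combined additively, the common convention when no combination rule is
  given;
* trade-off curves default to 30 evenly spaced growth values between 0
  and $\mu_{\max}$;
* production records fix growth at 0.4 mmol gDW$^{-1}$ h$^{-1}$ by
  default — inside the plateau where production is only marginally
  growth-limited.

## A worked tour

```{r tour, eval = FALSE}
core <- make_glutamate_core()
fba(core)$objective                       # 2.125, the core's mu_max

aud <- quality_audit(core)                # clean: 0 defects
aud$consistency$consistent_fraction      # 1

tc <- tradeoff_curve(core, "glu__L_c")    # the exact line 10 - 0.0149 mu
ko <- knockout_experiment(core, "PC")     # 9.99404 -> 9.99404 (compensated)
pr <- pinned_reactions(core)              # all pinned but PC, PPC, PYK

write_sbml(core, "core.xml")              # SBML L3V1 + fbc v2 + groups
```

## Known limitations

The pure-R simplex re-factorises densely and is not intended for
genome-scale FVA; the package's contract there is correctness of the
method, demonstrated at oracle-verifiable sizes. No pFBA, MOMA, flux
sampling, dynamic FBA or $\Delta G$-based thermodynamic constraints are
provided. Annotation coverage counts presence per database only; it
resolves nothing over the network. Gene knock-outs implement plain GPR
boolean semantics with no expression levels or enzyme capacities.
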