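# gemfba

Constraint-based analysis of genome-scale metabolic models (GEMs) in R:
SBML model handling, flux balance analysis, loopless flux variability
analysis, model-quality auditing, medium-constrained growth simulation,
and production phenotyping — with deterministic synthetic-model
generators so that every stage is verifiable offline against analytic
ground truth.

## Who this is for

Systems biologists and metabolic engineers who work with stoichiometric
reconstructions — e.g. of amino-acid producer strains such as
*Corynebacterium glutamicum* — and want a self-contained, auditable R
toolchain for the standard constraint-based workflow: read a model,
check its quality, simulate growth on defined media, and analyse
production capabilities and knock-outs.

## The method

A GEM defines the linear program of flux balance analysis (FBA):

    max  c'v   subject to   S v = 0,   l <= v <= u

with `S` the metabolites-by-reactions stoichiometric matrix and `v` the
flux vector in mmol gDW⁻¹ h⁻¹; the biomass reaction's flux is the growth
rate μ. Flux variability analysis (FVA) minimises and maximises each
reaction over that region; the *loopless* variant additionally forbids
thermodynamically infeasible internal cycles via a nullspace
mixed-integer formulation (binary flux directions coupled to
pseudo-potentials orthogonal to the internal-reaction nullspace).
Reactions whose loopless flux range collapses to a point
(|max − min| ≤ 10⁻⁸ + 10⁻⁵·scale) are *pinned*: the rigid backbone of an
optimum. The quality audit covers elemental/charge balance,
dead-end/orphan metabolites, stoichiometric consistency (positive
conserved masses with `S'm = 0`), biomass molecular weight, and
energy-generating-cycle scans over 13 energy/redox carriers with
canonical dissipation reactions.

Because no LP solver exists in this package's dependency universe, the
LP/MILP core (bounded-variable two-phase simplex with Bland's rule,
branch and bound) is implemented in pure R and validated in the test
suite against brute-force vertex enumeration of the flux polytope and
against an external constraint-based toolchain.

## Worked example

The built-in glutamate-producing core network (glycolysis → anaplerosis
→ TCA entry → glutamate, with both pyruvate carboxylase and PEP
carboxylase) has hand-derivable optima:

```r
library(gemfba)
core <- make_glutamate_core()
fba(core)
#> <lp_solution> status: optimal  objective: 2.125

aud <- quality_audit(core)
#> defects: 0   consistency: 1

tc <- tradeoff_curve(core, "glu__L_c")
head(tc, 3)
#>           mu production  status
#> 1 0.00000000  10.000000 optimal
#> 2 0.07327586   9.998908 optimal
#> 3 0.14655172   9.997816 optimal

ko <- knockout_experiment(core, reaction_id = "PC", growth_fix = 0.4)
#> glutamate at mu = 0.4: wild type 9.99404 -> PC knock-out 9.99404

pr <- pinned_reactions(core, growth_fix = 0.4)
setdiff(pr$ranges$id, pr$pinned)
#> [1] "PYK" "PPC" "PC"
```

What the numbers mean: the maximal growth rate is 85/40 = 2.125
mmol gDW⁻¹ h⁻¹ (ATP-limited); glutamate production follows the exact
trade-off line p(μ) = 10 − 0.0149·μ because biomass consumes glutamate
with coefficient 0.0149; knocking out pyruvate carboxylase changes
nothing because PEP carboxylase reroutes the anaplerotic flux — and that
anaplerotic split (PC vs PPC, balanced by pyruvate kinase) is exactly
the set of reactions the loopless-FVA pinning analysis leaves free.

See `vignettes/constraint-based-analysis.Rmd` for the model of the
methods, all tunable parameters, and the design decisions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's full pipeline from scratch against the
installed package — model generation and SBML round-trip, the quality
audit on clean and defect-planted models, growth under the shipped
media, the amino-acid production profile, the growth–glutamate
trade-off, the pyruvate-carboxylase knock-out experiment, and the
pinned-reaction extraction — logging each stage to stderr and writing
the result object to `--out`.
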