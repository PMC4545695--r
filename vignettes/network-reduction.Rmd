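---
title: "Reducing stoichiometric metabolic models to core models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing stoichiometric metabolic models to core models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreduce)
```

## The problem

Genome-scale metabolic reconstructions have grown to thousands of
reactions, which puts many stoichiometric analyses (elementary-mode
enumeration, metabolic flux analysis, kinetic modelling) out of reach
and buries the central metabolism a modeller actually wants to study.
`netreduce` reduces such a model to a *core model* automatically, while
provably preserving a user-declared set of protected parts and
behaviours, instead of relying on error-prone manual curation.

The package works on the standard constraint-based representation. A
network with $m$ internal metabolites and $n$ reactions is an
$m \times n$ stoichiometric matrix $N$; steady state imposes
$N\,r = 0$ on the flux vector $r$, bounds $\alpha_i \le r_i \le
\beta_i$ encode reversibility and capacities, and flux balance analysis
(FBA) maximises a linear objective $z = c^T r$ over this polyhedron.
The dimension of the steady-state space is the degrees of freedom,
$\mathrm{dof} = n - \mathrm{rank}(N)$. Flux variability analysis (FVA)
minimises and maximises each rate individually, yielding the feasible
flux range of every reaction.

## What is protected

A reduction is driven by a protection specification
(`protection_spec()`, or YAML via `read_protection_spec()`):

(a) **protected metabolites** — must keep at least one feasible
    (non-blocked) reaction in the reduced network;
(b) **protected reactions** — never deleted; optionally each must stay
    able to carry nonzero flux (`enforce_protected_feasibility`);
(c) **protected phenotypes** — scenarios, each a set of linear
    inequalities $D_k r \le d_k$ that must remain satisfiable by at
    least one steady-state flux vector. A scenario may override bounds
    (e.g. shut off oxygen uptake for an anaerobic phenotype), and
    constraint strings may use the token `FBA_MAX(rxn)`, which is
    resolved on the *full* model under the scenario's other
    constraints. The idiom `-mu <= -0.999 * FBA_MAX(mu)` therefore
    demands that at least 99.9 % of the full model's maximal growth
    rate stays reachable, without hard-coding the number;
(d) **`dof_min`** — a floor on the degrees of freedom (0 disables it);
(e) **`n_min`** — a floor on the reaction count.

## Pruning

`prune()` first preprocesses: every scenario must be feasible on the
full model (otherwise an error names the offending phenotype), blocked
reactions that are not protected are removed, and unconnected
metabolites are dropped. Blocked-reaction detection uses the base
bounds only; scenarios are tightenings of the base polyhedron, so
anything blocked at base bounds is blocked in every scenario and its
removal is always safe.

The main loop then repeats:

1. Compute FVA for every still-removable reaction under every scenario
   $k$, giving ranges $F_i^k$, and their union
   $F_i = \cup_k F_i^k$ (with no scenarios, the base flux range is
   used).
2. Any reaction whose range is entirely positive or entirely negative
   in *some* scenario must carry flux whenever that phenotype is
   realised: it is **essential** and leaves the removable set for good.
3. The removable reaction with the smallest union width is the deletion
   candidate — removing a nearly-determined flux is assumed to destroy
   the least variability. The deletion is trialled by fixing the
   reaction's bounds to zero and re-testing (a)–(e). On success the
   column is removed and the loop recomputes ranges; on failure the
   reaction is reinserted bit-identically, marked non-removable, and
   the next-smallest candidate from the *same* table is tried.

The loop stops when no removable reaction is left. Because only whole
columns are ever removed, the result is a proper subnetwork: any of its
steady-state flux vectors, zero-padded, is a steady-state flux vector
of the full model. The removal log (`tidy()` on the result) records
every event with iteration, action, and the widths that drove the
choice.

Reactions with identical widths occur routinely (parallel paths), so
the outcome is genuinely non-unique; ties are broken by a seeded
uniform draw (`seed`, recorded in the result) or deterministically by
lowest index (`tie_rule = "lowest_index"`). Equal-width candidates with
capped (unbounded) ranges rank after those without: a capped width is a
lower bound on the true extent, so honest comparison prefers the fully
known range.

Two points the procedure leaves open were settled as follows. The dof
floor is tested on the *tentative* model (column absent) during each
trial, so a deletion that would undershoot `dof_min` is rejected
immediately rather than discovered later. And after a rejection the
next candidate is taken from the same, still-valid range table — the
table only becomes stale after an accepted deletion actually changes
the network. An opt-in `lazy_fva = TRUE` keeps reusing the table across
accepted deletions until a rejection occurs; this can change, but never
invalidate, the trajectory, and is cheaper on large inputs.

## Loss-free compression

`compress()` lumps *enzyme subsets* — groups of reactions whose
steady-state fluxes are proportional in every feasible flux
distribution — into single overall reactions. Detection is one
null-space computation: two reactions are coupled exactly when their
rows in a kernel basis of $N$ are proportional, which costs one SVD
instead of the $O(n^2)$ LPs of pairwise FVA fixing (the FVA method is
retained as the independent oracle in the test suite). Protected
reactions are never members of a multi-reaction subset; a candidate
subset whose implied flux ratios are incompatible with the member
bounds (an irreversible reaction forced backward, no nonzero common
flux) is split back into singletons.

Each subset is replaced by one column $\sum_j \rho_j S_{\cdot j}$,
where $\rho_j$ is the flux of member $j$ per unit flux of the subset's
representative (the member with the largest stoichiometric support,
ties by lowest index — a naming choice only). Internal metabolites
whose rows become all-zero were interior to a lumped chain and are
deleted — unless protected, in which case they are always kept. The
whole transformation is the matrix $T$ with $S_c = S\,T$; the
objective maps as $c_c = T^T c$ and a compressed flux vector $v$
expands to the input-model vector $T v$ (`expand_flux()`). Compression
therefore changes neither the degrees of freedom nor the feasible
(projected) phenotypes, and every FBA optimum is preserved exactly.

Bounds of a lumped reaction are not prescribed by the procedure itself;
the package uses the tightest interval implied by the members,
$\bigcap_j \,[\alpha_j, \beta_j] / \rho_j$ (orientation flipped for
negative ratios), and errors if the intersection is empty — which
cannot happen after pruning, but is guarded anyway. Subset ratios are
computed from the kernel basis and then snapped to nearby
small-denominator rationals (continued fractions, relative tolerance
$10^{-7}$, denominators up to 1000): stoichiometries are rational, so
exact coupling ratios are rational, and snapping removes the float dust
an SVD introduces into reported stoichiometric coefficients.

### The condensed biomass reaction

Pruning typically keeps exactly one synthesis route from a protected
precursor to each biomass component; compression then folds that route
into the biomass synthesis reaction (BSR), replacing each monomer with
the cumulative demand for precursors and cofactors needed to make it.
The recommended setup is the *biomass tracker* convention
(`add_biomass_tracker()`): a pseudo-metabolite `biomass` produced by
the BSR with coefficient 1 plus a protected export reaction. The BSR
itself stays unprotected, so it can be lumped with the synthesis
chains; because it usually has the largest stoichiometric support it
survives as the subset representative, and `condensed_bsr_report()`
reads off the condensed coefficients (negative = consumed). Protecting
the BSR column itself would exclude it from every subset and no
condensed stoichiometry could form — which is why the packaged
worked-example toy protects the export reaction and the tracker
species, not the BSR.

```{r worked}
toy <- build_toy("worked_example")
pruned <- prune(toy$model, toy$spec, seed = 0)
pruned
compressed <- compress(pruned$model, toy$spec)
condensed_bsr_report(compressed, "BSR")
```

The three-step chain (2 P → D; D + NADPH → F; F + ATP → A) feeding a
BSR that consumes 2 A condenses to a biomass reaction consuming 4 P,
2 ATP and 2 NADPH, with the intermediates D, F, A eliminated.

## Numerical choices

* `EPS_FLUX = 1e-9` classifies a flux as zero / sign-definite;
  `EPS_FEAS = 1e-7` is the feasibility tolerance; rank computations use
  a relative singular-value cutoff of `1e-9` times the largest singular
  value. All are per-call arguments.
* Unbounded FVA directions are clipped at `flux_cap = 1e5` (flux units)
  with `capped_lo` / `capped_hi` flags preserved, so candidate ranking
  can compare unbounded ranges honestly rather than dropping them.
* The LP engine is a dense bounded-variable two-phase primal simplex
  written for this package (no LP solver is among its dependencies):
  statuses `optimal` / `infeasible` / `unbounded` are explicit, Dantzig
  pricing switches to Bland's rule under prolonged degeneracy, and the
  basis is re-factorised every iteration — slower than an industrial
  solver but numerically conservative and entirely adequate for the
  dense core-model LPs this package targets. It is cross-checked in the
  test suite against an independent implementation and closed forms.
* A model with no internal metabolites has rank 0, so its dof equals
  its reaction count (relevant for pure transfers between external
  species).

## What the synthetic networks emulate

`random_network()` generates sparse random stoichiometry with exchange
reactions, a configurable reversible fraction, and finite bounds, and
rejection-samples until the draw is mass-connected (every metabolite
reachable from an exchange) and admits a nonzero feasible flux. These
networks drive the property tests: subnetwork preservation,
scenario-optimum preservation, dof invariance of compression, and the
three brute-force oracles (blocked set via two LPs per reaction,
essentiality implication via deletion LPs, subset ratios via FVA
fixing). Defaults (6–8 metabolites, 8–12 reactions, 30 % reversible,
4 exchanges) keep each LP small enough that fifty networks with full
prune + compress runs finish in well under a minute; the packaged toys
pin down the qualitative behaviours (parallel-path ties, unbounded
cycles, trace-element collapse, oxidase preference).

What they do not emulate: genome-scale dimensions, compartments,
biomass reactions with dozens of components, thermodynamically coupled
loops, or the heavy degeneracy of real reconstructions. Passing
property tests therefore validate the algorithmic invariants, not
performance or numerical behaviour at genome scale; genome-scale
inputs are supported through `run_benchmark()` on user-supplied SBML
files, which are deliberately neither shipped nor downloaded.

## Known limitations

* Pruning is greedy and order-dependent; it finds *a* minimal (fixed
  point) subnetwork, not a minimum-cardinality one, and different seeds
  can yield different (equally valid) cores. Only the smallest-width
  selection criterion is implemented.
* FVA tables are recomputed from cold-start LPs; there is no warm
  starting, so genome-scale runs are substantially slower than with an
  industrial solver behind the same interface.
* Elementary-mode counting (`count_efms()`) is an exhaustive
  validation oracle limited to ~20 reactions by design.
* SBML support covers Level 3 + fbc v2 (plus the Level 2 COBRA bound
  convention on read); gene–protein–reaction rules are ignored, as the
  algorithm does not use them.
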