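---
title: "Blocked metabolites: detecting abolished de-novo biosynthesis in constraint-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocked metabolites: detecting abolished de-novo biosynthesis in constraint-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fluxblock)
```

## The question the package answers

A genome-scale metabolic reconstruction describes a cell's biochemistry as a
stoichiometric matrix $S$ ($m$ metabolites $\times$ $n$ reactions) with flux
bounds $lb \le v \le ub$ and gene–protein–reaction (GPR) rules. Flux balance
analysis (FBA) studies the steady-state flux cone $\{v : Sv = 0,\ lb \le v
\le ub\}$ by linear programming.

The package asks, for a perturbation of the network — a gene defect, or the
loss of a cofactor pool such as intracellular folate — *which metabolites
can no longer be synthesized de novo from the growth medium at all*, and
then ranks gene defects by how closely their footprint of newly blocked
metabolites matches the footprint of the cofactor deficiency. The
motivating application is the observation that knockouts of the de-novo
purine-synthesis genes produce nearly the same blocked-metabolite footprint
as folate deficiency, with downstream consequences for ATP, SAM and BH4
supply in dividing cells.

## Why a sink-based definition of "blocked"

The classical definition of a blocked metabolite uses the flux-sum, the
turnover $\Phi_i = \tfrac12 \sum_j |S_{ij} v_j|$: a metabolite is blocked
when its maximal turnover is zero. This definition has a blind spot: a
cofactor that is consumed and regenerated inside a cycle can turn over at a
high rate even when the network cannot synthesize one additional molecule
of it. Pools of such cofactors are diluted at every cell division; without
de-novo synthesis or import they decay exponentially with the number of
divisions, which is exactly the situation of interest in rapidly dividing
cells.

The package therefore measures *producibility*: append to every metabolite
$i$ an irreversible **sink reaction** (`SK_<id>`: consumes one unit of $i$,
produces nothing, bounds $[0, 10^6]$) and maximize its flux,

$$\max\ c^T v \quad \text{s.t.}\quad Sv = 0,\ lb \le v \le ub,$$

with $c$ the indicator of the sink. A metabolite is **blocked** when this
optimum is zero: no steady-state route from the medium replenishes it. The
`cofactor cycle` fixture makes the contrast concrete:

```{r contrast}
t2 <- make_cofactor_cycle()$model
blocked_metabolites(t2)          # Fred/Fox: no de-novo source
is_blocked_fluxsum(t2, "Fred")   # yet the cycle can spin
```

The flux-sum test is implemented without maximizing $\Phi$ itself (a convex
maximization that futile cycles make ill-posed as an LP): $\Phi_i$ can be
positive iff some reaction touching $i$ has a non-degenerate flux
variability (FVA) range, which is what `is_blocked_fluxsum()` checks. This
answers blocked-vs-not, the only question the turnover definition is used
for here.

## Perturbations

* **Gene knockout** (`knockout_genes()`): every reaction whose GPR rule
  evaluates false (knocked genes false, others true; AND = complex
  subunits, OR = isozymes) gets $lb = ub = 0$. Reactions without a rule are
  never disabled.
* **Cofactor deficiency** (`block_consumers()`): every reaction that *can
  consume* any member of a metabolite pool — negative coefficient with
  $ub > 0$, or positive coefficient with $lb < 0$ — is closed. Blocking
  only the import of the cofactor would not work: the intracellular cycle
  would keep regenerating it, and nothing downstream would notice the
  deficit. Instrumentation sinks are exempt (they consume everything by
  construction and would be closed vacuously). Whether membrane transport
  counts as consumption is genuinely open; the default says yes (a
  transporter with a negative coefficient is a consumer by the definition
  above), and `exclude_transporters = TRUE` exempts pure relocation steps.
* **Cofactor strip** (`strip_cofactor()`): removes a consumed/produced
  cofactor couple from a reaction's stoichiometry, leaving the rest of the
  reaction intact — the surgical tool behind the rescue experiment below.

A perturbation's **footprint** is the set difference of blocked metabolites
after minus before (`knockout_delta()`, `deficiency_delta()`). Footprints
are compared by the Jaccard coefficient
$JC(A,B) = |A \cap B| / |A \cup B|$ and by its generalized form over
proportional production reductions,
$JC_g(x,y) = \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)$, where
$x_i = \mathrm{clamp}((\mathrm{native}_i - \mathrm{perturbed}_i)/
\mathrm{native}_i,\ 0,\ 1)$ and $x_i = 0$ for natively blocked metabolites.
$JC_g$ is computed over natively producible metabolites only — natively
blocked ones carry reduction 0 under every condition and would merely
cancel. Two empty footprints compare as 0 (flagged), not 1: agreement about
nothing is not evidence.

## The purine toy end to end

`make_purine_toy()` is a 15-species miniature of de-novo purine
biosynthesis with a conserved folate-analog couple (`THF`/`fTHF`): the
GART- and ATIC-analog steps consume `fTHF` and return `THF`, re-formylated
from formate; IMP yields ATP and GTP; GTP yields the BH4 analog; Met + ATP
yields the SAM analog.

```{r toy}
fx <- make_purine_toy()
scan <- scan_all_genes(fx$model, profiles = TRUE)
glance(scan)

deficiency <- deficiency_delta(fx$model, fx$spec$folate_species)
deficiency$id
```

Folate-analog deficiency newly blocks seven species. Ranking every gene
knockout against that footprint:

```{r rank}
fp <- deficiency_footprint(fx$model, fx$spec$folate_species)
rank_against_reference(scan, fp$delta, reference_profile = fp$profile,
                       markers = c("SAM", "BH4"))
```

The GART analog matches the deficiency exactly ($JC = 1$): both cut the
pathway at the folate-dependent steps. The ATIC analog scores $5/7$ (its
knockout leaves FGAR and AICAR producible), and the side branch scores 0.
On this all-or-nothing toy the generalized coefficient coincides with the
set coefficient, which is also a package-wide invariant for binarized
reduction vectors.

The rescue experiment asks whether purine blockage is the *only* route by
which the deficiency reaches SAM: strip the folate couple from the two
dependent steps, exempt those steps from the consumer blockade, and re-run
the deficiency.

```{r rescue}
stripped <- strip_cofactor(fx$model, fx$spec$folate_steps, list(c("fTHF", "THF")))
rescued <- suppressWarnings(
  deficiency_delta(stripped, fx$spec$folate_species,
                   exclude_reactions = fx$spec$folate_steps))
"SAM" %in% rescued$id
```

SAM production is restored, so within the model the folate deficit
propagates to SAM exclusively through purine synthesis.

## Verification: an exact oracle against the LP

Producibility decisions ride on an LP solver, so the package carries its
own independent ground truth. `oracle_producible()` enumerates the extreme
rays of the flux cone of the (fully sink-augmented) network by the double
description method in exact integer arithmetic — reversible reactions
split, every intermediate ray gcd-reduced, adjacency decided by the
zero-set criterion — and declares a metabolite producible iff some
elementary mode carries positive sink flux. This shares no code with the
simplex path. The test suite and the acceptance script check LP-vs-oracle
agreement for every metabolite of 100 seeded random fixtures (6–12
reactions, integer coefficients in $\{-2,-1,1,2\}$, 70% irreversible, at
least one exchange) in the native state and under one gene knockout each,
plus the three structured toys; agreement is 100%.

Enumeration is exponential in the worst case, so the oracle refuses
networks above a fixed reaction count (default 16, which admits the purine
toy; the random-fixture generator stays at 12).

## Numerical and design choices

* **Zero threshold.** A flux is zero iff $|x| \le \varepsilon$ with
  $\varepsilon = 10^{-6}$ by default (`options(fluxblock.epsilon = ...)`),
  sitting between simplex tolerance ($\sim 10^{-9}$) and the smallest
  meaningful flux relative to uptake bounds of order 10. Every blockedness
  decision routes through this one predicate (`is_flux_zero()`).
* **Finite flux cap.** Sinks and clamped infinite bounds use $10^6$ flux
  units rather than $\infty$, keeping every LP bounded; the gap between
  $\varepsilon$ and the cap is twelve orders of magnitude, so the
  blockedness decision is insensitive to the cap.
* **LP backend.** A dense two-phase simplex with Dantzig pricing falling
  back to Bland's rule (guaranteed termination under the degeneracy that
  flux networks produce) ships inside the package; problems here are tens
  of rows, where a dense tableau is both simple and fast. It is validated
  by the oracle-agreement suite above.
* **Blocked reactions** are computed on the bare network by default:
  instrumentation sinks would act as universal drains and unblock
  dead-end-limited reactions. `with_sinks = TRUE` gives the augmented
  variant, in which sinks themselves are never reported.
* **Medium semantics.** The uptake direction of an exchange reaction is
  read off its stoichiometry (the direction importing the compound), not
  from a bound-sign convention, because SBML dialects differ. Unlisted
  exchanges are closed for uptake only; secretion stays open. Blocked sets
  are invariant to uniform scaling of medium bounds (producibility is a
  conic question), which the tests assert.
* **Compartments.** Metabolite identity is per compartmentalized species;
  `collapse_compartments()` provides the base-id report view for reading
  results the way pathway databases name metabolites.
* **Folate pool.** "Any form of folate" is a user-supplied id set;
  a curated default of the canonical folate forms in BiGG/Recon
  nomenclature ships as editable data (`folate_species()`), expanded per
  model across intracellular compartments.
* **Scan economy.** `scan_all_genes()` computes the native blocked set
  once, shares evaluations between genes with identical disabled-reaction
  signatures, and short-circuits genes that disable nothing; a test
  asserts equality with naive per-gene evaluation.

## What the fixtures do and do not show

The synthetic networks exercise the semantics the method depends on —
conserved cofactor pools, folate-analog-dependent steps, branched
biosynthesis, OR/AND gene rules, byproduct-coupled pathways — at a size
where exact enumeration is possible. Problem sizes were chosen so the full
suite and the acceptance run each finish in about two minutes: 100 random
fixtures of 6–12 reactions, toys of 6–20 reactions. They do not emulate
genome-scale properties: thousands of reactions, extensive compartment
structure, isozyme-rich GPRs, or the curation artifacts (dead ends,
unbounded cycles) of real reconstructions. Passing tests certify the
method's semantics, not any biological claim about a particular
reconstruction; genome-scale runs take an externally supplied SBML file
through the same `cmd_*` workflow.

## Known limitations

* Producibility is qualitative; the package deliberately does not rank
  partial (type-2) production reductions beyond the generalized Jaccard
  input, and does not model growth objectives, thermodynamics or loopless
  constraints.
* The dense simplex targets small-to-medium LPs. Genome-scale models are
  read and analyzed correctly but slowly; the per-metabolite loop is
  embarrassingly parallel and the solver is abstracted behind one
  `lp_solve()` entry point should a faster backend become available.
* `strip_cofactor()` removes a couple per reaction; reactions coupling the
  cofactor with stoichiometry other than 1:1 on both members are stripped
  of the pair as written, which changes mass balance exactly as intended
  only for genuine couples.
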