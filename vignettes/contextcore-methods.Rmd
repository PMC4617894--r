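---
title: "contextcore: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{contextcore: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextcore)
```

# The model

`contextcore` works on constraint-based metabolic models: a stoichiometric
matrix $S$ (metabolites × reactions), flux bounds $lb \le v \le ub$, and
the steady-state assumption $S v = 0$. Three LP primitives are built on
this:

* **FBA** (`maximize_flux`): $\max v_{obj}$ subject to the constraints.
* **FVA** (`fva`): per reaction, $\min v_i$ and $\max v_i$.
* **Consistency** (`fastcc`): the set of reactions that can reach
  $|v_i| \ge \varepsilon$ in some feasible flux distribution. Implemented
  as the LP-7 sweep — maximize the number of candidate reactions pushed
  above $\varepsilon$ at once, flip the bounds of unsupported reversible
  candidates, and fall back to singletons — with the naive $2n$-LP FVA
  definition shipped alongside as an independent oracle
  (`blocked_reactions_fva`). The test suite asserts their equality on
  dozens of randomized fixtures.

Context extraction (`fastcore_extract`, `modified_fastcore`) alternates
LP-7 with LP-9, which fixes the supported core fluxes at
$\varepsilon \cdot s$ (scale $s = 10^5$) and minimizes
$\sum_i w_i |v_i|$ with weight 1 on penalized reactions and 0 on core and
non-penalized reactions. LP-9 is solved in scaled flux space (bounds
multiplied by $s$, solution divided back): the scaling is a numerical
device of the algorithm lineage, and applying it to the forced flux alone
would collide with finite capacities on small networks (a toy model with
an uptake cap of 10 cannot force two branch reactions to 10
simultaneously). The support semantics — which reactions exceed
$\varepsilon$ — is unchanged by this choice.

The workflow (`run_workflow`) composes the pieces exactly as the
extraction method prescribes: discretize, map through GPR rules, split
scored reactions into core / non-penalized transporters / inactive, zero
the inactive bounds, re-check consistency, then extract. With a biomass
reaction, pass 1 forces biomass while leaving core reactions and core
transporters free of cost so the biomass support re-uses expression-backed
machinery; the pass-1 output joins the core (transporters moved to the
non-penalized set) and pass 2 forces the whole core.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `eps` | 1e-4 | minimal flux magnitude counting as "carrying flux" (flux units); the value used throughout the FASTCORE lineage |
| solver feasibility tol | 1e-9 | at least 100× below `eps` by construction |
| discretization thresholds | 0 / 5 | z ≤ 0 → −1, z > 5 → +1; z = 5 itself scores 0 (strict "above") |
| consensus fractions | 0.9 (arrays), 0.75 (donors) | share of samples required for a +1/−1 consensus call |
| LP-9 scale | 1e5 | anti-degeneracy scaling of the forced core flux |
| essentiality cutoff | 0.01 | fractional growth decrease above which a knockout is essential |
| enhancer extension | 450 bp | symmetric growth of short peaks (odd base to the end side; clipping at 0 shifts the deficit right, preserving length) |
| nearest-gene cap | 500 kb | maximal region-midpoint-to-TSS distance |
| HRL rule | top 10 % ∩ ≥ 7 | boundary ties in the top decile are included |
| cofactor list | ATP/ADP/AMP, GTP/GDP, UTP/UDP, CTP/CDP, NAD(H), NADP(H), FAD(H₂), acetyl-CoA/CoA pairs; H⁺, H₂O, Pi, PPi, O₂ and common ions; CO₂/HCO₃⁻ | fully overridable via `cofactor_config()`; entry-point results are cofactor-config-dependent |

Probe-to-gene collapse takes the maximum z over a gene's probes
(`collapse_probes`), favoring detection; the upstream normalization and
frozen reference estimation are out of scope — the package consumes
z-scores or (reference mean, reference SD) tables.

# Cross-validation semantics

`crossvalidate` repeats the reconstruction once per core reaction with
that reaction left out. Retained reactions present in **all** runs are
supported by at least two core reactions → **high**; core reactions
absent from their own left-out run rest on their own expression call only
→ **moderate**; the rest → **low**. Note that with a forced biomass
reaction its unique support appears in every run and is therefore *high*
by this definition — being forced is itself multi-evidence. The same
procedure over the inactive set labels exclusions: a reaction that
reappears as soon as its own inactive call is lifted was excluded on
**single-evidence**, one that stays out on **multi-evidence**.

# Entry points and positional enrichment

Flux directions come from FVA on the consistent model (bounds alone
overstate reversibility). For each gene-associated non-transporter
reaction and each feasible direction, consumed metabolites are filtered:
inorganics and CO₂ always, cofactor couples when both members sit on
opposite sides (acetyl-CoA only when CoA is the opposite member, i.e. it
acts as CoA donor), and same-formula couples when formula annotations are
present. Reactions left with no metabolites are not considered. A
producer of a remaining substrate from a different subsystem marks an
entry point after a **pathway change**; a transporter producer is traced
to the origin compartment, where producers in the reaction's own
subsystem mark a **compartment change** and foreign ones a pathway change
(pathway change dominates when both occur; transported from the boundary
counts as a pathway change). Hypergeometric positional enrichment is
computed in three modes; in the transporter-excluding mode both the
population and the successes drop transporters, and draws count
high-regulatory-load *reactions* (the source description is ambiguous
between genes and reactions; reactions keep the counts in one universe).

# What the synthetic data does and does not establish

`make_toy_model`/`make_random_model` build small pathway networks with
planted blocked reactions; `simulate_expression` draws active genes from
N(8, 1) and inactive ones from N(−1, 1), so active genes clear the +1
threshold with probability Φ(3) ≈ 0.9987 per sample and inactive genes
score −1 with probability Φ(1) ≈ 0.84; `simulate_peaks` plants per-gene
enhancer counts with sub-peak-length replicate jitter and genes 1 Mb
apart, making nearest-gene assignment unambiguous. A green suite
establishes that the algorithms implement their definitions exactly on
networks where exhaustive search is feasible and that the pipeline
recovers planted truth under clean signal. It does **not** establish
behaviour on genome-scale reconstructions (thousands of reactions,
degenerate alternative optima, noisy annotations), platform-specific
normalization effects, or the adequacy of the default cofactor list for a
real reconstruction's namespace.

# Numerical choices

* The LP solver is a dense two-phase bounded-variable simplex with
  Bland's anti-cycling rule; infinite bounds are boxed at 1e7 and a
  solution pressed against that box on an originally unbounded variable
  is reported as unbounded. Adequate and exact at fixture scale; not
  intended for genome-scale models.
* Flux support uses the threshold $0.99\,\varepsilon$ to absorb solver
  tolerance, as in the algorithm lineage.
* Tie-breaking among equal-cost supports is deterministic (fixed pivot
  rules and reaction ordering), so identical inputs give identical
  models; equal-cost alternatives may differ between input orderings,
  which is why only the consistency *set* (not the support choice) is
  asserted order-independent.
* The permutation p-value counts null statistics
  $\ge D_{obs} - 10^{-9}$: the observed statistic is an atom of the
  permutation distribution and strict floating-point comparison would
  bias the estimate downward.
* `reproducible_regions` uses the reference-replicate convention
  (intervals of replicate 1 overlapping ≥1 bp with every other
  replicate); a merged-intersection variant is available behind
  `mode = "intersect"` since the source pipeline's merged representation
  is not specified. Peak extension is applied before replicate
  intersection in the pipeline order used here, matching the stated
  order of the original workflow; both orders are trivially composable
  from the exported functions.

# Known limitations

* The simplex is $O(\text{rows} \times \text{cols})$ per pivot with a
  dense tableau — fine below a few hundred reactions, unsuitable beyond.
* SBML support covers L3+fbc v2 and legacy note-encoded annotations, not
  every historical dialect; models are re-validated on read and
  bound inconsistencies are reported per reaction.
* Entry-point classification inherits subsystem annotation quality;
  unannotated reactions are skipped with a warning, and generic
  reconstructions are known to leave many branch/entry points
  unannotated.
* No thermodynamic or loopless constraints: a fully reversible internal
  cycle counts as flux-consistent by definition of the method family.
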