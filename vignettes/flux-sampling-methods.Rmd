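---
title: "Constrained flux sampling and informative-flux extraction: methods"
author: "fluxpin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained flux sampling and informative-flux extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxpin)
```

## The problem

A constraint-based metabolic model defines, for a given organism, the set of
flux distributions $v$ compatible with steady state and capacity limits:

$$\mathcal{P} = \{\, v : S v = 0,\ \ell \le v \le u \,\}$$

where $S$ is the stoichiometric matrix (metabolites $\times$ reactions) and
$\ell, u$ are per-reaction bounds in mmol·gDW⁻¹·h⁻¹ (COBRA sign convention:
uptake through an exchange reaction is negative). Flux balance analysis
picks one point of $\mathcal{P}$ by optimising an objective; flux *sampling*
instead draws many points, treating the metabolic state as uncertain within
$\mathcal{P}$.

fluxpin implements a pipeline built around one question: **which fluxes, and
how many, must be measured to pin the cell's metabolic state down to
(approximately) one flux distribution?** Exchange fluxes — substrate uptake,
gas exchange, by-product secretion — are cheap to measure in the culture
medium; intracellular fluxes are not. If a handful of exchange measurements
suffices to identify the state, expensive omics campaigns can be replaced or
focused.

The stages are:

1. **Constraint seeding.** Plain hit-and-run sampling of a genome-scale
   polytope concentrates in a narrow band of the phenotypically important
   fluxes and can miss experimentally observed combinations of substrate
   uptake, growth and product formation. The pipeline therefore generates
   seed triples (substrate, growth, product) by nested FBA: draw the
   substrate uptake uniformly over an experimentally motivated interval,
   bracket the feasible growth range at that uptake by FBA min/max and draw
   growth uniformly inside it, then do the same for the product with both
   clamped. Sampling is then run *sequentially*, a small batch per seed,
   inside the polytope clamped at each triple.
2. **Diversity check.** Both sample sets (seeded and default) are rescaled
   to a common basis of 100 units of substrate uptake per row and compared
   on one metric-MDS plane; the mean distance of each labelled cloud to its
   centroid (`spread_metric()`) summarises coverage.
3. **Importance ranking.** For each candidate (exchange) flux, every sampled
   value in turn is used as a ±10% query against the whole set; a flux whose
   query windows isolate few samples is an informative measurement. Fluxes
   are ranked by mean hit count, ascending.
4. **Grouping and minimum-flux estimation.** Fluxes with $|r| \ge 0.95$
   (Pearson, over samples) are linked and grouped by connected components;
   group members are mutually redundant measurements. Repeatedly: draw one
   representative per group, shuffle the group order, and for every target
   row apply the representatives' values (±10%) as cumulative filters until
   one sample remains. The mean and median of the number of filters needed,
   over orderings × target rows, estimate how many measured fluxes identify
   a state.
5. **Validation.** Sampled distributions are compared against an external
   ¹³C metabolic flux analysis reference table (per 100 substrate): rows
   matching a measured anchor flux (e.g. CO₂ emission, ±10%) are selected
   and scored by mean absolute percentage error over a set of
   central-carbon reactions; the best k are reported.

## The LP engine

No linear-programming backend is assumed: the package carries a dense
bounded-variable two-phase primal simplex (`R/simplex.R`) sized for the
desk-scale models it ships. Design points:

* Feasibility/optimality tolerances are $10^{-9}$; the steady-state check
  applied to samples downstream uses $10^{-6}$.
* "Clamping a flux at $x$" is implemented as the interval
  $x(1 \pm 10^{-6})$ (absolute $10^{-9}$ at zero), never exact equality, so
  floating-point noise cannot make a feasible clamp infeasible.
* Degenerate optima are accepted as-is: only objective values and
  flux ranges are contractual, never the coordinates of a particular
  optimal vertex.
* The basis is refactorised every iteration and the pivot rule switches
  from Dantzig to Bland's rule after a fixed iteration count, trading speed
  (irrelevant at this scale) for robustness against cycling.
* Correctness is tested against exhaustive vertex enumeration on every toy
  with few free dimensions, and on randomised bounded LPs during
  development.

## The sampler

The hit-and-run core follows the artificially-centred scheme: from the
current point, the direction is (random warmup point − running centre of
all points seen), which preferentially aligns steps with the polytope's
elongated axes; the step is uniform on the feasible segment; every
`thinning`-th point is kept. Warmup points are the flux-variability corners
(each reaction minimised and maximised), plus random ±1 objective
combinations if more are requested. Multiple chains in the style of
parallel samplers are independent ACHR chains from distinct warmup starts
whose outputs are concatenated; the contract is sequential-equivalent
(same seed ⇒ same matrix regardless of scheduling), so reproducibility is
never a function of worker count.

Numerical choices:

* Default configuration: 20,000 samples, thinning 10,000, 10 chains —
  the full-scale case-study setting. Desk-scale analyses pass smaller
  values explicitly; the vignette and tests use thinning 5–50 on toys with
  ≤ 6 free dimensions, where the chains mix within a few steps.
* Kept points are re-projected onto the null space of $S$ every 100
  samples (and once when a chain ends), so numerical drift cannot
  accumulate over long thinned runs; after projection, points are clipped
  to bounds. Both residuals stay far below the $10^{-6}$ row tolerance.
* Directions with a numerically empty feasible segment (width $<10^{-12}$)
  are resampled and counted; a run of $10^6$ consecutive failures aborts.
* No burn-in is discarded: on the desk-scale toys the first kept samples
  are statistically indistinguishable (in distance-from-centre terms) from
  late ones, so a burn-in parameter would be dead weight at this scale.

The coordinate-hit-and-run-with-rounding family is deliberately not
implemented: rounding is known to fail on large models with many
near-fixed fluxes, which is exactly the regime this pipeline targets;
single-chain ACHR is available as `n_chains = 1`.

## Toy models: what they emulate, what they do not

`make_toy_model()` builds four topologies with analytically known
geometry, so every stage is testable without downloading a genome-scale
model:

* `linear_chain` — the polytope is a segment; all internal fluxes equal.
* `diamond` — two parallel branches; branch fluxes sum to the inlet.
* `box` — independent exchange pairs; the polytope is an axis-aligned box
  with uniform marginals and an analytic centroid, the reference case for
  sampler uniformity (Kolmogorov–Smirnov and centroid checks).
* `core_like` — a ~20-reaction caricature of central metabolism: glucose
  uptake, lumped glycolysis and a pentose-phosphate-like branch, a
  two-step TCA whose steps are fully coupled through a dedicated
  intermediate, respiration, acetate overflow, lactate and α-ketoglutarate
  release valves, a biomass-like sink consuming several precursors
  (including a trace iron requirement), and a forced ATP maintenance
  drain. Exchange capacities are jittered by the seed. Stoichiometry is
  stylised, not elementally balanced; what is engineered is the polytope:
  strictly positive optimal growth, a coupled pair, an overflow branch and
  measurable exchanges.

What passing tests on these toys shows: the LP engine, sampler, seeding,
ranking, grouping, filtering and validation machinery are correct on
polytopes whose geometry is known exactly. What it does **not** show: any
claim that depends on the *high dimensionality* of a genome-scale
polytope. The clearest instance is the diversity comparison: in a
genome-scale model, default sampling concentrates (volume mass
concentration in ~10³ dimensions) and constraint seeding visibly widens
the normalized sample cloud; on a toy with ~6 free dimensions default
sampling already covers the phenotype ranges, and the seeded set is wider
in only about half of random runs — the package's acceptance suite states
this check as specified and records the outcome rather than weakening the
test. Full-scale behaviour is exercised by `scripts/full_scale.R`, which
needs the iJO1366 model file and hours of CPU.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_samples` | 20,000 | kept flux vectors (default-mode sampling) |
| `thinning` | 10,000 | chain steps per kept sample |
| `n_chains` | 10 | independent ACHR chains |
| `n_patterns` | 1,000 | constraint seed triples |
| `per_pattern` | 20 | kept samples per seed |
| `substrate_interval` | — | signed uptake range for the substrate draw; must come from experimental data, no default is meaningful |
| `rel_window` | 0.10 | relative query/filter/selection half-width |
| `correlation_threshold` | 0.95 | \|r\| cutoff for flux grouping |
| `n_orders` | 800 | orderings in the minimum-flux estimate |
| `k` | 5 | best samples reported by validation |

Resolved design questions (where the procedure description leaves room):

* **Zero query values.** A ±10% window around zero matches only exact
  zeros; queries at zero use an absolute window (default $10^{-6}$).
* **Ranking order.** Ascending mean hit count (fewest hits = most
  informative); ties break by median, then reaction id.
* **Grouping.** Connected components of the $|r| \ge 0.95$ graph — the
  transitive reading of "grouped", and the only one that yields the
  partition the minimum-flux procedure needs. Zero-variance fluxes have
  undefined correlation and carry no discriminating information; they form
  one designated constant group excluded from representative drawing.
* **Representatives.** Re-drawn independently for each ordering trial
  (`fixed_representatives = FALSE`), the closest reading of the stepwise
  procedure; a switch fixes them once instead. An `orderings =
  "exhaustive"` mode enumerates all group permutations so small instances
  can be checked against complete enumeration.
* **Unresolved targets.** If duplicates remain inside every window after
  all groups are applied, the count is the number of groups and the trial
  is flagged (`n_unresolved`), not an error.
* **Degenerate seed ranges.** A growth or product range narrower than
  $10^{-9}$ yields its midpoint. Infeasible draws retry up to 10 times,
  then the pattern is flagged infeasible and skipped with a warning at
  sampling time.
* **MAPE.** Reactions with a reference flux of exactly zero are excluded
  from the sum (the ratio is undefined) and logged. Signs are compared
  as-is: literature fluxes reported in the opposite direction must be
  sign-mapped in the reference CSV (`direction_sign` column), because a
  genuine sign disagreement between sampled and reference flux is
  information, not noise.
* **MDS.** Metric MDS: classical scaling initialisation refined by SMACOF
  (Guttman transform) iterations — deterministic, so embeddings are
  reproducible without seed juggling. Distances are Euclidean over all
  reactions after substrate normalization; a `reactions` argument
  restricts to a subset (e.g. exchanges only).

## Problem sizes used by the shipped analyses

The test-suite and the acceptance script run entirely on toys: 5,000-sample
validity and uniformity checks per topology, a 20-pattern × 5-sample
sequential run against a 100-row default run on `core_like`, 50-row
synthetic sets for the oracle comparisons, and exhaustive (24-ordering)
minimum-flux enumeration on a 10-row, 4-group set. These sizes were chosen
so that each stage's contract is exercised with margins (e.g. the
Kolmogorov–Smirnov statistic at $n = 5000$ sits near 0.015 against a 0.05
gate) while a full run of everything remains a coffee-break affair.

## Known limitations

* The simplex is dense and refactorises every iteration: fine up to a few
  hundred reactions, slow for genome-scale FVA. The full-scale script
  works but is patient work; a sparse LP backend would be the first
  optimisation.
* Uniformity of hit-and-run output is only tested at desk scale; on
  genome-scale polytopes all hit-and-run samplers mix slowly and no
  convergence diagnostic (R-hat, volume estimation) is provided.
* The minimum-flux estimate is conditional on the sample: it answers "how
  many fluxes isolate one *sampled* distribution", which approaches the
  biological question only as sampling covers the polytope.
* Gene–protein–reaction logic, knockouts, thermodynamic constraints and
  parsimonious-FBA variants are out of scope.
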