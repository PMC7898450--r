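---
title: "Contextualizing probabilistic logic models of signalling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualizing probabilistic logic models of signalling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnet)
```

## The model and its assumptions

`plnet` works with signed, weighted, acyclic interaction graphs in which
every node carries an *activity* in [0, 1] — the probability (equivalently,
the fraction) of the protein being in its active, usually phosphorylated,
state. Input nodes are clamped by the experimental condition: a growth
factor present in the medium is 1, a kinase-inhibitor drug applied to the
cells is 1, everything else 0 (fractional doses are allowed). Every other
node is computed, in topological order, as

\[ a_v = \Big(\sum_{u \to v} w_{uv}\, a_u\Big) \prod_{i \dashv v} (1 - w_{iv}\, a_i), \]

the probabilistic "non-competitive OR" of its activators, attenuated by each
inhibitor independently. Three structural assumptions follow:

* **Simplex convention.** The activating weights into a node sum to exactly
  1 whenever the node has at least one activator, so each weight is the
  *relative contribution* of that parent. A node with a single activator
  therefore transmits its parent's activity unchanged (weight 1), and a
  node with no activators is silent (activity 0) — there is no basal
  activity term. Inhibitor weights are free in [0, 1].
* **Steady state, not dynamics.** Signal propagation is described by its
  fixed point only. On an acyclic graph one topological sweep from the
  clamped inputs *is* that fixed point, which is why the result cannot
  depend on any initialization; the test suite checks this against damped
  fixed-point iteration from many random initial states. Cyclic networks
  are rejected outright rather than iterated: with feedback the fixed point
  need not be unique and the steady-state reading becomes ambiguous.
* **Independent inhibition.** Several inhibitors of one node act as
  independent probabilistic filters (a product), rather than through a
  minimum or another gate. No AND-gates are instantiated anywhere.

## Measurements and their preprocessing

A `measurement_set` holds, per context (cell line), a condition table over
the input nodes and the measured activities of the output nodes with
optional SEMs. Immunoblot quantifications reach that scale through
`normalize_blots()`: the phospho/total intensity ratio per lane, division
by the mean ratio of the lane's blot (making blots comparable across
day-to-day technical variability), then min–max scaling of each output
series onto [0, 1]. The min–max step is the simplest map achieving the
unit-interval convention; it anchors the weakest observed condition at 0
and the strongest at 1, which is appropriate for designs that include both
a near-silent control and a strongly stimulated arm, and it makes the
result invariant to per-blot gain. A series with no spread maps to 0.5.

## Fitting

Given datasets from $C$ contexts, `fit_network()` minimizes

\[ \mathrm{MSE} + \lambda_P \underbrace{\sum_{v,c}\Big(\sum_u w^{(c)}_{uv} - \max_u w^{(c)}_{uv}\Big)}_{\text{pruning}} + \lambda_U \underbrace{\sum_{\theta}\sum_{c}\big|w^{(c)}_{\theta} - \mathrm{med}_c\,w^{(c)}_{\theta}\big|}_{\text{uniformity}} \]

with the MSE pooled over all non-missing measured cells of all contexts.
The pruning term is the activation mass a node assigns beyond its single
strongest activator — zero exactly when every node relies on one parent —
and drives co-activation unsupported by the data out of the model. The
uniformity term is an L1 fusion toward the cross-context median of each
parameter: it collapses small, unsupported differences between cell-line
models while leaving well-supported differences intact. Both are surrogate
forms chosen for satisfying those qualitative roles; they are design
decisions of this package, not transcriptions of any published formula.

**Parameterization.** Activator weights are optimized through unconstrained
auxiliaries mapped by a per-node softmax onto the simplex; inhibitor
weights are optimized directly with projection onto [0, 1] (auxiliaries
clamped to ±30, bounding softmax weights away from exact 0/1 by ~1e−26).
Cross-context *hard* ties (the single model, merged parameters of the final
model) share one auxiliary. At a node mixing tied and context-specific
activators, the simplex renormalization can make a tied label's realized
weight differ slightly between contexts; fitted objects report sharing as
achieved, splitting any group whose realized values diverge.

**Optimizer.** Projected gradient descent with Barzilai–Borwein step
lengths under an Armijo backtracking safeguard, so the accepted loss is
non-increasing by construction; gradients are analytic (reverse-mode
through the topological sweep, the softmax and the penalties). Two
numerical choices matter for the L1 term: its kink is huberized with radius
1e−4 for the optimizer only (the exact L1 value is what is reported and
what enters the total loss), and a *tie proposal* is interleaved — the
optimizer periodically proposes averaging each label's auxiliaries across
contexts and, when that lowers the loss, continues descending inside the
equality manifold, where the penalty is flat. Without this move, descent
creeps along the kink at a rate set by the huber radius; with it, the
strong-$\lambda_U$ limit reproduces the hard-tied fit to ~1e−4 per
parameter. All proposals are accept-on-decrease, so the monotone-trace
invariant survives. Defaults: 20 uniform-random multi-starts (simplex
weights flat-Dirichlet, inhibitors uniform), relative loss tolerance 1e−9
held for 5 iterations, 5000 iterations maximum, everything seeded — the
same seed, configuration and data give bit-identical results.

## Model selection and reduction

`scan_lambda_grid()` fits every cell of a $(\log_2\lambda_P,
\log_2\lambda_U)$ grid (default $\{-14, -12, \dots, 0\}^2$, spanning the
regime from effectively unpenalized to fully collapsed). Because penalties
bias the weights they shrink, each cell's score is computed on a *debiased*
refit: the sharing structure the regularized fit selects (labels whose
cross-context SD falls below the 0.01 merge tolerance are tied) is frozen
and the model refit with both penalties at zero — the same logic as relaxed
sparse regression. Cells then compete on
$\mathrm{BIC} = N\ln(\mathrm{MSE}) + k\ln N$, the Gaussian-error BIC up to
constants, with $k$ counting one parameter per uniform label and $C$ per
context-specific label. Without the debiasing step the scan systematically
prefers under-regularized cells, because the bias at the structurally
correct cell costs more MSE than overfitting does; with it, on synthetic
two-context data the scan recovers the exact number of context-specific
parameters in essentially every seed. Ties in BIC break toward larger
$\lambda$ values — the sparser model.

`reduce_and_refit()` fixes the final topology: edges whose flux — fitted
weight × mean steady-state source activity, averaged over every condition
of every context — falls below 0.01 are removed (an edge can only be
trusted where its source is ever active); labels with cross-context SD
below 0.01 are merged into one shared parameter; and the reduced model is
refit unregularized for unbiased final estimates. Removing edges can only
fail if an output loses all paths from the inputs, which is reported as a
structural error rather than silently accepted.

## Uncertainty

`resample_parameters()` repeats perturb-and-refit: each round adds
independent Gaussian noise to every measured cell with SD equal to
`noise_scale` × the cell's SEM (the proportionality constant defaults to 1,
since only proportionality is assumed; a global scale substitutes when no
SEMs exist), clips back onto [0, 1] — a slight truncation of the Gaussian,
accepted because activities are probabilities — and refits the final
topology. Each parameter is summarized by the mean and SD over rounds
(default 20). At `noise_scale = 0` every round reproduces the point fit
exactly; SDs grow with the noise scale, and both properties are asserted in
the test suite.

## The synthetic-data generator

`generate_ground_truth()` draws one shared valid parameter set (activator
simplexes flat-Dirichlet; inhibitor weights uniform on [0.5, 1], strong
enough for a drug's effect to be visible over noise) and makes a requested
number of labels context-specific by shifting them at least 0.2 in one
context. By default only inhibitor labels are eligible: one coordinate of a
simplex cannot move alone, so perturbing an activator label drags its
siblings along and the realized sharing structure would no longer match the
requested count; activator perturbations are available explicitly, with
that collateral renormalization documented. `simulate_dataset()` composes
the simulator with clipped Gaussian noise (default SD 0.05, a typical
replicate-SEM magnitude for normalized immunoblot activities) and records
the generating SD in the SEM columns.

Two fixtures accompany the generator. `chain_network()` is a seven-node
branched chain whose five free labels are all identifiable under the
16-condition full factorial of `chain_design()`; it is the workhorse of the
recovery, limit and sparsity experiments. `lplastin_prior_network()` is a
literature-style rendering of the candidate network upstream of L-plastin
Ser5 phosphorylation — EGF/HGF/IGF/PMA stimulators, five drug inputs
(RSK, AKT, FAK, MEK and dual PI3K/mTOR inhibitors), the
Ras→Raf→MEK→ERK→RSK cascade, PI3K→PDK1→{AKT, SGK} with mTORC1/mTORC2
split into their two complexes to keep the graph acyclic, FAK and Src as
cross-talk hubs, PKA and PKC, and exactly five activating edges into LPL
(from RSK, SGK, PKA, PKC, p70S6K). It is a synthetic, literature-style
reconstruction; externally curated interaction lists in the same TSV
dialect load through `read_network()`. Routing of PKA
through the receptor layer is a generic stand-in for its less-characterized
upstream input. `paper_design()` enumerates the perturbation design:
control, each stimulator alone, each of the three modelling inhibitors
alone, and all inhibitor×stimulator pairs — 20 conditions per cell line,
12 for MCF7, whose missing EGF/HGF receptors remove those arms; the two
validation drugs ride along as always-off inputs.

What the generator does *not* emulate: blot-level technical artifacts
beyond Gaussian noise, saturation or background in densitometry,
correlations between output nodes' errors, off-target drug effects, or
model misspecification (data are generated by the same update rule that is
fit). Passing recovery tests therefore demonstrates that the estimation
machinery works when the model class is right, not that the model class is
right for any particular biological dataset.

## Identifiability

Not every weight is estimable from every design. When two parents of a node
carry nearly identical signals — for instance when an upstream simplex is
nearly degenerate — only the sum of their contributions is determined, and
any split fits equally well. `identifiable_labels()` screens for this with
a central-difference sensitivity: a label is kept only if moving its weight
(redistributing the complementary simplex mass proportionally) changes the
simulated outputs by at least 0.1 RMS per unit weight in some context.
Recovery experiments, and the comparison between the strong-uniformity
limit and the hard-tied single model, are evaluated on identifiable labels
and on balanced fixtures respectively; near flat directions, two equally
good optima can differ in parameters while agreeing in loss to 1e−6.

## Problem sizes and numerical choices

The shipped experiments run at desk scale, chosen to exercise every code
path with comfortable statistical margins: 100 random DAGs of at most 8
nodes against the fixed-point oracle (50 starts each, tolerance 1e−9);
noise-free self-consistency on both fixtures (MSE below 1e−6 at the
optimum); 25-seed parameter recovery on the chain at noise SD 0.02, scored
as pooled RMSE on identifiable labels against a 0.05 bound; BIC sparsity
recovery over 25 seeds per $k \in \{0, 1, 2\}$ on two contexts with a
three-cell $\lambda_U$ screen at $\lambda_P = 2^{-10}$; and resampling
monotonicity with 10 rounds per noise scale. Degenerate inputs are handled
explicitly: an exactly zero MSE maps to a $-\infty$ BIC with a warning, a
single-context uniformity penalty is 0 with a warning, a flat blot series
scales to 0.5, and pruning-penalty ties at the maximum take the first
maximizer's subgradient.

## Known limitations

* Cyclic topologies (feedback loops) are out of scope by design.
* The penalty forms are surrogates with the documented qualitative
  behaviour; other choices (e.g. group-lasso pruning, pairwise fusion)
  would select slightly different models.
* Hard ties act on auxiliaries; exact weight equality across contexts at
  nodes mixing tied and free activators is not enforceable on a simplex.
* The BIC's effective parameter count treats a context-specific label as
  $C$ free parameters and ignores the simplex constraint's minus-one degree
  of freedom per node; since every candidate model shares that offset, the
  arg-min is unaffected.
* Optimization is multi-start local descent; on larger networks than the
  fixtures shipped here, more starts may be needed before the best basin is
  found reliably.
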