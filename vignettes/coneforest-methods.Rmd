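---
title: "Cone-regularized Poincaré embedding: model, optimizer and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cone-regularized Poincaré embedding: model, optimizer and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneforest)
```

This vignette is the package's own account of the model it fits, the
optimizer that fits it, the defaults and their units, what the synthetic
generator does and does not emulate, and the design choices made where the
design was genuinely open. Everything quantitative stated here is computed
by the package's tests or by `scripts/acceptance.R`; nothing is quoted
from elsewhere.

## The setting

The input is a heterogeneous graph with two structural families of edges:
directed *hierarchical* edges (parent → child) whose subgraph is a DAG —
typically a forest of several trees in which a child may have parents in
more than one tree (a poly-hierarchy, as in subject-term vocabularies) —
and undirected *non-hierarchical* edges, either between two non-hierarchy
nodes or linking a non-hierarchy node to a hierarchy node (an article
tagged with a term). The goal is a single embedding of all nodes in the
open Poincaré ball whose geometry makes the hierarchy explicit: roots
central, depth increasing radially, each subtree confined to the angular
cone its parent defines, and non-hierarchy nodes placed inside the cones
of the hierarchy nodes they link to.

## Objective

With the Poincaré distance $d(u,v) = \operatorname{arcosh}\!\big(1 +
2\lVert u-v\rVert^2 / ((1-\lVert u\rVert^2)(1-\lVert v\rVert^2))\big)$,
the fitted objective is

$$
\sum_{(u,v) \in E} -\log\frac{e^{-d(u,v)}}{\sum_{v' \in \{v\}\cup N(u)}
e^{-d(u,v')}}
\;+\; \lambda_r \sum_{\text{roots}} \big[d(0,r) - \delta\big]_+
\;+\; \lambda_c \sum_{(p,c)} \big[d(0,p) - d(0,c) + m\big]_+
$$
$$
\;+\; \lambda_{\text{cone}} \sum_{(p,c)} \big[\angle_{pc} -
\psi(p)\big]_+
\;+\; \lambda_{\text{nh}} \sum_{(h,v)} \big[\angle_{hv} -
\psi(h)\big]_+ ,
$$

where $[x]_+ = \max(0, x)$, $\psi(x) = \arcsin\!\big(K(1-\lVert
x\rVert^2)/\lVert x\rVert\big)$ is the half-aperture of the entailment
cone at apex $x$, and $\angle_{xy}$ is the angle at the apex between the
half-line to $y$ and the outward continuation of the half-line from the
origin — so a child directly beyond its parent has angle 0. The aperture
is undefined for $\lVert x\rVert < r_{\min}(K)$ (the root of
$K(1-r^2)/r = 1$); cone terms with such apexes are *gated* (they
contribute zero and exert no force). Angles' and apertures' arc-trig
arguments are clamped to $[-1,1]$ and denominators floored at $10^{-15}$.

All four constraints are *soft*: satisfaction is measured after training
by `structure_report()`, never assumed. The hinge (rather than hard
projection onto the feasible set as a definition of the model) is
deliberate: for a poly-hierarchical child the intersection of its parents'
cones may be empty, so "the" feasible point need not exist.

Every edge — hierarchical or not — enters the base softmax as an
undirected pair; direction is carried entirely by the ordering and cone
terms. The `variant` switch reproduces the standard ablation family by
zeroing weights: `poincare` (all off), `R` (root only), `Ch` (ordering
only), `C` (all hierarchical terms, no non-hierarchical cones), `full`.

## Optimizer

The optimizer is the product of the constraints' geometry; its phases are:

* **Stochastic pass** (per epoch): every undirected edge is visited from
  both endpoints in one shuffled stream. A visit takes a negative-sampling
  step: gradients of the softmax term are rescaled by the inverse metric
  factor $(1-\lVert x\rVert^2)^2/4$ at each touched point, length-clipped
  (`max_step`), and applied; points are projected back to norm $\le
  1-\varepsilon$. Half of the `n_negatives` samples are uniform over
  non-neighbors; half are drawn from the node's current nearest
  non-neighbors (refreshed every 10 epochs). The hard half exists because
  uniform sampling essentially never draws a near-coincident non-neighbor,
  and without that repulsion two siblings confined to the same narrow cone
  collapse onto each other.
* **Constraint projections** (interleaved): after a visit, the edge's own
  structural constraints are *projected*, not descended. Hinge gradients
  have constant magnitude, so a fixed-weight gradient step overshoots
  small violations and oscillates — at moderate radii it can throw a point
  across the ball, where the projection strands it on the boundary and the
  metric factor freezes it there. The ordering projection closes (at most)
  its own violation, split between parent and child; the cone projection
  rotates the member about the origin onto the cone at constant radius (a
  slerp with bisection onto the boundary) and rotates the apex toward the
  member by at most 0.02 rad. The apex cap matters: an apex position
  doubles as its cone's axis with angular leverage $1/\lVert x\rVert$, and
  an uncapped apex move lets shallow apexes whip between spread children
  so the projections cycle instead of converging. A member constrained by
  several cones is projected only onto the *nearest* one: cones of nearly
  orthogonal apexes are often jointly unsatisfiable, and alternating full
  projections onto them makes the member — and, when it is itself a
  parent, its entire subtree — ping-pong between angular pencils.
* **Anchors and trust regions**: roots are projected into the
  $\delta$-ball at each epoch's end (with a small slack so the strict
  inequality holds); cone apexes are kept inside the annulus where their
  apertures are usable (floor marginally above $r_{\min}(K)$, ceilings at
  the radii where $\psi$ falls to 0.15 rad for hierarchical parents and
  0.1 rad for apexes of article-term links); and all radii are bounded by
  an outer trust region (the radius where $\psi$ would fall to 0.05 rad).
  Without the outer bound, softmax repulsion inflates the population onto
  the ball boundary, where the metric factor freezes every point and all
  pairwise distances degenerate; the annulus mirrors the restriction
  customary in entailment-cone training.
* **Schedule**: `burn_in_epochs` at `burn_in_factor × lr`, a constant
  plateau, then a linear cool-down over the final `anneal_frac` of epochs
  to `anneal_floor × lr`. The cone terms activate only after
  `cone_warmup_epochs`: on a still-random configuration they mostly
  chatter against the aperture gate, so the distance loss and the radial
  penalties lay out the skeleton first. During the cool-down,
  `polish_sweeps` deterministic projection sweeps per epoch hold the
  coupled constraints near their boundaries.
* **Settling phase**: after the last epoch, `final_sweeps` deterministic
  sweeps of all structural projections run with the stochastic pass
  frozen (members landing well inside the cone boundary, apex rotation
  damped to 0.002 rad). Because the projections are learning-rate-free,
  they retain full strength here and the coupled constraints crystallize;
  this is plain alternating projection onto the constraint sets.

Training is fully deterministic given the seed (all randomness comes from
R's RNG, including inside the compiled core), and an epoch always ends
with the structural projections applied, so the logged satisfaction rates
describe the state a user receives.

## Defaults

| parameter | default | units / meaning |
|---|---|---|
| `dim` | 10 | embedding dimension; enough angular room for desk-scale forests (larger corpora would use 30–50) |
| `delta` | 0.5 | hyperbolic radius bound for roots |
| `K` | 0.1 | aperture scale; $r_{\min}(K) \approx 0.099$ |
| `margin` | 0.1 | ordering slack in hyperbolic distance; comparable to the per-level radial spacing the apex annulus allows (with the legacy 0.01 the radial ladder collapses into interleaved levels under stochastic noise) |
| `lambda_*` | 1 | penalty weights; for the projection steps a weight $\ge 1$ means full projection, $< 1$ under-relaxation |
| `n_negatives` | 10 | per edge visit; half uniform, half hard |
| `lr` | 0.3 | base learning rate |
| `burn_in_epochs`, `burn_in_factor` | 10, 0.1 | reduced-rate start |
| `anneal_frac`, `anneal_floor` | 1/3, 0.02 | linear cool-down |
| `cone_warmup_epochs` | 50 | skeleton phase before cones activate |
| `polish_sweeps`, `final_sweeps` | 2, 500 | in-cool-down and settling projection sweeps |
| `epochs` | 300 | |
| `init_scale` | 1e-3 | uniform init half-width |
| `eps_ball` | 1e-5 | boundary margin of the ball projection |
| `max_step` | 0.1 | per-update Euclidean length cap |

## The synthetic generator

`make_forest()` emulates the target setting at desk scale: `n_trees`
complete `branching`-ary trees of a given depth; with probability
`poly_prob` a non-root node gains one extra parent from *another* tree at
strictly smaller depth (so the level structure stays jointly satisfiable);
`n_nonhier` article-like V nodes each pick a uniform home tree, link to
1–3 hierarchy nodes sampled from the subtree of one random home-tree node
(locality is what makes the home tree recoverable from the embedding, and
is the planted classification label), and V pairs sharing a home tree link
with probability `vv_prob`. The standard fixture used throughout the tests
is `standard_forest()`: 3 trees × branching 3 × depth 4 (121 hierarchy
nodes per tree), 10% poly-hierarchy, 100 V nodes, 2% V–V density, seed 7.

What the generator does *not* emulate: realistic vocabulary text or sizes,
citation dynamics, degree distributions of real corpora, cross-links
between hierarchy nodes, or labels with any noise. Passing tests therefore
show that the machinery enforces and measures what it claims on graphs
with this structure — not that the method attains any particular score on
a real screening corpus.

## A structural trade-off worth knowing

Tightly satisfied cones and high neighbor-ranking reconstruction are in
tension, and the tension is geometric, not an optimizer artifact. A child
inside its parent's cone is confined to an origin-angle pencil of
half-width roughly $\psi(r_p)\,(r_c - r_p)/r_c$; two siblings satisfying
the same cone are therefore at most about $2\sin\psi$ times the
parent–child distance apart ($\psi \le 0.15$ over eligible apexes at
$K = 0.1$). Siblings consequently rank ahead of the parent in a distance
ranking, which caps the average precision of a single-neighbor leaf near
$1/b$ for branching $b$. A hand-constructed layout with *perfect* root,
ordering and cone satisfaction scores a reconstruction MAP of ~0.43 on the
standard forest — close to what trained full-model fits achieve (~0.3) —
while relaxing the cones lets MAP rise to ~0.9. The package prioritizes
the structural constraints (they are the model's point) and reports the
honest MAP; if ranking reconstruction is the primary goal, use the
`poincare` or `Ch` variants.

A related ceiling effect appears in ablation comparisons: any variant that
includes the ordering term drives the ordering rate to exactly 1.0 (the
constraint is imposed by projection), so two such variants cannot be
strictly ordered on that rate.

## Numerical choices and degenerate inputs

* Strict inequalities (root radius, ordering) are evaluated with zero
  tolerance; ties count as violations. Projections therefore land slightly
  *inside* their boundaries (1% of δ for roots; the margin plays this role
  for ordering; cones use a landing fraction of the aperture).
* A member exactly coincident with its apex has no defined apex angle;
  evaluation counts such pairs as violations, and training never produces
  them (the hard-negative repulsion separates coincident points).
* Graphs with no hierarchical edges are legal: all rates with empty
  denominators are reported as `NA`, and hierarchy-typed isolated nodes
  count as their own roots.
* `epochs = 0` returns the initialization unchanged, which keeps the
  initialization contract testable.
* Duplicate edges are collapsed (in either orientation for undirected
  edges) with a warning; cycles in the hierarchical subgraph are an error
  that names one offending cycle.

## Problem sizes used by the tests

The test-suite and the acceptance script work at the standard-forest scale
(463 nodes, ~560 edges, 300 epochs plus 500 settling sweeps; a second or
two per fit with the compiled core). The ablation comparisons average
three seeds; the classifier evaluation uses 70/30 train–test splits.
Geometry properties are checked on 1000 random pairs or triples.

## Known limitations

* The non-hierarchical cone rate saturates well below 1: an article
  linked to several terms must sit in the intersection of their cones,
  and for terms on different branches the intersection is thin or empty.
  The rate is best read comparatively across variants.
* Poly-hierarchical children commit to their nearest parent cone; the
  cross-tree edge that loses the commitment stays violated unless the two
  parents' axes happen to align.
* Hierarchy nodes that also share non-hierarchical edges are accepted in
  the data model but receive no cone treatment for those edges (they only
  enter the distance loss) — the semantics of such links are left to the
  user.
* Curvature is fixed at −1; there are no exponential/log maps, product
  manifolds, or Lorentz-model conversions.
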