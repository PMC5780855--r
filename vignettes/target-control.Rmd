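---
title: "Objectives-guided target control of directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objectives-guided target control of directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcoa)
```

## The problem

A directed network with linear(ised) dynamics $dx/dt = Ax + Bu$,
$y = Cx$ is *target controllable* for a target set $O$ when the output
controllability matrix $[CB, CAB, \dots, CA^{N-1}B]$ has rank $|O|$ for a
generic choice of the nonzero entries of $A$ (the network's adjacency
support) and $B$ (indicator columns of the *driver nodes*, where
independent input signals attach).  In drug-target work the interesting
question is not just "how few drivers control the disease-associated
targets", but "how many of those drivers can we pick from nodes we already
know how to perturb" — approved drug-target genes, say.  `tcoa()`
scalarises that bi-objective: with constraint set $Q$ the weight of a
driver set $D$ is

$$W = 2\,|D| - |D \cap Q| \;=\; |D| + |D \setminus Q|,$$

so a driver inside $Q$ costs 1 and any other driver costs 2.  Minimising
$W$ minimises the driver count and, among equally small sets, maximises
the overlap with $Q$.  A useful consequence for interpretation: trading
one unconstrained driver for *two* constrained ones is weight-neutral.

## The procedure

`tcoa()` runs three stages.

**1. Iterated matching.**  Level 0 of the *linking and dynamic graph* is
the bipartite graph whose right side is $O$ and whose left side is the
direct predecessors of $O$ (restricting to direct predecessors is
lossless: a distant ancestor contributes no bipartite link and could
never be matched).  A maximum matching is found by randomized Kuhn
augmenting paths; the matched left nodes become the next level's right
side, and so on.  The iteration stops when the left side empties, when a
(right-set, matching) state repeats — which happens in cyclic networks —
or after $N$ levels, so it terminates on every finite input.  Matching
*cardinality* is invariant, but *composition* is not, and that degeneracy
is deliberately exposed through the seed: the set of maximum matchings is
the state space the sampler explores later.

**2. Tree, subspaces, integer program.**  Within each level, matched
pairs chain (if $u$ is matched to $w$ and $w$ is itself matched onward to
$z$, then $u$ also controls $z$), and the chained pairs across all levels
form the *target control tree*.  Breadth-first reachability over the tree
gives each node $v$ its controllable target subspace $TCS(v) \subseteq O$,
with $v \in TCS(v)$ whenever $v$ is itself a target (a direct input on a
node trivially controls it — this is also what makes the covering problem
always feasible).  Dually, $F_u = \{v : u \in TCS(v)\}$ lists the
candidate drivers for each target.  Selecting a $W$-minimal driver set
subject to "every target covered by some member of its family" is a
weighted set cover with costs 1 on $Q$ and 2 elsewhere; `solve_driver_ilp()`
solves it exactly with branch and bound (component decomposition,
candidate/target dominance reduction, a greedy incumbent, and an
admissible lower bound built from family-disjoint targets).  An
exhaustive-enumeration oracle, `brute_force_min_weight()`, verifies the
optimiser in the test suite; they agree on every generated instance.

**3. Metropolis–Hastings over matchings.**  Different maximum matchings
induce different trees, subspaces, and hence different optimal weights.
The sampler treats the matching realisation as the state of a Markov
chain: a proposal picks one matched path (the chain of matched links a
target anchors across levels) uniformly, deletes one link in it,
re-matches that level without the deleted link (rejection if the
cardinality cannot be restored), rebuilds all deeper levels, and re-runs
the integer program.  A proposed weight change $\Delta W$ is accepted with
probability $\min[1, e^{-c\,\Delta W}]$.  The run keeps the best selection
ever seen and stops once the best weight has not improved for `window`
iterations (default 100) or at `max_iter` (default 1000), with $c = 10$ by
default.

**A note on the acceptance sign.**  This family of samplers is sometimes
written with the opposite sign, favouring *high*-weight matchings; that
would contradict the minimisation objective the integer program optimises
and the worked example, where the preferred state is the lower-weight
one.  This implementation is consistently minimising: the stationary
distribution is proportional to $e^{-cW}$, improvements are
always accepted, and a unit worsening at $c = 10$ survives with
probability $e^{-10} \approx 4.5\times10^{-5}$.  With so sharp a penalty
the sampler is close to a randomized descent; `c` is the knob to soften it.

## Verification, and a known gap in the tree construction

The rank condition is implemented numerically in `generic_target_rank()`:
random nonzero weights on the adjacency support (magnitudes in
$[0.5, 1.5]$, random signs), $A$ rescaled to spectral radius below 1 so
that $N-1$ powers neither overflow nor underflow (rank is unaffected),
and the numeric rank of the stacked blocks taken at a relative
singular-value tolerance of $10^{-8}$.  Generic rank is approximated as
the maximum over 3 independent draws; the block build stops early once
rank $|O|$ is reached.  Networks beyond 500 nodes are refused rather than
silently mis-ranked — the dense build is a verification tool, not an
interactome-scale one.

Verification is not decorative.  The tree-reachability construction is an
approximation, and on cyclic networks it can overclaim: a node may be
credited with two targets that are both single-parent children, at equal
delay, of the same junction node, and no input routed through that
junction can steer them independently (if $\dot x_1 = a x_3$ and
$\dot x_5 = b x_3$, then $b x_1 - a x_5$ is invariant).  `tcoa()`
therefore screens, in weight order, the distinct selections the chain
visited and reports the best one that certifies full generic rank; in the
rare case none does, it repairs the best selection by adding direct
inputs on targets (constrained nodes first) until the rank condition
holds.  The `verified` and `repaired` fields of the fit record what
happened.  Screening uses the dense oracle and is skipped above
`verify_cap` (200 nodes by default); on interactome-scale networks the
selection is reported as the sampler produced it, unscreened, and the
same caveat applies to any method built on this family of matching
constructions.

## Baselines

Two reference schemes are included for comparison.  Full-network control
(`liu_full_control()`) takes the unmatched right-side nodes of one
maximum matching of the whole network; its driver count is always
$\max(N - |M|, 1)$ regardless of the matching realised.  Note the count
convention: in the original full-control accounting one input *signal*
may attach to several nodes, so an inaccessible cycle costs nothing; with
one indicator column per driver node — the convention used throughout
this package — such a cycle genuinely needs its own driver.  The
iterated-matching target-control scheme (`gao_target_control()`) collects
unmatched right-side nodes level by level.  Its published description
stops when the right side empties or repeats; a bare repeat-stop would
declare matched-around cycles controlled for free, which fails the rank
condition, so this implementation grants one driver to a repeating right
set and resumes, excluding drivers from later right sides.  Because
unmatched sets vary across maximum matchings, the smallest driver set
over seeded restarts (default 10) is reported.  Neither baseline looks at
$Q$ when selecting drivers, which is exactly what the comparison
fractions expose: $f_1 = |D|/|O|$ (cost) and $f_2 = |D \cap Q|/|D|$
(consistency with prior knowledge).

## Synthetic data and what passing tests mean

All test inputs are generated in code.  The Erdős–Rényi generator draws
exactly $L$ ordered pairs (self-loops allowed) without replacement, so
edge counts are exact; the scale-free generator uses a static fitness
model with requested in/out exponents (default 2.5, typical of biological
interactomes) and recovers the exponent to within about $\pm 0.3$ under a
maximum-likelihood fit.  The six-node worked example is reconstructed
from its documented matchings; one edge (v4→v5) is a reconstruction
chosen so the full-control analysis needs exactly two drivers while every
documented level matching is preserved, and nothing but that full-control
count depends on it.

These generators emulate the *combinatorial* structure of curated
interaction networks — directedness, sparsity, heavy-tailed degrees —
and none of their biology: no edge signs or confidence weights, no
correlation between degree and being a drug target, no curation bias.
Tests passing on this suite certify the algorithmic contracts (matching
maximality, tree/duality identities, ILP optimality, rank certification,
reproducibility), not that any particular protein will be a good drug
target.

Problem sizes in the shipped suites were chosen to make exhaustive
oracles exact and runs quick: random certification instances use up to 12
nodes (where subset enumeration and dense rank checks are trivially
exact), surface comparisons use 25-node networks over a reduced
$3 \times 3$ grid of $(\alpha, \beta)$ fractions with 2 draws per cell,
and the end-to-end ingestion test uses a 300-node scale-free stand-in.
The full $10 \times 10$ grid with 10 repeats per cell remains the default
of `controllability_surface()` for real use.

## Numerical and design choices

* **Termination of the level iteration** is unspecified for cyclic
  inputs in the source description; repeat-state detection plus the
  hard cap at $N$ levels guarantees halting and keeps the level count
  $r$ finite, consistent with the method's $O(r\sqrt{|V|}\,|E|)$ bound.
* **Ties among $W$-optimal sets** are broken deterministically in the
  solver (cost, then coverage, then node order), but all optima the
  chain visits are retained and show up in the capacity table.
* **Integer tolerances** are a non-issue by construction: the solver is
  combinatorial branch and bound, so indicators are exactly 0/1 and no
  LP rounding is involved.
* **Convergence** is monitored on the best-so-far weight (the
  alternative, current weight, can oscillate forever at sharp `c`);
  burn-in defaults to 0 and rejected proposals advance the iteration
  counter, which bounds runtime.
* **Capacity** $f_d(v)$ counts, by default, every retained post-burn-in
  state (including repeats after rejections), because the chain's
  dwell time is what makes the frequency interpretable; restriction to
  best-weight states is available (`optima_only`).
* **Degenerate inputs**: empty target sets are usage errors; targets
  with no predecessors are their own (forced) drivers; duplicate edges
  collapse with a message; identifiers are opaque case-sensitive
  strings, and no gene-ID normalisation is attempted.

## Limitations

The method operates on linearised dynamics around an operating point;
nothing here addresses nonlinear reachability.  The tree construction is
an approximation with the overclaim mode described above, mitigated but
not eliminated by rank screening (screening is off above `verify_cap`).
Betweenness in `topology_stats()` is computed on the directed graph,
unnormalised.  Real case-study networks are supported as inputs
(edge-list plus node-list files) but are not shipped; all packaged
results are computed on generated data.
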