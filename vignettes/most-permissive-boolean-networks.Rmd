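---
title: "Most Permissive semantics for Boolean networks: models, algorithms, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Most Permissive semantics for Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpbnet)
```

## The modeling problem

A Boolean network (BN) over components $1,\dots,n$ is a function
$f : \mathbb{B}^n \to \mathbb{B}^n$; the local function $f_i$ gives the
value toward which component $i$ evolves from a configuration
$x \in \mathbb{B}^n$. The classical execution semantics update either all
components at once (synchronous), exactly one (fully asynchronous), or any
nonempty subset of the unstable ones (generalized asynchronous). All of
them commit to a crucial hidden assumption: a component's activity is
*instantaneously* binary, so a regulator is either fully above or fully
below every interaction threshold at all times.

Real regulatory molecules ramp up and down through intermediate
concentrations, and different targets can respond at different thresholds.
The consequence is well known from the incoherent feed-forward loop of
type 3 (shipped as `fixture_i3ffl()`): an input that inhibits its output
directly but activates it through a relay produces a *transient* pulse of
output activity in quantitative models, yet no synchronous or asynchronous
Boolean execution can ever activate the output. A modeler validating the
(correct) Boolean logic against the observed pulse would wrongly reject
it.

```{r}
relay <- fixture_i3ffl()
relay
reachable_set(relay, "000", "asynchronous")   # output never active
```

## The Most Permissive semantics

The Most Permissive (MP) interpretation removes the hidden assumption
instead of adding parameters. Each component takes one of **four states**:
inactive `0`, active `1`, increasing `+`, decreasing `-`. A component in a
dynamic state (`+`/`-`) is read non-deterministically as 0 *or* 1 by each
of its targets — formally, the admissible interpretations of an MP
configuration $x$ are
$\gamma(x) = \{ z \in \mathbb{B}^n \mid x_i \in \mathbb{B} \Rightarrow z_i = x_i \}$.
The transition rules are local and independent per component:

* `0` or `-` $\to$ `+` whenever some $z \in \gamma(x)$ has $f_i(z) = 1$;
* `1` or `+` $\to$ `-` whenever some $z \in \gamma(x)$ has $f_i(z) = 0$;
* `+` $\to$ `1` and `-` $\to$ `0`, unconditionally.

This is the tightest Boolean abstraction of quantitative refinements: any
behavior of a multivalued (or ODE) model following the same interaction
logic is captured, and nothing weaker than MP has that guarantee. The
package makes that statement *executable* rather than taking it on faith
(see the refinement section below).

```{r}
mp_reach_subcube(relay, "000", "**1")   # the transient pulse is recovered
```

## Deciding reads: the monotone fast path

The transition conditions quantify over $\gamma(x)$, which is exponential
in the number of dynamic regulators. `can_read()` therefore has two
routes:

* **Locally monotonic functions** (no regulator both activates and
  inhibits the same target — the standard assumption for biological
  networks): to read value $v$, substitute every dynamic activator with
  $v$ and every dynamic inhibitor with $1-v$; one evaluation decides the
  question. Polarities are computed exactly from the function's truth
  table up to 16 inputs, or from negation normal form beyond (sound,
  syntactic).
* **Non-monotonic functions**: the dynamic inputs of $f_i$ are enumerated
  exhaustively. This requires the function to have at most 16 inputs; the
  operation errors out loudly beyond that rather than guessing.

## Polynomial reachability and its witness

MP reachability between Boolean configurations always admits a
three-phase shortcut visiting at most $3n$ transitions: first components
leave their Boolean state (`P1`), then dynamic components flip direction
(`P2`), finally everything settles (`P3`). `mp_reach()` implements the
corresponding search:

1. **Saturation** — compute the largest set $M$ of components that can
   enter a dynamic state, growing monotonically (each candidate is tested
   with the current members dynamic and everything else at the start
   configuration; since enlarging the dynamic set only enlarges
   $\gamma$, the closure is order-independent, which the test suite
   asserts explicitly by permuting declaration order).
2. **Feasibility** — every component that must change value has to be in
   $M$; every member of $M$ whose target value equals its start value must
   be able to flip back in the fully saturated context.
3. **Blacklist and restart** — a component that cannot flip back in the
   *maximal* context can never do so; it is barred from becoming dynamic
   and the saturation is recomputed. Because flip-back readability is
   monotone in the dynamic set, all currently failing components can be
   blacklisted at once without losing solutions; the loop restarts at most
   $n$ times.

For subcube targets (`mp_reach_subcube()`), positions free in the target
are exempt from the flip-back requirement. With a minimal trap space as
the target this is exactly the reachable-attractor test.

The prose description of this exploration leaves room for interpretation
(notably how phase-2 flips interact), so the package treats the
brute-force search over the full $4^n$ MP transition graph
(`mp_reachable_boolean_set_oracle()`) as the correctness authority: the
polynomial procedure is validated against it on hundreds of random
locally monotonic networks, over *all* ordered pairs of configurations,
before being trusted at scale.

```{r}
sw <- fixture_switch3()$bn
mp_reach(sw, "000", "111", witness = TRUE)
```

## Attractors are minimal trap spaces

A trap space is a subcube closed under $f$; MP attractors are exactly the
minimal trap spaces. The package again offers an oracle and a scalable
route, cross-validated against each other:

* `method = "exhaustive"` scans all $3^n$ subcube patterns.
* `method = "implicants"` uses the characterization that a pattern is a
  trap space iff each fixed literal $(i,v)$ is supported by a prime
  implicant of $f_i = v$ whose literals are all fixed by the pattern.
  Minimal trap spaces are then the *maximal consistent self-supported
  literal sets*. Prime implicants are computed by Quine–McCluskey merging
  (function arities up to 14 free inputs), and the maximal sets are
  enumerated by branch-and-prune over components carrying both literals.
  No SAT or ASP engine is involved; the enumeration is exact.

Scaling to thousands of components relies on a factorization along the
condensation of the influence graph: processed in topological order, the
restriction of a minimal trap space to the blocks seen so far is itself
minimal, and each strongly connected block can be solved given the
upstream pattern, with upstream fixed values substituted and upstream
free components acting as permanently free inputs (any implicant
mentioning one is unsupportable). This also subsumes constant
percolation: a component whose function becomes constant given upstream
values is forced in every minimal trap space. Randomly generated
scale-free networks with 1000 components decompose into many small blocks
plus, typically, one larger core, and complete in about a second on a
desktop-class CPU; the branching budget (`node_limit`) guards against
pathological inputs with exponentially many trap spaces, which is a
genuine property of such inputs and not an artifact of the method.

```{r}
minimal_trap_spaces(sw)
reachable_attractors(sw, "000")
in_attractor(sw, "000")
```

`fixed_points()` uses the same read machinery inside a backtracking
search with constraint propagation, so it does not require explicit
enumeration either; singleton minimal trap spaces and fixed points agree,
which the tests check on random networks.

## Multivalued refinements and the completeness guarantee

A multivalued network (MN) over levels $0..m$ maps each configuration to
per-component tendencies in $\{-1, 0, +1\}$. The binarization
$\beta(x)$ reads level 0 as Boolean 0, level $m$ as 1, and intermediate
levels as either value — `binarizations("012", m = 2)` returns
`001` and `011`. An MN *refines* a BN when every nonzero tendency is
justified by some binarization: a decrease (increase) of component $i$
requires some $x' \in \beta(x)$ with $f_i(x') = 0$ (respectively $1$).

The central guarantee is that MP executions of the BN capture every
asynchronous trajectory of every refinement, with endpoints translated in
the natural way (extreme levels map to Boolean states, intermediate levels
to a dynamic state consistent with the direction of change).
`completeness_check()` verifies this property exhaustively for a given
refinement at enumerable sizes (the MP side walks the full $4^n$ graph),
and `random_refinement()` samples tendencies uniformly among those the
criterion permits, so the property can be tested over many random
instances — the executable face of the theorem. At sizes up to $n = 4$,
$m = 2$, fifty sampled refinements are checked in the acceptance suite
with no violation.

```{r}
fx <- fixture_switch3()
is_refinement(fx$mn, fx$bn)
mn_reachable_set(fx$mn, "000")[1:8]
```

The `maximal = TRUE` mode of `random_refinement()` with $m = 1$ collapses
to the Boolean asynchronous dynamics exactly, a useful consistency anchor
between the multivalued and Boolean modules.

## Synthetic data: what the generator emulates

`random_scale_free_bn()` emulates the connectivity statistics of curated
regulatory networks: in-degrees follow a truncated power law (default
exponent 2.5, at most 5 regulators — typical of published logical models),
regulators are drawn with Pareto-distributed weights so a few hubs acquire
very high out-degree, each regulator gets a fixed polarity, and local
functions are random AND/OR trees over those literals. Every sample is
locally monotonic by construction, and self-regulation is excluded (as in
standard random Kauffman-style ensembles; it also avoids inflating the
count of trivial single-node feedback attractors). Generation is
deterministic per seed and leaves the caller's RNG state untouched.

What the generator does *not* emulate: correlated motifs (feed-forward
enrichment), canalizing function bias, and the input-layer structure of
signaling networks. Passing the randomized suites therefore demonstrates
algorithmic correctness on heavy-tailed monotone ensembles, not biological
realism of any particular sampled model.

## Numerical and design choices

* **Explicit-state bounds.** Classical semantics routines refuse networks
  above 20 components (they allocate $2^n$ flags); the MP graph oracle is
  bounded at $n = 8$ by default ($4^n$ states). These are oracle tools;
  the scalable path never builds a state space.
* **Problem sizes in the validation suites.** The randomized suites use
  100 networks with $n \le 6$ for all-pairs reachability (about
  $4 \times 10^5$ decided pairs), 100 networks with $n \le 8$ for trap
  spaces, and 50 refinements with $n \le 4$, $m \le 2$ for completeness —
  sizes at which the exhaustive oracles remain exact and the suites
  complete in a few minutes.
* **Encodings.** Configurations print as binary strings in declaration
  order (first component leftmost); MP states use `+`/`-`; trap spaces
  print as `{0,1,*}` patterns. All user-facing functions accept either
  strings or integer vectors.
* **Degenerate inputs.** Fixed points have empty successor sets in every
  semantics, while reachable sets always contain the start; a
  single-component network with negative self-regulation has the full
  cube as its only minimal trap space; binarizing an all-extreme
  configuration yields exactly one Boolean vector.
* **Tie-breaks.** When `random_refinement(maximal = TRUE)` may justify
  both signs at an intermediate level, the increase is preferred; only
  the $m = 1$ case (where the situation cannot arise) carries a formal
  equivalence claim.

## Known limitations

* MP reachability between two arbitrary *four-state* configurations is
  only available through the small-n oracle; the polynomial path covers
  Boolean endpoints and subcube targets, which is what attractor and
  validation workflows need.
* Non-monotonic functions are supported through enumerative reads up to
  16 inputs; beyond that the package refuses rather than approximating.
* Trajectory counting or propensity estimation between attractors is out
  of scope: the semantics answers possibility questions, not probability
  ones.
* No SBML-qual or GINsim import; the `.bnet` dialect is the single
  exchange format.
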