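# mpbnet — Most Permissive semantics for Boolean networks

`mpbnet` analyzes Boolean networks of gene and signalling regulation under
the **Most Permissive (MP)** execution paradigm. It is aimed at logical
modelers who need to know whether a model *can* reproduce an observed
behavior (reachability) and what its long-term phenotypes are
(attractors), without the two classical pitfalls of synchronous and
asynchronous updating: missed behaviors caused by instantaneous binary
switching, and the 2^n state-space explosion.

## The model in brief

A Boolean network is a function *f* : 𝔹ⁿ → 𝔹ⁿ; *f<sub>i</sub>* gives the
value toward which component *i* evolves. Under the MP semantics each
component takes one of four states — inactive `0`, active `1`, increasing
`+`, decreasing `-` — and a component in a dynamic state is read
non-deterministically as 0 or 1 by each target (the interpretation set
γ(x) fixes Boolean components and frees dynamic ones). Three facts make
this interpretation practical:

* **Completeness.** Every asynchronous trajectory of every multivalued
  refinement of *f* (tendencies justified through the binarization β:
  level 0 ↦ 0, level m ↦ 1, intermediate levels free) has an MP
  counterpart. If MP says "impossible", no quantitative model following
  the same logic can do it.
* **Polynomial reachability.** If an MP trajectory exists between two
  Boolean configurations, one exists with at most 3n transitions, in
  three phases (enter dynamic states, flip, settle). For locally
  monotonic networks each step is decided in linear time.
* **Attractors = minimal trap spaces.** A trap space is a subcube closed
  under *f*; MP attractors are exactly the minimal ones, which can be
  enumerated from prime implicants without building any state space.

## Worked example

The three-component switch (mutual inhibition between `x1` and `x2`,
output `x3` activated by `x2` and inhibited by `x1`):

```r
library(mpbnet)
bn <- parse_bnet("targets, factors
x1, !x2
x2, !x1
x3, x2 & !x1")

reachable_set(bn, "000", "general")
#> [1] "000" "010" "011" "100" "110"
```

The all-active configuration `111` is not in the classical closure, but a
quantitative refinement of the same logic can reach it — and MP
reachability recovers that, with a phase-annotated witness:

```r
mp_reach(bn, "000", "111", witness = TRUE)
#> Most Permissive trajectory (6 transitions)
#>   000
#>   +00  [P1]
#>   ++0  [P1]
#>   +++  [P1]
#>   1++  [P3]
#>   11+  [P3]
#>   111  [P3]
```

`111` is transient: it lies in no attractor, and both fixed points remain
reachable from `000`:

```r
minimal_trap_spaces(bn)
#> [1] "011" "100"
reachable_attractors(bn, "000")
#> [1] "011" "100"
in_attractor(bn, "111")
#> [1] FALSE
```

The same workflow scales far beyond explicit state spaces — a sampled
scale-free network with 1000 components:

```r
big <- random_scale_free_bn(1000, seed = 7)
reachable_attractors(big, strrep("0", 1000))  # completes in ~1 s
```

Multivalued refinements close the loop on the theory side:

```r
fx <- fixture_switch3()
is_refinement(fx$mn, fx$bn)        # TRUE
binarizations("012", m = 2)
#> [1] "001" "011"
completeness_check(fx$mn, fx$bn)   # TRUE
```

## Command line

A thin wrapper is installed at `inst/cli/mpbnet`:

```sh
Rscript inst/cli/mpbnet attractors model.bnet
Rscript inst/cli/mpbnet reach model.bnet 000 111 --mode mp
Rscript inst/cli/mpbnet generate --n 1000 --seed 7 --out model.bnet
```

Exit codes: 0 success, 1 property violation, 2 usage/input error.

## Documentation

The methods vignette
(`vignettes/most-permissive-boolean-networks.Rmd`) describes the
semantics, the algorithms (saturation/blacklist reachability, prime
implicant trap-space enumeration with SCC factorization), the generator's
assumptions and the package's design decisions in detail.
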