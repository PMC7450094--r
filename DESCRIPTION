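Package: mpbnet
Title: Most Permissive Semantics for Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Boolean networks of gene and signalling regulation
    under the Most Permissive execution paradigm, in which each component
    takes one of four states (inactive, increasing, decreasing, active) and
    dynamic states are read non-deterministically as 0 or 1 by their targets.
    Provides a BoolNet-style '.bnet' parser, the classical synchronous,
    fully asynchronous and generalized asynchronous semantics as explicit
    state-space oracles, polynomial-time Most Permissive reachability with
    bounded-length witnesses for locally monotonic networks, attractor
    computation as minimal trap spaces (exhaustive and prime-implicant based
    enumeration), multivalued refinements with a binarization-based
    refinement criterion and an enumerative completeness checker, random
    scale-free network generators for property-based validation, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
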