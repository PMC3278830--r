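---
title: "Network-based functional enrichment: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based functional enrichment: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NetFEA)
```

## The model

Set-based enrichment asks how surprising the *count* of interesting genes
annotated with a function is; NetFEA asks how surprising their
*connectivity* is. The universal network `G = (U, I)` is a simple
undirected graph over the gene universe (direction, multiplicity and
self-interactions in the input are normalized away — biologically, an
interaction either links two distinct genes or it tells us nothing about
between-gene wiring). The interesting network `H = (C, J)` has
`C ⊆ U` and `J ⊆ I`; it need not be the induced subgraph, because a
response network typically keeps only the edges its construction
supported. For a function `f` annotating genes `U_f`, the object under
test is `H_f`, the subgraph of `H` induced by `U_f ∩ C`, summarized by
`cs(H_f)`: its component sizes in non-increasing order.

`cs` sequences are compared by zero-padding the shorter to the length of
the longer and deciding at the first index where they differ; the
sequence holding the smaller value there is the smaller sequence. This is
a total order whose minimum, for a fixed node count, is the all-singleton
partition, and under which merging two components always increases the
statistic — the properties that make "more connected" well defined. Its
null distribution has no known closed form, so both tests are permutation
tests:

* **Function randomization** holds the network fixed and asks whether a
  *random gene set of the same size* would be as connected: the p-value is
  the fraction of uniform draws `X` of `u_f` genes from `U` with
  `cs(H_X) ≥ cs(H_f)`. On edgeless networks every `cs` is a run of 1s and
  the comparison collapses to counting overlap, so the test reduces
  exactly to the one-sided Fisher's exact test — the package's tests
  verify this convergence against `phyper`.
* **Structure randomization** holds the gene set fixed and asks whether
  the genes would be as connected in a *random network of the same degree
  sequence*: each iteration rewires `G` by `floor(k·|I|)` double-edge-swap
  attempts and compares the subgraph induced in the rewired network by
  `C ∩ U_f` against the observed `cs(H_f)`.

The two nulls answer different questions (a hub-heavy term can survive
one and not the other), so a function is reported by the maximum of the
two p-values: only functions that both nulls call coherent score well.

### An asymmetry worth knowing about

The observed statistic is computed on `H`, which may lack some universal
edges among `C`; the structure null, however, induces its subgraphs
directly in the rewired `G'`. When `H` is sparser than the induced
subgraph of `G` on `C`, the null is conservative for `H`-based
observations. This mirrors how the interesting network is defined in the
first place and is intentional; callers who want the induced behaviour
can simply pass `inducedSubgraph(G, C)` as `H`.

## Parameters

* `iterations` (default 100,000 in the file-based runners): Monte-Carlo
  samples per null. Empirical p-values lie on the grid
  `{0, 1/n, 2/n, …, 1}`, so the smallest nonzero value at the default is
  1e-5; a reported 0 means "below 1/iterations" and is kept as 0 rather
  than floored, except inside merge scores (below). The in-memory
  `enrich()` defaults to 1,000 for interactive use.
* `k` (default 10): swap-attempt multiplier of the structure null.
  Attempts, not accepted swaps, are counted — `floor(k·|I|)` attempts give
  a bounded runtime, and rejected attempts (self-loop or duplicate
  proposals) are a property of the degree sequence the null is supposed
  to preserve.
* `minUniversal` (default 5) and `maxInteresting` (default 100): a term
  must annotate at least 5 genes *present in the universal node set* and
  at most 100 genes in the interesting node set; both bounds inclusive.
  Counts are taken against node sets because the nulls sample from them;
  annotations to genes outside the universe are retained in the
  `AnnotationSet` but never counted toward `u_f`.
* `weightThreshold` (optional): for confidence-scored edge lists (e.g.
  0–1000 combined scores), edges with weight strictly below the threshold
  are dropped at read time.
* `floor` in `mergeScore()` (default `1/iterations`): a zero p-value
  would make the log-ratio infinite, so zeros are replaced by the grid
  resolution — the only place any flooring happens. The score
  `s(f) = log10(p_without/p_with)` is positive when the added edges
  improved coherence.

## Determinism and random-number plumbing

Each term's function-randomization stream is seeded from the run seed and
the term identifier, so per-term p-values are reproducible regardless of
the order in which terms are processed. The structure null draws one
shared sequence of rewired networks per run and evaluates every term
against it; this matches the per-iteration formulation, cuts the cost of
the expensive null by a factor of the number of terms, and keeps the
rewiring stream independent of the term list. (The alternative —
per-term rewiring substreams — would introduce independent noise between
terms at considerable cost; sharing the pool only introduces positive
correlation between per-term p-values, which the maximum combination
tolerates.) Both loops run in compiled code and draw from R's RNG, so a
single `seed` argument reproduces every number, and identical
configurations produce byte-identical output files.

## Ontology handling

True-path propagation makes annotation upward-closed: a gene annotated to
a term is annotated to all DAG ancestors. Propagation processes children
before parents over the acyclic child→parent graph, is idempotent, and
only grows gene sets; a cyclic input is rejected with one offending cycle
named. The OBO convenience reader extracts `is_a` edges only by default:
which relations the rule should traverse is a modelling choice, `is_a` is
the uncontroversial core, and `part_of` can be opted in
(`readOboDag(..., includePartOf = TRUE)`).

## The synthetic generators

`fixtureNetwork()` produces complete graphs, paths, disjoint cliques,
Erdős–Rényi graphs and preferential-attachment graphs; the last family
exists because real interactomes have heavy-tailed degree distributions
and the swap null's selling point is preserving them, so tests should
exercise hubs. `generateFixture()` plants terms that are connected (a
randomly grown connected induced subgraph — feasible only inside a
component at least as large as the term, otherwise an error) or
fragmented (a random independent set, so the induced subgraph is all
singletons). The generators emulate the *combinatorial* situations the
statistics must distinguish — coherent versus scattered gene sets at
matched sizes, hubs, multiple components. They do not emulate the
modular, locally dense, annotation-correlated structure of real
interactomes, nor annotation bias toward well-studied genes; passing
tests therefore demonstrate the statistics' correctness and
discrimination, not organism-scale biological performance.

Default study conditions used across the test suite and the acceptance
script: 40-node Erdős–Rényi universes at edge probability 0.1 with
planted 6-gene terms (1,000 iterations, 20 fixture seeds) for
discrimination; a 10-node edgeless universe with a 5-node interesting
half (100,000 iterations) for the Fisher-equivalence check; 12-node or
smaller fixtures with terms of at most 4 genes, where every draw can be
enumerated, for the exhaustive cross-check (10,000 iterations). These
sizes keep every exact enumeration feasible while giving the Monte-Carlo
estimates standard errors far below the effects being detected.

## Numerical and degenerate-input choices

* Ties count: draws with `cs` exactly equal to the observed sequence are
  included in the p-value (the "≥" in the definition), so the observed
  configuration itself always has positive null mass and the function
  null can only return 0 when not even one draw tied in `n` iterations.
* An empty `H_f` (no annotated gene in the interesting collection)
  compares equal to every empty sequence and `≥` nothing else, giving
  p = 1 from both nulls; an all-singleton `H_f` is the order minimum and
  likewise forces p = 1. "No interactions among the genes" can never be
  significant, by construction.
* Edge swaps pick two distinct edges uniformly and one of the two
  endpoint pairings uniformly; a rejected proposal leaves the graph
  unchanged. Networks with fewer than two edges are returned as-is.
* `compareCS` validates its inputs (positive, non-increasing) and
  returns a three-way answer so both strict and tie-inclusive tests can
  be expressed without recomputation.
* Boundary conventions: weight filtering drops *strictly below* the
  threshold; term filters are inclusive at both ends.
* Benjamini–Hochberg adjusted values are emitted as a convenience column
  and never used for filtering, since the empirical p-values of
  overlapping GO terms are strongly dependent and the maximum-combination
  already makes the per-term values conservative.

## Limitations

* Runtime is dominated by the structure null (`iterations × k|I|` swap
  attempts); organism-scale networks at 100,000 iterations are a batch
  job, not an interactive one.
* The test is one-sided for coherence; it cannot flag functions that are
  *less* connected than expected.
* Edge weights are used only as a read-time filter; a weighted `cs`
  (component sums of edge weights) would slot into the same comparison
  framework but is not implemented.
* Identifier mapping is out of scope: annotations and networks must
  already share a namespace, and identifiers are matched case-sensitively.
* Functions are tested one at a time; overlapping terms yield redundant
  hits, and no joint or model-based selection is attempted.

## A minimal session

```{r example, eval = FALSE}
fx <- generateFixture("erdos-renyi", n = 40, param = 0.1,
    plantedTerms = list(
        list(id = "coherent", size = 6, mode = "connected"),
        list(id = "scattered", size = 6, mode = "fragmented")),
    nRandomTerms = 3, seed = 7)
res <- enrich(fx$network, fx$network, fx$annotations,
              iterations = 10000, seed = 42)
res[, c("term", "cs", "p_function", "p_structure", "p_combined")]
```

The planted coherent term spans one component and earns a small combined
p-value; the scattered term of identical size sits at the order minimum
and is reported with p = 1 by both nulls.
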