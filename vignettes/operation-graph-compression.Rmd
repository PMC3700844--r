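---
title: "Operation-graph genotype compression in forward-time simulation"
author: "ogsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operation-graph genotype compression in forward-time simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogsim)
```

## The problem

A forward-time population-genetic simulator carries every genotype of the
evolving population through every generation.  With genome-scale genotypes
(megabases of sequence, or whole regulatory networks) the genotype heap
dominates memory and eventually crashes the run; with naive compression,
run time explodes instead, because genotypes are read and modified
thousands of times per generation.  ogsim bounds the genotype heap by a
user-chosen number of explicitly stored genotypes while keeping
per-generation run time near-constant, and does so *losslessly*: the
simulated populations are byte-identical to an uncompressed run with the
same seed.

## The operation graph

Every evolutionary event that occurs in a run — point mutation, insertion,
deletion, crossover, or binding-site gain/loss — is recorded as a node of a
rooted, labeled, weighted DAG, the *operation graph*
`OG = (V, E, l, f, w, c)`:

* `f(v)` is the operation (with its parameters: position, new base,
  inserted string, breakpoint, gene pair) and `c(v) >= 0` its application
  cost;
* `l(v)` is the genotype label: the stored genotype, or nil when the node
  is *compressed*; nodes with `l(v) != nil` form the cached set `C(V)`,
  which is never empty;
* `w(v)` counts the individuals currently carrying the genotype; nodes
  with `w(v) > 0` are *active*;
* mutation-derived nodes have one incoming edge, recombination-derived
  nodes two (the first recorded parent donates the prefix).

Any node's genotype can be reconstructed by walking up to its lowest
explicit ancestors `Anc(x)` and re-applying the operations on the way down
(`og_decompress()`); a single base can be read by mapping its coordinate
up the same path without materialising anything (`og_partial_decompress()`,
used heavily during event generation).  The graph is maintained
incrementally: each event adds one node, and when a genotype is lost from
the population its branch is deleted up to the nearest node that is
active, carries another surviving branch (out-degree two), or is the root
(`og_prune_lost()`).

Two measures drive the cache decisions.  The decompression cost
`cost(x)` sums `c(v)` over all nodes on paths from `Anc(x)` to `x`, and
the *load*,

```
load(x) = sum over y in U(x) of w(y) * cost(y, x),
```

weighs each dependent node `y` (in `U(x)`, the nodes requiring `x` for
their decompression) by its frequency.  Endpoint conventions are fixed as
follows: `cost(x, y)` includes `x`'s own cost and excludes `y`'s, so
`cost(x) = 0` for explicit `x`; `U(x)` includes `x` itself when `x` is
compressed and active, contributing `w(x) * c(x)`.  These conventions make
the worked example below come out exactly as published and are asserted by
the test suite against independent path-enumeration oracles.

## Cache policies

`store_active` keeps every active genotype explicit (what conventional
simulators do: no compression, fastest access).  `store_root` keeps only
the root (maximum compression: memory is all in operation records, but
decompression cost grows with simulation time).  Between the two sits
**Greedy-Load** (`greedy_load_update()`), applied every `t` generations
with a cache budget `k`:

1. every cached node that no longer serves any active genotype is
   compressed (keeping at least one cached node); every other cached node
   is *advanced*: its explicitness moves down the loaded part of the graph
   to the highest node that is a leaf, is active, or is a fork with two
   loaded uncached children;
2. while `|C(V)| < k` and addable nodes remain, the max-load child of the
   max-load cached node is decompressed, and both ends are advanced again.

After every application `|C(V)| <= k`.  Because exact load is exponential
to maintain under recombination, simulations use a cheap proxy: each node
counts the *data requests* that reach it (demands for its genotype by
mutation, recombination, or fitness evaluation, propagated up through
compressed nodes to the explicit frontier, one per batch session).
High-frequency genotypes attract proportionally more requests, so request
counts track load.  A node can carry load yet have no recent requests, so
the "non-zero load" tests use a boolean *required* flag (is the node on
some active genotype's decompression path), recomputed in time linear in
the number of such nodes.  The exact-load mode remains available
(`exact_load = TRUE`) and is what the worked-example trace and the oracle
tests run under.

One point deserves emphasis because it is easy to get wrong: the descent
inside `advance()` must be restricted to *required* nodes.  If it may step
into an unloaded branch, a dead zero-weight leaf can capture the advance
(it satisfies the "is a leaf" stopping rule) and the explicit frontier
abandons the loaded paths — our property tests caught exactly this, as a
root compressed while an active genotype still needed it.

Counter maintenance in proxy mode: a node compressed in phase 1 has its
counter reset to zero; a node decompressed in phase 2 has its counter
subtracted (floored at zero) from its former explicit ancestors'.  The
decrement rule is deliberately isolated in one helper so it can be swapped;
only the ranking it induces matters.

### The worked example

`build_example_og()` constructs the twelve-node, twelve-edge example graph
(root `a`; recombination node `d`; active nodes `e, h, i, j, k, l` at unit
weight; unit costs; `C(V) = {a, c}`), and `trace_example()` replays one
exact-load Greedy-Load application with `k = 4`:

```{r trace}
trace_example(k = 4)
```

With unit weights and costs the load order works out to
`load(c) = 6 > load(d) = 5` and `load(f) = 3 > load(e) = 1`, which is what
makes the third panel decompress `f` (advancing to `i`) and `e`.  The
fixture's genotype payloads and weights are not dictated by the topology;
unit values are the simplest choice that realises every inequality the
trace requires, and the suite asserts them.

## The simulator

`run_simulation()` drives a strictly neutral Wright-Fisher loop
(non-overlapping generations, multinomial parent sampling) or a Moran loop
(one birth-death replacement per step; `N` steps are reported as one
generation).  Per offspring: with probability `1 - exp(-c_rate * L)` a
uniformly drawn second parent and a single uniform breakpoint produce a
crossover node; insertions, deletions, and point mutations follow, with
Poisson counts (mean rate times current length), uniform positions,
geometric indel lengths (mean `indel_mean`, default 3 — no canonical length
model exists, so this is a documented package choice), and uniform
non-identical replacement bases.  Deletions are clipped at the sequence
end and a deletion that would empty a sequence is resampled: the machinery
never meets an empty genotype.  When parent lengths differ (possible after
indels) the breakpoint is uniform on `[1, min(lengths) - 1]`, and
crossover is skipped entirely when `min(lengths) < 2`.

Two implementation details matter for speed and for the request counters.
*Batch decompression* (`batch_decompress()`): one read session per event,
so an event touching several bases decompresses (and counts) once.
*Partial decompression*: reading the pre-mutation base walks coordinates
up the graph instead of materialising the sequence; a crossover is
followed only into the parent owning the coordinate.  Fitness evaluation
is neutral here, but the genotype *read* a fitness function would perform
is still stubbed in (`fitness_requests = TRUE`, one frequency-weighted
request per active node per generation) so that request-count dynamics
match what a selective simulation would generate.

The RNG draw order is fixed and documented (parents; crossover; indels;
point mutations; reads never draw), and no cache policy consumes
randomness.  Two runs with the same seed therefore share the entire event
stream whatever the policy — this is what turns "the compression is
lossless" into a testable statement: `store_active`, `store_root`, and
`greedy_load` produce byte-identical populations every generation, and the
suite asserts it over a sweep of seeded configurations with and without
recombination and indels.

A mutation-only Wright-Fisher configuration takes a vectorised fast path
(population-wide Poisson counts per generation); it consumes differently
ordered but identically distributed draws, and the cross-policy identity
is unaffected because the path is selected by the configuration, not the
policy.

### Rescaling and burn-in

`rescale_parameters()` implements the standard trade: a run at
`(N, u, c, G)` with factor `lambda` stands for a system `lambda` times
larger and longer with rates `lambda` times smaller; `N*u` and `N*c` are
preserved.  Metrics are recorded after a burn-in (default `10 * N`
generations, the conventional coalescent equilibration; the choice is a
package default, not a law).

### Verification statistics

For an indel-free sequence sample, `verify_stats()` reports segregating
sites `S`, Watterson's `theta_W = S / a_n`, mean pairwise difference `pi`,
and the implied mutation rate.  The reproduction models here are
*haploid*: `N` genotypes, pairwise coalescence at rate `1/N`, hence the
coalescent expectation `E[theta_W] = 2*N*u*L` and
`estimated_u = theta_W / (2 * effective_N * L)`.  (The textbook `4*N*u`
presumes `N` diploid individuals; with one genotype per individual the
correct factor is 2.  The acceptance suite tests recovery against `2*N*u`
for this reason.)  `rmin` is the Hudson-Kaplan four-gamete lower bound on
recombination events in the sample history; the derived `estimated_c`
normalises it like Watterson's estimator and should be read as a
conservative, qualitative index — near zero without recombination,
positive with it — not an unbiased rate estimate.

## Memory accounting

Reported memory uses a deterministic byte model rather than process RSS,
so numbers are hardware- and GC-independent: one byte per base,
`genes^2` bytes per pathway, and per-operation payloads of 1 byte for a
point mutation, the inserted length for an insertion, and 2 bytes for
deletion, crossover, and binding-site records.  Under this model a million
point-mutation records weigh exactly one megabase genotype, which is the
sense in which operation storage is "inconsequential" next to explicit
genotypes; at desk scales the operation share is larger (the suite reports
a few percent) simply because the genotypes are tiny.  The compression
ratio is `|C(V)|/N` and the space savings `1 - |C(V)|/N`;
`memory_ceiling_k()` converts a memory ceiling in MB into the budget
`k = floor(ceiling / MB-per-genotype)`.

## Problem sizes used by the test suite

All empirical claims in the package are established by the suite itself at
desk scale, chosen once for statistical validity rather than tuned:

* **losslessness**: ten seeded configurations, `N` 30-100, `L` 300-2000,
  200 generations, with and without recombination and indels, three
  policies each, compared generation by generation;
* **theta recovery**: twenty replicates of `N = 100`, `L = 1000`,
  `u = 1e-4` (so `2Nu = 0.02` per site), `10N` generations, samples of 25
  sequences; the replicate mean must sit within three standard errors of
  `0.02`;
* **time-scaling shape**: `N = 60`, `L = 2e4`, `u = 5e-5`, 300
  generations; Greedy-Load's fitted time drift over the run must stay
  below 25% of its mean seconds/generation (a timer-noise allowance),
  while Store-Root's must exceed 50% growth — in practice it multiplies
  several-fold.  Absolute wall-clock values are hardware-dependent and are
  never asserted.

These runs demonstrate the algorithmic properties (losslessness, bounded
cache, constant-time shape, correct diversity), not production scale: the
regimes the method is actually for — tens of megabases, thousands of
individuals, `k/N` around 0.05 — are far beyond a test budget, and
nothing in the suite should be read as evidence about wall-clock
performance there.  What does carry over is every exact invariant
(losslessness, the budget, the byte model), since none of them depends on
scale.

## Known limitations

* Strictly neutral reproduction; a fitness callback is the natural
  extension point (the data-request plumbing for it already exists).
* No demography, migration, linkage maps, or multi-breakpoint crossover;
  indel lengths are geometric by choice, not by biology.
* Exact load is exponential under recombination and is only meant for
  small graphs and tests; production runs use the request-count proxy,
  which is approximate by design (the suite reports its top-1 agreement
  with exact load, typically around 0.95 on scripted patterns).
* The operation graph lives in memory for the duration of a run; there is
  no cross-run persistence.
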