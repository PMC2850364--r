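---
title: "Path-feature indexing and locality-guided subgraph search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-feature indexing and locality-guided subgraph search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PathQuery)
```

## The problem

Substructure search — find every graph in a collection that contains a
query graph, or every embedding of a motif in one large network — underlies
chemical screening (atoms as labeled vertices, bonds as edges), motif
search in transcription networks whose genes are labeled with discretized
expression levels, and complex matching in protein–protein interaction
networks. Subgraph isomorphism is NP-complete, so scanning a database with
a matcher is infeasible; practical systems *filter* with an index first and
*verify* only the surviving candidates.

Classical feature-based filters ask only whether (or how often) each query
feature occurs anywhere in a target. On large graphs this degrades: almost
every small feature occurs somewhere in a big graph just by chance. The
idea implemented here is to keep, per feature, *where it starts* — cheap
locality information that both sharpens filtering and prunes the matcher
itself.

## Model and assumptions

Graphs are undirected, with one opaque label per vertex; edges carry no
labels. A *path feature* is the label sequence spelled by a simple path
(all vertices distinct), with length counted in **vertices** and bounded by
`lp`. Single-vertex paths are included: they encode label counts, and they
guarantee every query vertex contributes at least one feature. An
*occurrence* is a directed traversal — an undirected path is counted once
from each endpoint. The convention is applied identically to database
graphs and queries, so query counts remain valid lower bounds for any
graph the query embeds into (graph upward monotonicity of the
(path, count) feature family), which is exactly what the pruning rule
needs. Occurrence counts are deliberately *not* monotone under feature
extension — a branch vertex can give `A B C` two occurrences while `A B`
has one — and the filter never assumes they are.

Subgraph semantics are **non-induced** (monomorphism): the query's edges
must be preserved, its non-edges impose no constraint. This matches the
definition of subgraph isomorphism as isomorphism onto *a subgraph* of the
target, and is the semantics the brute-force oracle implements as well.
Matches are distinct vertex mappings, so automorphic images of one
embedding are enumerated separately in `all` mode.

## Parameters that matter

* `lp` — maximum path length in vertices; default **4**, sensible up to
  about 10. Larger `lp` grows the feature universe (at most
  `Σ |alphabet|^k`) and the index roughly geometrically while improving
  selectivity; `lp` is stored in the index and enforced at load/query time
  because FQ/FVQ extracted at a different depth would be incomparable.
* `mode` — `first` reports each matching graph once (containment queries);
  `all` enumerates embeddings, optionally capped by `maxMatches` (motif
  counting workloads routinely cap at, say, 100 matches per graph).
* Generator parameters are the benchmark conditions they emulate, see
  below.

## Query feature extraction

Database graphs index *every* path occurrence. Queries record only
**maximal** occurrences: a depth-first occurrence is kept iff it is
terminal — it reached depth `lp` or a dead end. Maximality is
occurrence-level, not feature-level: a feature may be recorded and also be
a prefix of another recorded feature via a different branch. This sits
between the set of maximal features and the set of all features, which is
a sound choice because terminal-occurrence counts are still lower bounds,
and prefix-closure of start sets (`start(f·x, g) ⊆ start(f, g)`) makes the
per-vertex intersections lossless: intersecting over maximal features only
can never be weaker than intersecting over all their prefixes too.

## Filtering and verification

Step one intersects, over the query features, the graphs whose stored
occurrence count reaches the query's bound. Step two computes, for each
survivor `g` and query vertex `v`, `M[g][v]` as the bitwise AND of the
start bitsets of the features starting at `v`, discarding `g` if any
`M[g][v]` is empty. The surviving `M` constrains the matcher: a
backtracking search in the VF2 family whose per-vertex candidate list is
`M[g][v]` instead of all equally-labeled vertices. Since every true
embedding maps `v` into `M[g][v]`, the restriction is conservative — the
match set is provably identical to label-only matching, only the explored
search tree shrinks. The matcher counts its explored states (feasible
assignments), which is the observable the hub experiments rely on.

Degenerate inputs: an empty FQ (zero-vertex query) keeps all graphs and
yields one empty embedding per graph; disconnected queries are rejected
with an explicit error rather than silently mis-handled (per-component
matching with a product assembly is out of scope for this version);
features of FVQ absent from a graph's local index short-circuit the
intersection to the empty set.

## Numerical and ordering choices

Depth-first enumeration visits neighbors in ascending vertex index; this
affects no count or set, only traversal order. The matcher's default
vertex order is dynamic — among unmatched query vertices adjacent to the
partial match, the one with fewest unused candidates, ties by lowest
index; target candidates ascend — making enumeration order deterministic.
For state-count *comparisons* between two compatibility maps the package
uses an explicit static order (`staticMatchOrder()`, breadth-first from the
vertex with fewest candidates) for both runs: with the order fixed, a
pointwise-smaller candidate map explores a subset of the larger map's
states, so the comparison is a guaranteed containment rather than a
heuristic tendency. No search ordering is prescribed by the method itself,
so state counts (never match sets) may differ across implementations.

Features are stored and serialized in C-locale lexicographic order, graphs
in database order, so a database and `lp` determine the index file
byte-for-byte. Bitsets pack bit `v` into byte `v >> 3`, position `v & 7`
(the `packBits()` layout); serialization base64-encodes those bytes inside
a gzip-compressed JSON envelope with a format tag, a version, and a simple
integrity checksum (feature count plus total occurrence count) verified on
load. There is no in-place index update; rebuild on database change.

## Synthetic data: what it emulates, what it does not

* `genScaleFree()` grows a preferential-attachment network: each new
  vertex attaches to an existing one with probability proportional to
  degree (plus-one smoothing so the process can start), then extra edges
  are added with both endpoints degree-proportional until the target edge
  count. Defaults (2000 vertices, 4000 edges, 8 uniform labels) are the
  single-large-graph benchmark conditions. The construction guarantees
  connectivity and a heavy-tailed degree sequence; no particular power-law
  exponent is targeted.
* `sampleQueryBFS()` draws a connected query of exactly `t` edges by
  growing a random breadth-first edge frontier from a random start vertex
  (up to 50 restarts on dead ends); sampled queries are subgraphs by
  construction, so they must be found — the self-containment check.
  Benchmark workloads use `t` ∈ {4, 8, 16}.
* `genMoleculeDB()` emulates databases of small sparse connected
  compounds: a random spanning tree plus ~25% extra edges per graph,
  labels from a geometric-decay distribution (`labelSkew = 0.6` mimics one
  dominant, carbon-like label). `sizeRange` is the vertex-count range; the
  default 8–20 keeps the brute-force oracle exact and fast.
* `hubQueryFixture()` builds the pathological case for backtracking
  matchers: a 13-vertex, 16-edge query whose central hub has degree 12,
  and a target with a similar hub that cannot host the query (one leaf
  label is undersupplied), so the true match count is zero while a
  label-only matcher must still explore the hub neighborhood.

These generators reproduce the *structural* conditions of the benchmarks —
they do not reproduce real atom-type chemistry, expression discretization,
or BLAST-derived cluster labels. Tests passing on them demonstrate
correctness of the algorithms and the claimed containments; they are not
evidence about wall-clock performance on any particular real dataset.

## Testing strategy and problem sizes

All correctness claims are anchored to `bruteForceMatches()`, an
exhaustive enumerator over injective label-preserving assignments that
shares no code with the index or matcher, and to an equally independent
brute-force path enumerator in the test helpers. The suite checks exact
match-set equality on 200 random query/target pairs (targets ≤ 12
vertices, queries ≤ 6, `lp` ∈ {2, 3, 4}), zero filtering false negatives
on a 100-graph molecule-like database against 100 sampled queries with the
embedded-map and state-count containments verified on every true match,
the branch-versus-chain locality scenario, hub-workload conservativeness,
self-containment of 30 sampled queries on the 2000-vertex network, and
bit-exact index round-trips on 50 random graphs. These sizes keep the
oracle exact while exercising every code path; `scripts/acceptance.R`
recomputes the same quantities end-to-end from a single seed.

## Known limitations

Directed or edge-labeled graphs are not supported (the model extends, the
code does not). Disconnected queries are rejected. Multi-edges must be
collapsed by whoever produces the transaction file. The global index
stores counts for every containing graph (no support threshold, no
discriminative-feature mining, no secondary-storage paging). Filtering
power degrades gracefully but measurably when the label alphabet is tiny
or one label dominates — the locality step then does most of the work, and
the matcher's candidate lists grow.
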