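# PathQuery

Filter-and-verify subgraph isomorphism search for databases of node-labeled
undirected graphs — chemical compound collections, transcription-regulation
networks labeled with discretized expression levels, protein–protein
interaction networks — and for single large graphs. Given a query graph *q*,
it reports every database graph *g* with *q* ≾ *g* (an injective,
label-preserving map of query vertices carrying every query edge onto a
target edge), either once per graph (`first` mode) or as the exhaustive list
of distinct embeddings (`all` mode).

## Method

The index unit is the **path feature**: the label sequence
(*a₁*, …, *a_k*) spelled by a simple path of at most *l_p* vertices
(default *l_p* = 4). An **occurrence** is a distinct directed simple vertex
sequence spelling the feature; *start(f, g)* is the set of vertices an
occurrence of *f* starts from. Preprocessing enumerates all such paths
depth-first and builds

* **GI** — a global inverted index, `GI[f][g]` = number of occurrences of
  *f* in *g*;
* **LI** — a local index, `LI[g][f]` = *start(f, g)* packed as a bit array
  of |V(g)| bits.

A query is answered in three steps:

1. **Occurrence-count pruning.** From the query's maximal depth-first path
   occurrences, FQ maps each feature to a lower bound on its occurrence
   count; the candidates are
   `C1 = ∩_{f ∈ FQ} { g ∈ GI[f] : GI[f][g] ≥ FQ[f] }`.
2. **Locality pruning.** FVQ maps each query vertex *v* to the features
   starting there. For each *g* in C1 the compatibility map
   `M[g][v] = ∩_{f ∈ FVQ[v]} start(f, g)` is computed by bitwise AND of LI
   rows; if some `M[g][v]` is empty, no embedding can place *v*, and *g* is
   discarded (set C2). Counting alone cannot make this distinction — two
   features may each occur in *g* yet never start from a common vertex.
3. **Verification.** A VF2-style backtracking matcher enumerates embeddings
   of *q* in each surviving *g*, with the per-vertex semantic test replaced
   by membership in `M[g][v]`, which narrows the search tree without losing
   any embedding (every true embedding φ satisfies φ(v) ∈ M[g][v]).

Both pruning steps are sound: no graph containing the query is ever
discarded. A single large target graph is handled as a one-graph database;
the locality map is then what prunes the matcher, which is decisive around
high-degree hubs in scale-free networks.

## Worked example

Two graphs that plain occurrence counting cannot separate: `g1` is the
branch B–A, A–C (both features `A B` and `A C` start at its A vertex) and
`g2` is the chain B–A–A–C (each feature starts at a *different* A vertex).

```r
library(PathQuery)
db <- parseGspan("t # g1
v 0 B
v 1 A
v 2 C
e 0 1
e 1 2
t # g2
v 0 B
v 1 A
v 2 A
v 3 C
e 0 1
e 1 2
e 2 3")
idx <- buildIndex(db, lp = 2)
q <- labeledGraph(c("B", "A", "C"), rbind(c(0, 1), c(1, 2)), "q")
fqCounts(queryFeatures(q, 2))
#> A B A C B A C A
#>   1   1   1   1
firstStepFilter(idx, queryFeatures(q, 2))
#> [1] "g1" "g2"
res <- runQuery(idx, db, q, "all")
res
#> QueryResult (all mode): |C1| = 2, |C2| = 1, 1 graph(s) matched, 3 state(s) explored
cat(formatMatches(res), sep = "\n")
#> g1	0->0,1->1,2->2
```

Both graphs contain every query feature at least once, so the count filter
keeps both (`|C1| = 2`). The locality filter intersects
`start("A B", g2) = {1}` with `start("A C", g2) = {2}`, gets ∅ for the
query's A vertex, and discards `g2` (`|C2| = 1`); the matcher then finds the
single embedding of `q` in `g1`, mapping query vertices 0, 1, 2 to target
vertices 0, 1, 2.

## File formats

Graphs travel in the transaction format of the graph-mining community
(`t # id` / `v idx label` / `e u v`, vertices 0..n−1 in order); see
`?parseGspan`. The index is a gzip-compressed JSON envelope; for a one-edge
graph built with `lp = 2` the decompressed payload is

```json
{"format":"pathquery-index","version":"1","lp":2,
 "graphs":[{"id":"g1","n":2}],
 "gi":{"A":{"g1":1},"A B":{"g1":1},"B":{"g1":1},"B A":{"g1":1}},
 "li":{"g1":{"A":"AQ==","A B":"AQ==","B":"Ag==","B A":"Ag=="}},
 "checksum":8}
```

with each `li` entry the base64 of the packed start bitset (bit *v* in byte
`v >> 3`, position `v & 7`; `"AQ=="` = byte 0x01 = vertex 0, `"Ag=="` =
0x02 = vertex 1).

## Command line

A thin script over the package functions is installed at
`<library>/PathQuery/exec/pathquery`:

```sh
pathquery build --db db.gspan --lp 4 --out db.idx
pathquery query --index db.idx --db db.gspan --query q.gspan \
    --mode all --max-matches 100 --explain --report run.jsonl
pathquery generate scale-free --nodes 2000 --edges 4000 --labels 8 \
    --seed 1 --out net.gspan
pathquery sample-query --graph net.gspan --edges 8 --seed 2 --out q.gspan
```

Matches are written one per line as `graph_id<TAB>v0->u0,v1->u1,...`;
`--explain` prints |FQ|, |C1|, |C2| and the explored-state count to stderr.

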