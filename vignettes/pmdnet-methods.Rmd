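---
title: "Confidence-scored interaction networks with pmdnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-scored interaction networks with pmdnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmdnet)
```

## The problem

Public interaction resources (BioGRID, IntAct, DIP, MINT, HPRD, DrugBank,
HMDB, YMDB, ECMDB, ...) describe overlapping sets of protein, metabolite
and drug interactions under incompatible identifier schemes, and any
network built by expanding a seed list through them inherits both their
redundancy and their noise. `pmdnet` implements the computational core of
that workflow locally: deduplicate heterogeneous evidence into a
pair-level store, expand seeds into an induced subnetwork, attach
per-edge and per-node confidence measures, test the subnetwork for
over-represented biological-process and pathway terms, and export the
result to Cytoscape.

## The store and its keys

Every record is anchored on accessions (UniProt-style for proteins,
HMDB/YMDB/ECMDB for metabolites, DrugBank for drugs; kind is inferred
from the namespace). Redundancy is eliminated by concatenating the two
accessions (lexicographically ordered, so the key is symmetric) with the
supporting publication id: records sharing `idA_idB_pmid` collapse to one
evidence row with merged source databases and methods, and keys sharing
the pair collapse to one stored pair whose publication set accumulates.
Records without a publication use an empty-pmid sentinel so unpublished
reports of the same pair still merge. Self-interactions are stored but
excluded from neighbor sets, induced edges and all degree-like counts; we
prefer clean degree semantics over representing autointeractions in
downstream topology.

## Edge confidence: the Class score

The Class score is additive over three evidence components:

* **Evidence type**: +4 if any supporting record is experimental, 0 for
  purely predicted pairs.
* **Publication record**: +4 if described in more than one paper with at
  least one *not* high-throughput, +3 if in more than one paper (all
  high-throughput), +1 for exactly one paper, 0 if unpublished. A
  high-throughput paper is one describing **more than 500** interactions
  (strict boundary; papers with unknown interaction counts are treated as
  high-throughput, the conservative choice because such papers can never
  then push an edge into the top class on their own).
* **Co-localization**: +1 when the partners' selected cellular-component
  sets intersect.

Totals map to classes and rendering widths A (9, 2.5), B (7–8, 2.0), C
(6, 1.5), D (5, 1.0), E (4, 0.5). Two boundary rules deserve note.
First, an experimental pair described in no paper is labeled **E even
when its partners co-localize**; we keep the total additive (5) and
implement the rule as a label override, so the totals stay monotone in
every component while the label honors the novel-interaction convention.
Second, all named classes describe experimental evidence; predicted
pairs (totals 0–5) that are not experimental are labeled `unclassified`
and removed by any Class-score filter.

## Edge reliability: FSWeight

The Functional Similarity Weight estimates how likely a reported
interaction is genuine from neighborhood overlap alone. With closed
neighborhoods $N_u, N_v$, common count $c = |N_u \cap N_v|$, exclusive
counts $e_u, e_v$ and pseudo-counts
$\lambda_{u,v} = \max(0,\, \bar n - (e_u + c))$ (where $\bar n$ is the
graph's average closed-neighborhood size),

$$\mathrm{FSW}(u,v) \;=\; \frac{2c}{e_u + 2c + \lambda_{u,v}}
  \times \frac{2c}{e_v + 2c + \lambda_{v,u}}.$$

The pseudo-count penalizes neighborhoods smaller than the graph average,
so a pair of poorly characterized nodes cannot score highly by sharing
their only neighbor. The score is symmetric, lies in $[0,1]$, is 0 for
disjoint neighborhoods and 1 for identical closed neighborhoods at least
as large as $\bar n$. `lambda_mode = "none"` drops the correction for
ablation. FSW is computed on the pre-filter induced subnetwork; a
post-filter recomputation can be done by calling `fsw_edge_scores()` on
the filtered network, but the filter pipeline itself uses pre-filter
values (the pipeline lists FSW last, and recomputing mid-pipeline would
make the stage semantics depend on each other in ways the contract does
not promise).

## Node significance

For node $i$ with $k_i$ pairs among the subnetwork's $n$ pairs, and $K_i$
pairs among the organism-filtered store's $N$ pairs, a binomial
proportion z-score

$$z_i = \frac{k_i/n - K_i/N}{\sqrt{(K_i/N)(1-K_i/N)/n}}$$

is standardized by the batch mean and standard deviation, and the
upper-tail standard normal probability of the standardized value is the
node's p-value — over-connected nodes (relative to the batch) are
significant, matching the filtering intent of discarding random expansion
partners. Whether to standardize before taking the tail is a genuine
ambiguity; we implement the standardized reading and export both `z_raw`
and `z_std` so either convention can be inspected. Degenerate store
counts ($K_i \in \{0, N\}$) have no defined z; those nodes receive the
worst p in the batch and a flag, rather than failing the whole batch. A
zero batch standard deviation yields p = 0.5 everywhere.

## Expansion and the filter pipeline

Seeds grow breadth-first to depth 1–3; metabolite and drug partners join
the frontier only when enabled (seed entities are kept whatever their
kind). The edge set is the **induced subgraph** — every stored pair among
the retained nodes, not just traversal edges — because within-level edges
are what give clusters and FSW their meaning. Filters then run in a fixed
order: Class score, node p-value, deletion of nodes with degree 0 and 1,
FSW. Each stage only removes elements and degrees are refreshed between
stages. The degree prune is a **single simultaneous pass** on entry
degrees (a node reduced to degree 1 by the pass itself survives); the
iterated 2-core variant sits behind `iterate_prune = TRUE`. Seeds and
bait are pruned like any other node unless `protect_seeds = TRUE`
(default off). Permuting the filter order can change the result; only
the stated order is contractually tested.

Bait attachment (two-hybrid workflows) adds the bait as a level-0 seed;
preys without store evidence get a novel experimental edge with zero
publications — class E with width 0.5, per the novel-interaction rule —
and the `novel` flag set.

## Expression annotation

Fold-change uploads are matched by accession, then by gene symbol.
Regulation boundaries are **closed**: up iff $fc \ge$ `up_cutoff`, down
iff $fc \le$ `down_cutoff` (conventionally ±1.3 for proteome data and
±1.2 for metabolome data). Up/down nodes recolor red/green, overriding
level colors, and node size becomes proportional to $|fc|$ under the
default scaling; other nodes keep a degree-proportional size so hubs
stand out.

## Enrichment

For each term the quadruple $(k, n, K, N)$ counts **annotated proteins
only** (network proteins in the term; network proteins with any
annotation; likewise for the background universe; metabolites and drugs
are excluded). Whether to count all entities or annotated entities was
left open by the source description; we count annotated entities and the
report header records this. The p-value is the upper tail
$P(X \ge k)$ of the hypergeometric distribution — the standard
over-representation reading. Two evaluation modes exist: *exact*
(binomial coefficients evaluated directly in linear space, which
overflows double precision for very large counts) and *log-gamma* (terms
accumulated via `lgamma` in log space, safe at any size). The handoff is
by term size, $K > 1800$ by default — the empirical transition point of
the original implementation — and both modes agree to $10^{-9}$ relative
error wherever both are computable. Raw p-values are reported with no
multiple-testing correction by default (matching the $p \le 0.05$
convention of the source analyses); Benjamini–Hochberg is available via
`adjust = TRUE`.

Per-node cluster assignment gives each node the enriched term containing
it with the smallest p, restricted to terms with more than `min_cluster`
(default 3) member nodes and, optionally, at least one seed member. Ties
on p break by larger $k$, then lexicographic term id — determinism over
aesthetics.

## Topology diagnostics

`P(k)` is the raw-binned fraction of nodes at each degree (log-binning is
not used; the choice is recorded here because the source figures do not
state it), the FSW distribution uses 0.1-wide bins, and the power-law
exponent is the unweighted least-squares slope of $\log P(k)$ vs
$\log k$ over positive bins. On noiseless $P(k) \propto k^{-\gamma}$ the
fit recovers $\gamma$ exactly; on finite preferential-attachment graphs
raw-binned OLS gives slopes around $-1.8$, shallower than the asymptotic
$-3$, which is expected for this estimator and why the tests check the
scale-free band $[-3.5, -1.5]$ and agreement with an independent fitter
rather than the asymptotic constant. `score_class_composition()` ranks
edges by FSW (ties: class rank, then pair key) and compares class
percentages in the top fraction against the whole edge set.

## XGMML

The writer emits the Cytoscape 2.8-era dialect (typed `att` elements,
`graphics` children). Node shapes: proteins ELLIPSE, metabolites
RECTANGLE (squares), drugs TRIANGLE. Colors are fixed hex constants:
bait `#FF0000`, seeds `#0000FF`, level 1 `#00FF00`, level 2 `#FFA500`,
level 3 `#800080`, metabolites/drugs `#FFFF00`, up/down `#FF0000`/
`#00FF00` (the original tool's exact colors are unpublished; these are
the named colors it describes). Edge width encodes the class (A 2.5 …
E 0.5). Elements are written in sorted order and reals with 17
significant digits, so output is byte-deterministic and numerics
round-trip; `read_xgmml()` restores a network attribute-wise and stashes
unrecognized `att` elements in a spare map.

## The synthetic world

`synth_store()` emulates the statistical structure of an integrated
interaction database, not its content: a scale-free protein graph from
preferential attachment (`n_proteins = 200`, `attachment_m = 2` —
desk-scale but enough for a heavy-tailed degree distribution), 70/30
experimental/predicted evidence, Poisson(1.5) publications per pair with
30% of papers high-throughput (counts drawn above/below the 501
boundary), metabolites and drugs attached to degree-weighted proteins,
and term vocabularies kept at or below 50 terms so enrichment oracles can
enumerate exactly. `evidence_fsw_coupling` concentrates multi-paper
experimental evidence on pairs with many shared neighbors; near 1 this
reproduces the qualitative signature that top-FSW edges are enriched in
classes A and B. Defaults were chosen once as a realistic desk-scale
world and are not tuned to test outcomes.

What the generator does **not** emulate: real identifier semantics,
organism biology, annotation hierarchy (the GO DAG), inter-database
biases, or the size of genome-scale backgrounds. A green test therefore
establishes the correctness of the algorithms on stores with this
statistical shape, not the biological conclusions of any particular
case study; the published case-study networks require the full external
databases and are out of scope.

## Known limitations

* Identifier resolution covers accessions and gene symbols with a
  reviewed-first rule; isoforms and RefSeq versioning are not modeled.
* The child-to-ancestor cellular-component mapping is a flat table; no
  DAG reasoning.
* Enrichment offers no term-redundancy trimming or permutation tests.
* Host–pathogen records store both organism labels; organism filtering
  keeps any pair touching the organism and leaves interpretation to the
  caller.
* Graph layout is Cytoscape's job; only attributes enabling it are
  written.
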