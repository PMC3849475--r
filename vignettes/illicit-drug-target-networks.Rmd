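---
title: "Methods: illicit drug-target networks, hubs, bridges and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: illicit drug-target networks, hubs, bridges and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(illicitnet)
```

## The model

`illicitnet` treats drug–target data as an undirected bipartite graph: one
node class is drugs, the other is the human genes encoding their protein
targets, and an edge records that the drug binds a product of that gene.
Three networks are derived from one record collection:

* the **illicit network** — drugs whose legal-status groups contain the
  tag `illicit`, plus their mapped human target genes;
* the **illicit-extended network** — the illicit network plus every
  *illicit-related* drug (a non-illicit drug sharing at least one target
  gene with at least one illicit drug), with the related drugs' edges
  restricted to the illicit target genes. The gene side therefore never
  grows, and the illicit network is an exact subgraph of the extended one:
  both facts are asserted by the constructor's invariants;
* the **full network** — every target-bearing drug and every mapped gene.

Three modelling assumptions are baked in and worth stating plainly:

1. **Edges are simple and unweighted.** Multiple pharmacological actions
   between one drug and one gene collapse to a single edge, because the
   degree-based analyses treat edges as counts of distinct partners.
2. **Gene identity is the mapped symbol.** Two UniProt accessions mapping
   to one symbol are one node. Targets are filtered to records whose
   species tag equals `Humans` (case-insensitively) *before* mapping; a
   target accession missing from the mapping table is dropped from the
   network but reported in an `unmapped_accessions` attribute, so
   attrition is auditable rather than silent.
3. **Drug sets partition target-bearing drugs only.** A drug with no
   mapped human target belongs to no set and is reported separately; the
   illicit / illicit-related / other sets are pairwise disjoint and
   jointly exhaustive over the rest.

## Centrality, cutoffs, and the hub/bridge rules

Degree is the number of incident edges. Betweenness is the unnormalized
pair-dependency sum over unordered node pairs,
\(B(v) = \sum_{s \ne t \ne v} \sigma_{st}(v) / \sigma_{st}\),
with disconnected pairs contributing zero. Two conventions exist in the
wild — summing over unordered pairs, or over ordered pairs (exactly twice
the former). The package computes the unordered form by default and
records the convention in the result's attributes; `pair_convention =
"ordered"` doubles the values for parity with tools that count directed
pairs. The implementation delegates the shortest-path accounting to
igraph's Brandes algorithm; the test suite checks it against an
independent exhaustive geodesic-enumeration oracle (minimal-length walk
counting via adjacency-matrix powers) on 200 random bipartite graphs of up
to 12 nodes.

Hubs and bridge nodes are defined by *strict* threshold exceedance:
`degree > t` and `betweenness > t`. The strictness matters at the
boundary — a degree cutoff of 9 flags nodes of degree 9 or more only if
one states the rule as "greater than 8"; the package always applies
`metric > threshold` to whatever threshold is supplied, so a cutoff
reproducing a "greater than eight" rule is the value 8.

The cutoff itself is, in visual practice, "where the rank distribution
reaches its asymptote". The package makes that reproducible as a
Kneedle-style knee: sort the values in descending order, draw the chord
from the first to the last point of the rank curve, and take the rank at
maximum perpendicular distance from the chord. Ties break toward the
smallest rank, an (almost) linear curve is flagged `low_confidence`
(there is no knee to find), and fewer than three distinct values is an
error directing the caller to manual mode. Manual thresholds are
first-class — they are the documented way to reproduce externally chosen
cutoffs — and the axis scaling of the rank curve does not affect the
detected rank, because for a fixed chord the perpendicular distance is a
constant multiple of the vertical deviation.

## Exact statistics

All of the category analyses reduce to two exact computations, implemented
in log space with log-gamma binomial coefficients because realistic
category tables push p-values to 10^-26 and beyond, far past where naive
products underflow:

* **Two-sided Fisher exact test.** The p-value is the sum of
  hypergeometric point probabilities, over all tables with the observed
  margins, that do not exceed the observed table's point probability
  (minimum-likelihood two-sided definition, with the classical
  `1 + 1e-7` relative guard against log-gamma rounding at
  equal-probability tables). A table with an empty row or column carries
  no information: p = 1 with a warning. p-values are never reported as 0;
  if the log-space sum underflows double precision the smallest positive
  double is returned with an `underflow` attribute.
* **Upper-tail hypergeometric probability** P(X ≥ k), an exact tail sum
  over the feasible support. P at the support minimum is exactly 1. The
  candidate-gene overlap test is this query with population = gene
  universe, successes = candidates inside the universe, draws = network
  genes, observed = candidates among network genes. The package reports
  tail probabilities only — the point mass P(X = k) is not a p-value and
  is never substituted for the tail.

Benjamini–Hochberg adjustment wraps `stats::p.adjust(method = "BH")`
behind input validation; there is no reason to re-derive a standard
step-up procedure. Likewise the large-sample Wilcoxon comparison delegates
to `stats::wilcox.test` (normal approximation with tie and continuity
corrections), but the small-sample path is an authored exact enumeration
over all assignments of the pooled values: the standard implementation
abandons exactness in the presence of ties, while the package's contract
is exact enumeration whenever both samples have at most 10 observations,
ties included.

### Category analyses

ATC second-sublevel membership is the first three characters of a
seven-character ATC code (anatomical letter + two-digit therapeutic
subgroup). A drug belongs to a category if *any* of its codes maps there,
and contributes at most once per category; drugs with no ATC annotation
are excluded from both comparison sets before counting, since their
membership is unknowable rather than negative. Comparative enrichment
(two drug sets, or two disjoint gene universes) runs one two-sided Fisher
test per category with at least one member in either set, flags
significance at raw p < α (default 0.05), and is anti-symmetric under
swapping the sets. The two-stage pathway analysis first tests the gene
set of interest against each pathway within a stated universe
(hypergeometric tail + BH across pathways, adjusted α = 0.05 by default),
then compares the two gene sets per pathway with the comparative Fisher
design at raw α. Gene universes are always explicit parameters: overlap
handling between "illicit target genes" and "genes also hit by other
drugs" is a modelling decision the caller should see, not something to
infer silently.

## The synthetic generator

Because curated drug–target content is licensed and versioned, the
package ships a generator rather than data. It emulates the qualitative
structure of a curated drug–target database: drugs organized in a few
dense therapeutic clusters, a minority illicit group concentrated in some
clusters, category-correlated ATC codes, a handful of very-high-degree
drugs, and genes that join otherwise separate clusters.

The edge model is a planted-partition bipartite graph: each within-cluster
drug–gene pair is an independent Bernoulli draw at `p_within` (default
0.3), each cross-cluster pair at `p_between` (default 0.01). The default
world has four clusters — depressants, stimulants, analgesics, steroids —
of 20 drugs × 15 genes each. Bernoulli independence is the simplest model
that reproduces the cluster structure; it does *not* produce the
heavy-tailed degree distributions of real databases, which is why two
kinds of structure are planted explicitly:

* **Hub drugs** (one per cluster by default) have their within-cluster
  edge probability multiplied by `hub_boost` (default 3, capped at 1),
  giving expected degree ≈ 13–14 against a cluster background of ≈ 4–5.
* **Bridge genes** (two by default) belong to no cluster; each is wired
  to `bridge_edges_per_side` drugs in each of its two assigned clusters
  and to nothing else. The default is 10 of the 20 drugs per side — a
  bridge gene is meant to emulate a target shared broadly across two
  medication categories, and it must carry more cross-cluster traffic
  than the background `p_between` edges do, or it is not structurally a
  bridge at all. With weak attachment (say 2–3 drugs per side) the
  random cross-edges between two 300-pair cluster faces already provide
  comparable shortest-path capacity, and "recovering the planted bridge"
  would be a coin flip rather than a property of the method.

Illicit status is a per-cluster Bernoulli flag; the default fractions
(0.5, 0.4, 0.3, 0.1 across the four clusters) already contain a 5-fold
contrast between the most- and least-illicit clusters. ATC codes are
syntactically valid seven-character codes whose second sublevel is drawn
from the cluster's pool (80% the cluster's dominant category, 20% a
shared `V03` filler); 85% of drugs carry an ATC annotation, mirroring the
fact that category counts in real data always run on an annotated subset.
Ten percent of drugs carry one non-human decoy target so the species
filter is exercised on every generated dataset. All randomness flows from
one integer seed through deterministic per-stage sub-seeds, and the
generated records serialize to byte-identical XML under the same seed.

What passing tests on this generator do show: the pipeline recovers
planted structure (hubs by knee-cutoff degree flags, bridges by
betweenness rank) and the category tests are calibrated (null
false-positive rate near the nominal 5%). What they do not show: behavior
under real heavy-tailed degree distributions, real ATC code multiplicity,
or real curation noise — the generator is a correctness instrument, not a
realism claim.

## Numerical and design choices

* **Problem sizes.** The oracle suites run 200 random graphs (≤ 12
  nodes) for betweenness and 300 random instances (population ≤ 200) for
  the exact tests; parameter recovery uses 20 seeds of the default
  4-cluster world; the null-calibration suite uses 500 replicate
  category tests at set sizes 86 vs 594 with membership probability 0.3.
  Those null-set sizes are chosen so the Fisher support is fine-grained
  enough for the test's discreteness not to push the false-positive rate
  far below nominal, which it does for very small sets.
* **Power in property tests.** The planted-ATC-enrichment property is
  certified on 100-drug clusters: with the default 20-drug clusters the
  illicit set is ~24 drugs, and no exact test can promise p < 0.001 in
  every seed at that sample size. The property is about the enrichment
  machinery, not about small-sample miracles.
* **Rounding.** Report tables print percentages at one decimal, rounded
  half-up (so 6.25% prints as 6.3, where C-style formatting would give
  6.2); a zero count prints as `0 (0)`. Mean degrees are reported both
  unrounded and at one decimal, because a published one-decimal figure
  can disagree with the unrounded ratio of the published counts — the
  summary keeps both so any discrepancy is visible rather than hidden.
* **Determinism.** `run_pipeline()` with the same configuration and seed
  writes a byte-identical bundle; input files are read with fixed column
  contracts and all outputs are sorted before writing.

## Limitations

* The ID-mapping step uses a local accession→symbol table; resolution of
  multi-species target entries beyond the Humans-only rule is out of
  scope, as is any live ID-mapping service.
* Interaction sign (agonist/antagonist), edge weights, drug–drug and
  protein–protein edges are not modelled.
* Knee detection is a geometric heuristic; on distributions without a
  clear asymptote its threshold is reported with `low_confidence` and a
  manual cutoff should be preferred.
* Whether a given external tool counts ordered or unordered node pairs in
  betweenness cannot always be determined; both conventions are supported
  and the one in use is recorded in output metadata, but no claim is made
  about any particular tool's convention.
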