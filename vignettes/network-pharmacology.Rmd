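---
title: "Network pharmacology of a multi-herb formula: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology of a multi-herb formula: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmnet)
```

## The analysis

A multi-herb formula is treated as a perturbation of a molecular
interaction network rather than as a single ligand hitting a single
receptor. The pipeline reconstructs that view in five stages:

1. **Ingest.** Five table kinds: a herb–compound roster; scored
   chemical–protein interaction records; a disease-target list; one or more
   scored protein–protein interaction (PPI) edge lists; and a term–gene
   annotation table (GMT or TSV). Confidence scores are kept only when
   *strictly* greater than 0.4 — the conventional medium-confidence cutoff
   in STRING/STITCH-style resources, whose integer 0–1000 dialect is
   auto-detected (any score above 1 switches the column to a /1000
   interpretation). Self-loops are dropped and duplicate unordered pairs
   collapse to their maximum score, which is conservative and monotone when
   further sources are added.
2. **Network construction.** Three undirected simple graphs:
   (i) the *compound–target network*, bipartite over compounds with at
   least one retained interaction (compounds without evidence are excluded
   here, not at ingest, so the raw roster stays intact) and their targets;
   (ii) the *herb–target–disease network*, where each herb links directly
   to every target reached through any of its compounds (compounds are
   collapsed out), and disease targets enter only if a PPI edge connects
   them to a compound target; proteins in both the compound-target and
   disease-target sets are labelled shared targets;
   (iii) the *PPI expansion network*, seeded with all compound and disease
   targets plus every protein directly interacting with a seed. By default
   the expansion keeps the full induced subgraph on that node set; a
   `star` switch restricts to seed-incident edges for sensitivity
   analysis. Seeds without any PPI edge remain as isolated nodes.
3. **Topology.** Degree; betweenness normalized by $(N-1)(N-2)/2$ with the
   standard fractional weighting over tied shortest paths; and closeness.
   Plain closeness (the reciprocal of a node's total distance to all
   others) is undefined on disconnected graphs, and the expansion network
   can be disconnected, so we use the Wasserman–Faust component-corrected
   form
   $$C(i) = \frac{r_i}{N-1}\cdot\frac{r_i}{S_i},$$
   with $r_i$ the number of nodes reachable from $i$ and $S_i$ the sum of
   those distances; it reduces to $(N-1)/S_i$ on connected graphs and lies
   in $[0,1]$. The raw $1/S_i$ variant is available behind
   `node_closeness(..., method = "raw")`. Graphs are treated as
   unweighted: confidence scores act as filters, not as edge lengths.
4. **Hub selection.** The three thresholds are the arithmetic means of the
   three indices over *all* nodes of the expansion network (including the
   neighbor proteins). A *major node* meets all three inclusively
   (ties select). *Potential targets* are the major nodes that are
   compound targets, counting shared compound/disease targets. The
   *direct-interaction network* is the induced subgraph on the major
   nodes with isolated nodes removed — removal is applied only here, since
   a hub that touches no other hub carries no direct-interaction
   information.
5. **Enrichment.** For a study set of $n$ annotated genes of which $k$ lie
   in a term with $K$ of $N$ background genes: fold enrichment
   $(k/n)/(K/N)$ and the hypergeometric upper tail $P(X \ge k)$. The
   default is the conservative EASE variant $P(X \ge k-1)$ used by DAVID
   and similar annotation servers; the plain tail sits behind
   `ease = FALSE`, and Benjamini–Hochberg q-values behind
   `correction = "BH"`. The background defaults to all genes annotated in
   the table (all a GMT file can know); it can be restricted to the
   network's nodes via the pipeline's `background = "network"` switch.
   Study genes absent from the background are dropped with a warning, as
   annotation servers do.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_score` | 0.4 | strict lower bound on confidence scores (both dialects) |
| `edges` | `"induced"` | expansion edge rule (`"star"` = seed-incident only) |
| `drop_isolated` | `TRUE` | isolated-node removal in the major-node subgraph only |
| `closeness` | `"wf"` | component-corrected closeness (`"raw"` = $1/S$) |
| `ease` | `TRUE` | EASE ($k-1$) hypergeometric tail |
| `correction` | `"none"` | raw p-values by default; `"BH"` optional |

Identifier reconciliation is deliberately out of scope: all tables are
assumed to share one protein namespace (e.g. gene symbols), since curated
resources disagree on mappings and the mapping step is upstream of this
analysis.

## The synthetic-study generator

Curated chemical–protein and PPI resources cannot be redistributed, so the
package generates complete studies with the statistical structure the
analysis assumes, and the planted structure provides ground truth that real
data never has.

* **Roster and interactions.** Per-herb compound counts are taken from the
  configuration; a configurable fraction of compounds receives
  above-threshold interactions whose target popularity follows preferential
  attachment, so a few targets are hit by many compounds, as compound–target
  maps typically show. Structural records draw scores uniformly on
  (0.4, 1]; decoy records (compounds without retained evidence, plus
  sub-threshold PPI pairs and a couple of self-loops) draw from [0.2, 0.4],
  so the filter is exercised while post-filter marginals match the
  configuration exactly.
* **PPI background.** A planted core–periphery interactome: a dense core of
  `planted_hubs` proteins (pairwise probability `p_core`, plus a
  connectivity ring), a quota of dedicated low-degree attachment proteins
  per core member, and remaining first neighbors attaching preferentially
  to the core (`hub_boost`). Every non-core protein's degree inside the
  expansion network is capped (`periph_cap`), keeping the degree
  distribution heavy-tailed and the core separable — interactomes are
  heavy-tailed, and hub selection must be exercised on a realistic degree
  spread. An Erdős–Rényi-style alternative (`ppi_model$model = "er"`)
  provides a hubless null. `n_far` proteins attach only outside the seed
  neighborhood, so first-neighbor expansion genuinely excludes something.
* **Disease targets.** `n_shared` of the disease targets are drawn from the
  compound targets; a configured number of the exclusive ones receive a PPI
  edge to a compound target (only those can enter the herb–target–disease
  network), and the rest stay unlinked.
* **Annotations.** Random gene sets, plus planted terms whose gene sets
  include each planted-hub compound target with probability
  `term_enrichment`, topped up with filler genes to `term_size`. When the
  study set recovers the planted targets, the expected fold enrichment is
  analytically $q\,N/K$ with $q$ the enrichment probability — the test
  suite checks the empirical mean over 20 seeds against this.

The default configuration is a desk-scale study (44 compound records, 40
targets, 12 disease targets, ~200-node expansion network, 20 planted hubs
of which 15 are compound or shared targets); it mirrors the proportions of
the paper-scale configuration at roughly one-third scale, and the planted
term's detectability at `term_enrichment = 0.85` and `term_size = 20` gives
the enrichment stage realistic but not trivial signal. The paper-scale
configuration (`paper_scale_config()`) pins the marginal counts of a
published four-herb osteoarthritis study: 435 herb–compound records
(32/88/143/172 per herb), 34 compounds with retained interactions over 122
targets, 24 disease targets (7 shared, 11 exclusive ones PPI-linked), a
609-node expansion (470 first neighbors), and a planted 41-node core (16
compound targets, 4 shared targets, 21 neighbor proteins). These marginals
are enforced by construction, for every seed; only identifier assignments,
scores, and the incidental edge counts vary. The fixture is regenerated
from its configuration rather than shipped as files — regeneration is
byte-identical under a fixed seed (the manifest records the configuration),
which also rules out fixture drift.

What the generator does *not* emulate: real identifier vocabularies and
their mapping problems, correlated evidence between STITCH-like and
STRING-like sources, annotation ontology structure (no is-a propagation),
and literature-driven annotation bias. Passing tests therefore demonstrate
that the machinery is correct and that the selection rules recover planted
structure under realistic degree heterogeneity — not that any particular
biological conclusion transfers to real resources.

## Numerical choices and degenerate inputs

* Thresholds are held unrounded internally; logs print them at the
  precision conventions of the field (two decimals for degree, five for
  betweenness, four for closeness).
* Betweenness of networks with fewer than three nodes is defined as zero;
  closeness of an isolated node is zero; a term with no background genes is
  skipped; `k = 0` gives fold 0 and p 1 (such terms are omitted from
  enrichment output).
* Enrichment ties are broken by descending fold then term id, so output
  order is total and deterministic.
* The pipeline is RNG-free; all randomness lives in the generator, which
  seeds the Mersenne-Twister locally and restores the caller's RNG state.
* Empty keep-sets, empty seed sets, empty tables, disjoint study sets, and
  all-filtered interaction files raise typed errors (or a warning plus an
  empty result where the condition is survivable, e.g. a legitimately
  filtered-out table).

## Design choices on genuinely open points

* The source study reports more exclusive disease targets in its expansion
  network than in its herb–target–disease network (12 vs 11) without
  explanation; we do not force agreement — each network reports its own
  role tally, and our expansion network carries all exclusive disease
  targets among its nodes.
* Whether its 72-major-node set reduced to a 41-node direct-interaction
  network purely by isolated-node removal is inferred rather than stated;
  `drop_isolated` is therefore a flag, defaulting to true only for that
  network.
* The same study counts 41 potential targets yet describes the 41-node
  network as containing 21 non-target proteins; both quantities cannot be
  the compound-target intersection. We implement them as distinct outputs:
  `potential_targets()` (the intersection) and the induced major-node
  network.
* Whether its enrichment p-values used the EASE correction is unstated;
  both variants are provided, with EASE as the default because the
  reported analysis used an annotation server that defaults to it.

## Problem sizes

The test suite and the acceptance script run the paper-scale study (609
nodes, ~1.2–1.4k retained PPI edges) once per seed, 200 brute-force oracle
comparisons on graphs of up to 12 nodes, exhaustive hypergeometric
enumeration up to a background of 12, and 20 default-scale recovery
studies; these sizes keep a full run in the low tens of seconds on a
single core while leaving every code path exercised.

## Known limitations

* No GO graph propagation; terms are independent gene sets.
* No weighted shortest paths; scores never act as distances.
* One shared identifier namespace is assumed across all tables.
* The generator's exactness is a design goal (marginals by construction),
  so it is not a fully "natural" random-graph model; the Erdős–Rényi
  switch exists precisely to check that conclusions about hub recovery are
  not artifacts of the planted construction.
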