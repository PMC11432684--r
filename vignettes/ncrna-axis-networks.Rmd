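---
title: "Building and interrogating mRNA-miRNA-lncRNA axis networks"
author: "ncaxis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and interrogating mRNA-miRNA-lncRNA axis networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncaxis)
```

## The problem

Gene Ontology tooling is protein-centric, while disease models increasingly
involve non-coding RNA: microRNAs (miRNAs) that repress mRNA targets, and
long non-coding RNAs (lncRNAs) that can sequester — "sponge" — those miRNAs
(the competing endogenous RNA, ceRNA, hypothesis). `ncaxis` implements a
workflow for extending a curated list of gene/protein biomarkers ("seeds",
or genes of interest) with experimentally supported ncRNA context: it
extracts a tripartite mRNA-miRNA-lncRNA network from a local NPInter-style
interaction table, reduces it to the loop-capable core, characterizes the
lncRNA-governed miRNA blocks that dominate such networks, propagates binary
expression hypotheses through sponge logic, and finally runs a conventional
GO over-representation test on the retained genes widened with their
BioGRID interactors.

## Network model

The network is a typed undirected graph with three node layers — seed genes
(mRNA and protein biomarkers are treated as one seed-matchable class),
miRNAs, and lncRNAs — and edges only between layers (seed-miRNA,
seed-lncRNA, miRNA-lncRNA). Each edge carries an `evidence_count`: the
number of interaction rows supporting that pair. Identifiers are compared
case-insensitively after whitespace stripping, which matters in practice
because community databases mix `hsa-miR-…` and `hsa-mir-…` spellings; the
first-seen spelling is kept for display.

### Two-step extraction (`build_axis`)

1. Keep every miRNA with at least one interaction with a seed.
2. Keep every lncRNA with at least one interaction with a seed *and* at
   least one interaction with any miRNA.
3. Extend the miRNA set with the miRNA partners of the retained lncRNAs.

Step 3 is what admits miRNAs with no seed contact: they enter the network
only through a shared governing lncRNA and form the characteristic "miRNA
blocks" (see below). We deliberately let step 2 qualify an lncRNA through
*any* miRNA partner rather than only seed-linked miRNAs: the alternative
reading would make seedless blocks impossible by construction, contradicting
their observed central role in these networks. Seeds enter the node set only
if they retain at least one edge.

### Occurrence threshold (`threshold_filter`)

Large interaction databases make raw axis networks unmanageable, so markers
occurring fewer than `k` times are expunged in a single pass (at threshold
3, markers occurring three or more times are retained). "Occurrence" is, by
default, the number of *distinct neighbors* (degree), which is robust to
redundant database rows; a `rows` mode counting total supporting rows is
available for sensitivity analysis, since either reading of "number of
occurrences" is defensible. The threshold is applied to the ncRNA layers
only: seeds are never thresholded directly and drop out only through edge
loss and pruning. This keeps the seed-retention counts an *output* of the
filtering rather than an input choice.

### Single-interactor pruning (`prune_single_interactors`)

Nodes with exactly one interactor cannot participate in a
mRNA-miRNA-lncRNA regulatory loop, so they are removed in one simultaneous
pass, followed by removal of any node left isolated. The default scope
restricts the degree-one predicate to seed nodes, because full-scope
fixed-point pruning destroys the chain-like peripheral structures that
published axis networks visibly retain; `scope = "all_nodes"` and
`fixed_point = TRUE` are available for aggressive reduction. The pipeline
order is fixed and logged: organism/evidence scoping, axis construction,
threshold, pruning.

## miRNA blocks and the reverse query

A *miRNA block* is a maximal set of seedless miRNAs (no edge to any seed)
held together by shared lncRNA governors — operationalized as a connected
component of the bipartite subgraph on lncRNAs and seedless miRNAs, reported
when it contains at least `min_size` (default 5) miRNAs. Governors are
ranked by within-block degree. This turns a judgment made visually on
network figures into a reproducible graph criterion.

The reverse query (`governed_genes`) asks which genes are regulated
*through* a block: every lncRNA interacting with at least `min_links`
(default 2) **distinct** block miRNAs is collected, and all mRNA/protein
partners of those lncRNAs are returned. Counting distinct miRNAs rather than
rows matches the intent of "at least two miRNA markers".

## Sponge-logic state propagation

`propagate_states` encodes the ceRNA reading of the network as a
deterministic two-step rule, starting from a partial assignment of lncRNA
states (`expressed` is the default for unassigned lncRNAs):

* a miRNA is **sponged** iff any neighboring lncRNA is expressed, otherwise
  **active** (a miRNA with no lncRNA neighbor is active);
* a seed gene is **repressed** iff any neighboring active miRNA remains,
  otherwise **uninhibited**.

Direct seed-lncRNA edges are *not* propagated through — lncRNA-on-gene
effects are mechanistically heterogeneous — and are returned as
`unresolved_edges` for manual review rather than silently guessed. The
result is independent of node iteration order. `psoriasis_axis_example()`
ships a 17-node network (six seed genes, seven miRNAs, four lncRNAs)
encoding a psoriasis drug-response hypothesis in which NEAT1 is
down-regulated: propagation leaves exactly the two NEAT1-dependent miRNAs
(hsa-miR-485-3p, hsa-miR-371a-3p) active and represses their targets
TNFAIP3, SHOC2 and HTR2A, while genes targeted only by sponged miRNAs stay
uninhibited. The five miRNAs sponged by the other expressed lncRNAs carry
placeholder names, as the narrative identifies only the two active ones.

## Interactor expansion and GO over-representation

Retained seeds are widened with their first-degree BioGRID partners
(`expand_interactors`), read from a local tab3 file with both interactors
required to pass the organism filter; self-pairs are flagged, not dropped.
`enrich` then emulates the usual "p < 0.05 with Bonferroni step-down"
over-representation setup directly: the raw p-value per GO term is the
right-tailed hypergeometric probability (`stats::phyper`) of the observed
study count, and the step-down correction is Holm's procedure
(`stats::p.adjust(method = "holm")` — "Bonferroni step-down" is the same
algorithm). Annotations come from a local GAF 2.x file restricted to
experimental evidence codes (EXP, IDA, IPI, IMP, IGI, IEP, HTP, HDA, HMP,
HGI, HEP) by default, with `NOT`-qualified rows and annotations to unknown
or obsolete terms skipped and counted. Direct annotations are propagated to
all ancestors via `is_a` and `part_of` (other relations ignored), and the
default background population is the set of all annotated genes, since
published analyses rarely state their background explicitly. Terms are
tested only when at least `min_study_count` (default 2) study genes hit
them. Kappa-score term grouping, term fusion and GO-level windows of
GUI-based tools are intentionally out of scope, so exact p-values from such
tools are not reproducible — term-level statistics under a declared
background are.

## The synthetic fixture generator

`generate_fixture` exists so that every stage is testable offline, with
*known ground truth*, against files that exercise the same parsing paths as
real downloads. Its planted structure mirrors the phenomena the workflow is
about:

* miRNA blocks: block miRNAs receive edges **only** to their governor
  lncRNAs, never to seeds; each governor also receives a seed edge
  (otherwise step 2 would discard it); background miRNAs always touch a
  seed, so no background node can leak into a block and truth recovery is
  exact on noise-free configs.
* decoy rows: wrong-organism rows (discarded by the organism filter in
  exactly their configured number) and unrecognized-type rows (carried as
  `"other"`, excluded by axis construction).
* enrichment: a planted term annotates the study genes (seeds plus their
  generated BioGRID partners) at `fold` times the baseline rate of 0.05.
  The default planted term is the last generated term, which is always a
  leaf of the generated DAG — planting at an internal node would confound
  the planted signal with annotations propagated up from noisy descendant
  terms and make the ground truth ill-defined.

Defaults (20 seeds, 40 miRNAs, 10 lncRNAs, one 12-miRNA block with 2
governors, edge density 0.08, population of 200 genes, fold 8) are sized so
that a full pipeline run takes well under a second while every stage still
has non-trivial work; they are structural mimics, not statistical ones — no
attempt is made to match real degree distributions, so passing tests
demonstrate rule correctness, not robustness to the extreme hub skew of real
ncRNA databases. All randomness flows from the single `rng_seed`, and the
same configuration always produces byte-identical files.

## Numerical and degenerate-input choices

* Unordered edges are stored canonically (endpoints sorted), so equality of
  networks is plain data-frame equality.
* Threshold and pruning are single simultaneous passes on counts computed
  from the *input* network, making them order-independent; the fixed-point
  variant iterates whole passes.
* Empty inputs degrade gracefully: header-only tables parse to empty tables
  with zeroed provenance, an unmatched seed list yields an empty network
  with a warning naming the seeds, and an empty study set yields an empty
  enrichment result with a warning.
* Malformed interaction rows are counted and skipped, never fatal; missing
  required columns (a dialect mismatch) are fatal and name the column.
* Ties in governor ranking and in enrichment ordering are broken by
  identifier to keep output deterministic.

## Problem sizes used in validation

The shipped validation suite runs entirely on generated data: brute-force
rule enumeration is compared exactly against the implementation on 200
random networks of at most 20 nodes; the hypergeometric tail is checked
against combinatorial enumeration on all ~87,000 instances with population
size at most 30 (agreement within 1e-12); planted-structure recovery and
Monte-Carlo detection of a planted term (50 generator seeds, fold 8, Holm at
alpha 0.05) use the generator defaults above. These sizes were chosen as the
smallest at which every rule path — seedless blocks, multi-governor
components, decoy filtering, step-down ordering — is exercised.

## Known limitations

* The NPInter dialect covers the tab-separated "experimentally validated
  interactions" layout and configurable header names; RNA-DNA and
  circRNA-specific extensions are carried as `"other"` but not modeled.
* Expression states are binary; there is no quantitative weighting of
  interaction strength or tissue specificity, which real applications of
  sponge reasoning eventually need.
* The OBO reader covers the subset of the format that annotation
  propagation needs (`is_a`, `relationship: part_of`, obsolescence); it is
  not a general ontology parser.
* Block detection depends on the seedless property, which is itself a
  function of the upstream threshold: aggressive thresholding can detach a
  miRNA from its last seed and move it *into* a block. This mirrors the
  method's behavior, but means block membership should be read relative to
  the stated threshold.
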