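---
title: "Reconstructing gene-family dynamics with orthodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene-family dynamics with orthodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodyn)
library(dplyr)
```

## The problem

Comparative studies of plant (and other) genomes summarize evolution at the
level of *orthogroups*: sets of genes descended from a single ancestral gene
in the last common ancestor of the species compared. Given a rooted species
tree and an orthogroup-by-species table of gene copy numbers, the questions
are *where* on the tree each family was gained or lost, where it expanded
from one copy to several (or contracted back), and where individual genes
duplicated. Because most species in such comparisons contribute de novo
transcriptomes rather than genomes, two additional problems arise: foreign
sequences (from symbionts, food sources, or lab contamination) must be
screened out before orthology inference is meaningful, and absence of a gene
may mean non-expression rather than loss — a caveat the reporting has to
carry, not hide.

orthodyn implements this analysis stack: an Alien Index contamination
screen, ancestral gene-content reconstruction under two parsimony criteria,
species-overlap duplication mapping on gene trees, hypergeometric term
enrichment of node-assigned gene sets, and a ground-truth simulator that
closes the loop on all of it.

## Ancestral content: Dollo and Wagner parsimony

Both reconstructions are topology-only: branch lengths are ignored
throughout, and multifurcating species trees are handled natively.

**Dollo parsimony** treats an orthogroup as gainable exactly once but losable
any number of times. The optimal solution is closed-form: the gain sits at
the MRCA of the species possessing the family; inside that subtree a node is
present iff some descendant leaf is present; each present-parent to
absent-subtree edge is one loss. This is implemented directly
(`dollo_reconstruct()`) and verified against exhaustive enumeration of every
single-gain presence assignment on trees of up to 8 leaves — the enumeration,
not the closed form, defines correctness in the tests.

**Wagner parsimony** treats copy number as an ordered integer character with
symmetric unit cost per copy gained or lost on an edge. We read "unweighted"
as *unit cost per copy change* (`|parent - child|`), not per transition
event; the alternative reading (one cost per event regardless of copy
difference) would collapse expansions into gains and is deliberately not
implemented. `wagner_reconstruct()` is a Sankoff dynamic program over states
`0..max_state`, multifurcation-safe, with each child folded in by an
O(states) distance-transform pass, so the per-orthogroup cost is
O(nodes × states) rather than O(nodes × states²). The state space is
truncated at the observed leaf maximum per orthogroup — with linear edge
costs no optimal ancestral state can exceed it — and leaf counts are capped
at `max_state` (default 64, with a warning) before the DP.

Ancestral-state ties are real in parsimony and must be broken reproducibly.
The rule: bottom-up, every node's full minimal-cost state set is kept (for
linear costs it is an interval); top-down, a node takes the state minimizing
its subtree cost plus the step from its parent's assigned state, preferring
the state closest to the parent and then the smaller one; the root takes the
smallest state in its optimal set. The bias is deliberately *against*
inventing ancestral copies. The exhaustive-enumeration tests confirm the
assignment always achieves the global minimum cost.

**Events.** For each node `v` with parent `u`: a gain is absence at `u` and
presence at `v`; a loss is the reverse; an expansion is `state(u) = 1` and
`state(v) >= 2`; a contraction the reverse. Gain and expansion are mutually
exclusive (a 0 → 2 shift is a gain only, since expansion is defined strictly
from the single-copy state). The root has no parent: a gain is charged there
when the root is reconstructed present (otherwise the family would exist
nowhere), but no root expansion or contraction is charged, because those are
defined only as parent-to-child shifts. Dollo-based and Wagner-based
gain/loss tallies are reported side by side — the two criteria bracket the
truth, Dollo being conservative near the leaves and Wagner near the root —
and either can be read off `tally_events()` output. `summarize_tree()`
re-derives ancestral totals and enforces the bookkeeping identity
`total(v) = total(parent) + gains(v) - losses(v)` at every node, erroring on
any violation (a bug trap; it cannot fire on valid reconstructions).

## Duplication mapping

Gene-tree nodes are classified by the species-overlap rule: an internal node
whose child subtrees share at least one species is a duplication (a pure
speciation cannot place the same species on both sides). The clade support
of a call is the overlap fraction `|intersection| / |union|` of the species
sets of the two most-overlapping children (the best pair, when the node is
multifurcating); events with support below 0.50 are discarded by default,
inclusively at the boundary. Each event maps to the species-tree MRCA of the
species beneath the gene-tree node. Per species-tree node, both the total
event count and the number of distinct orthogroups with at least one event
are reported, since one family duplicating five times and five families
duplicating once are different biology. Gene trees must arrive rooted; a
multifurcating root is treated as the signature of an unrooted tree and
rejected unless the caller asserts otherwise, and a convenience
midpoint-rooting flag (requiring branch lengths) warns that rooting choices
move duplication nodes.

## Alien Index screening

For each query protein, every hit's bit score is divided by the query's
maximum bit score after removing self-hits; "normalized" is not otherwise
pinned down by convention, and this choice is what makes the normalized
scores lie in (0, 1] and the index lie exactly in [-1, 1]. The Alien Index
is `AI = nbsO - nbsV`: the best normalized out-group score minus the best
normalized in-group score, with 0 substituted when a side has no mapped hit.
Queries with `AI >= 0.05` (inclusive) are flagged as possible contaminants.
The in-group defaults to Viridiplantae (green plants and algae); lineage
assignment comes from an explicit subject-to-group table rather than live
taxonomy lookups, so runs are deterministic and offline. Queries with no
mapped hits receive no score and are retained — absence of homology evidence
is not evidence of contamination — and are counted separately in the report.
No attempt is made to separate genuine horizontal transfer from
contamination; a transcriptome cannot distinguish them.

## Term enrichment

Node-assigned gene sets (e.g. the focal species' genes in orthogroups gained
at a node) are tested per term with the exact upper-tail hypergeometric
probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed via
`stats::phyper` (which is the exact tail sum); the test suite checks it
against direct binomial-coefficient arithmetic to a relative error below
1e-12. The background is all *annotated* genes of the focal species —
unannotated genes carry no information about term composition; using all
genes instead is a configuration choice the caller can make by padding the
annotation map. Adjustment is Benjamini–Hochberg via `stats::p.adjust`,
cross-checked against an explicit backward-minimum step-up loop. Note that
BH is *not* idempotent (re-adjusting adjusted values can move them up
again); what does hold, and what the tests assert, is order invariance and
that constant p-vectors are fixed points. Annotation maps are assumed
ancestor-propagated already; no ontology graph is parsed. Significant terms
(adjusted p < 0.05) are linked into an enrichment map when the Jaccard
similarity of their study gene sets reaches 0.2 (Jaccard and the cutoff are
explicit configuration, since no single convention exists), and connected
components define term clusters.

## The simulator, and what passing its tests does and does not show

`simulate_gene_content()` generates each orthogroup by choosing a gain
branch (the root with probability `root_gain_fraction`, default 0.5,
otherwise uniform over branches), starting one copy there, then walking the
tree: on each descendant edge the whole family is lost with probability
`p_loss`, otherwise each copy duplicates with probability `p_dup` (Bernoulli
per copy, so counts stay bounded and gene-tree growth stays simple).
Defaults are `n_orthogroups = 100`, `p_loss = p_dup = 0.05` — loss/retention
rates in the few-percent-per-branch range produce the mix of ubiquitous,
patchy and lineage-specific families seen in real orthogroup tables, while
keeping most histories uniquely reconstructable so recovery statistics are
interpretable. Loss is whole-family per branch, *not* per copy, so that at
`p_dup = 0` the generative model coincides exactly with Dollo's model class;
per-copy loss would make the generator strictly harder than the
reconstruction criterion and turn recovery rates into a property of the
mismatch rather than of the code. Gene trees are grown by deterministic
replay of the recorded event log (when an edge carries d duplications among
k copies, the first d copies duplicate — leaf counts are invariant to which),
so the emitted matrix and the gene trees agree by construction, and
hand-written histories are replayable too. An event recorded on the gain
node itself is interpreted as a duplication on the gain branch, above the
first speciation.

The closed-loop tests (zero-noise recovery of all states and tallies over
500 orthogroups; exact duplication-tally recovery over lossless replicates;
exact contaminant recovery; injected-term recall with a null-generator FDR
check) show that every stage inverts the generator it was built against.
They do not show robustness to what the generator omits: gene-tree estimation
error, incomplete transcriptome sampling (absence as non-expression — carried
as a per-species `data_type` caveat column, not modeled), orthology
mis-clustering, rate heterogeneity, or branch-length information, which the
parsimony criteria ignore by design. On real data the Dollo and Wagner
tallies should be read as bounds, not point estimates.

## Numerical and degenerate-input choices

* Internal species-tree nodes are named `N1, N2, ...` in preorder when
  unlabeled; user labels win. Event tables are therefore stable across runs
  and machines.
* The `Total` column of count matrices is always dropped and recomputed;
  hand-edited files lie.
* Strict species matching between matrix and tree is the default; the
  intersection mode logs every dropped species and refuses an empty
  intersection.
* Empty matrices, header-only files, all-absent profiles, single-leaf trees
  within gene trees, and studies with no annotated genes all return empty —
  not erroneous — results.
* All stochastic code paths run under a single caller-supplied seed via
  `withr::with_seed`, leaving the session RNG untouched; pipeline outputs
  carry no timestamps, so identical configurations produce byte-identical
  files (checksummed in `MANIFEST`).

## Problem sizes used in the shipped checks

The test suite and acceptance script exercise: 200 random tree/profile pairs
per parsimony criterion against exhaustive oracles (trees to 8 leaves for
Dollo, 6 for Wagner with counts to 3); 500 zero-noise orthogroups on an
8-leaf tree; 200-orthogroup runs across the loss grid {0, 0.02, 0.05, 0.1};
a 200-query screen at 10% contamination plus 1,000 small random tables for
the AI invariants; 20 lossless duplication replicates; 100 random
hypergeometric and BH configurations; 50 null enrichment replicates; and two
full pipeline runs compared checksum-for-checksum. These sizes make every
oracle comparison exhaustive rather than sampled where exhaustiveness is the
point, and keep each criterion's runtime in seconds.

## Limitations

Parsimony reconstruction reports one optimal solution under a stated tie
rule, not the full optimum set; no probabilistic birth–death model is
offered. Duplication support is the species-overlap fraction defined above —
external duplication tables computed under other definitions will not match
it and should be re-derived from the gene trees. The enrichment module does
not parse OBO ontologies or perform ranked-list (GSEA-style) analysis.
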