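---
title: "Disease-metabolic subpathway networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-metabolic subpathway networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpathnet)
```

## The problem

Disease genes rarely implicate a whole metabolic pathway; they concentrate
in local regions of it. `subpathnet` operationalizes such a region as a
**k-clique subpathway**: a maximal set of enzymes whose pairwise geodesic
distance in the pathway's enzyme graph is at most *k*. Linking every
disease to its enriched subpathways yields a bipartite disease–subpathway
network whose topology can be interrogated with standard network-biology
machinery: which subpathways sit under many diseases, whether disease and
subpathway classes cluster, and how the gene make-up of a subpathway
relates to the number of diseases it touches.

## From KGML to enzyme graphs

A KGML file contributes its enzyme entries (EC numbers) and reactions.
Two distinct enzymes are joined when they are co-listed on a reaction, or
when some compound is a product of one enzyme's reaction and a substrate
of the other's; reversible reactions contribute both orientations. This
compound-mediated rule is reconstructible from KGML alone and needs no
curated relation elements. KGML's `ECrel` relations encode similar
information, but inconsistently across pathway versions; the compound rule
is the single adjacency criterion exposed.

Currency metabolites (ATP, NAD(H), H2O, ...) participate in so many
reactions that linking through them makes every pathway near-complete. The
blacklist is **empty by default** — conservative, and reproducible without
judgement calls — and a documented optional list ships in
`inst/extdata/currency_metabolites.txt`.

Each EC number is one node even when a single gene carries several EC
activities, and gene IDs are opaque strings: identifier conversion is out
of scope, the gene↔EC table is taken as given.

## Mining semantics

Subpathways are the maximal cliques of the k-th graph power, with
distances measured in the **whole pathway graph** (the k-clique sense; a
k-club would re-measure distances inside the candidate subgraph and is a
different, harder object). Disconnected enzyme pairs (infinite distance)
never satisfy the bound. `k = 3` is the default working scale: large
enough to span a few reactions, small enough that a subpathway stays a
local region. `k = 4` gives coarser regions and is a parameter away.

Determinism matters because subpathway IDs are positional
(`<pathway_id>_<i>`): cliques are ordered by decreasing size, then
lexicographically, before indices are assigned. IDs are therefore
reproducible given the same inputs, but not comparable across different
pathway snapshots. No size floor is applied by default (`min_enzymes = 1`);
mining never merges overlapping subpathways.

## Enrichment model

For disease genes restricted to the background universe, the association
between a disease and a subpathway is scored with the hypergeometric upper
tail P(X ≥ x) — strictly "at least x", so x = 0 scores exactly 1. The
background defaults to all genes annotated to at least one enzyme of the
collection: the universe the subpathway gene sets live in. Using a larger
(e.g. genome-wide) background would deflate every P-value for reasons
unrelated to pathway structure; an explicit background can be supplied
where a different convention is wanted.

Edges keep pairs with **raw** P below α = 0.01; no multiplicity correction
is applied by default, so edge counts are comparable with the long line of
subpathway-enrichment analyses that threshold raw P-values. An optional
Benjamini–Hochberg flag (`fdr = TRUE`) thresholds adjusted values instead,
while still reporting raw P-values.

## Null ensemble

The resampling null keeps the tested universe fixed — every disease keeps
its gene-set size, the subpathway collection and background are untouched —
and redraws each disease's genes uniformly from the background, rerunning
enrichment and assembly per replicate. This preserves test multiplicity
and set-size structure while destroying true associations.

One subtlety: the bipartite `density` of a network whose nodes are only
the endpoints of retained edges is *not* comparable across replicates — a
null replicate with three edges among three diseases and two subpathways
scores density 0.5. The ensemble therefore also records
`universe_density`, the edge count over the fixed number of tested pairs,
and that is the statistic referred to the observed network. Empirical
P-values use the add-one estimator (1 + #extreme)/(1 + R), which cannot
return zero. The default R = 200 suits desk-scale runs; 1000 replicates is
the full-scale convention. "Breadth" of a degree distribution is
operationalized as its coefficient of variation (sd/mean): scale-free,
zero for regular sequences, large for fat tails; the variance is available
as an alternative.

## Class clustering: BD and BH

Dyadicity and heterophilicity are defined for one-mode graphs, so the
bipartite network is first projected: two same-side nodes are adjacent
when they share at least one neighbor (threshold configurable). On the
projection with N nodes, M edges and mean connection probability
p = 2M/(N(N−1)), a class with n1 members, m11 within-class edges and m10
class-to-outside edges scores

- BD = m11 / e11, e11 = p·n1(n1−1)/2
- BH = m10 / e10, e10 = p·n1(N−n1)

BD > 1 means the class wires to itself above chance; BH < 1 means it
avoids the outside; BD > BH indicates clustering. A permutation mode
replaces e11/e10 with means over uniform relabelings (class sizes
preserved), conditioning on the realized projection; analytic and
permutation expectations agree in mean, and the test suite checks them
against each other within Monte-Carlo error. This projection-based
bipartite adaptation is **this package's construction** — other
adaptations (hypergeometric shared-neighbor nulls, degree-preserving
rewiring) exist and would give different absolute values, so BD/BH values
should be compared within one construction only. Classes whose expectation
degenerates (n1 < 2 for BD, empty complement for BH) raise an
undefined-statistic error and are excluded, with a log line, from the
class-table averages; averages are unweighted over classes — classes, not
nodes, are the units.

Disease diversity of a subpathway divides the number of distinct disease
classes among its neighbors by the total number of classes; it is monotone
under edge addition and, on planted-signal data, positively rank-correlated
with degree.

Biclustering of the binary incidence matrix uses city-block (L1) distances
with complete linkage on each axis — the classic heat-map recipe for 0/1
association matrices. Rows and columns are pre-sorted by node ID so tied
merges resolve deterministically; leaf orders and Newick dendrograms are
exported for external viewers rather than rendered.

## Gene correlates

Per-subpathway ratios (|class ∩ genes| / |genes|) are regressed on node
degree by OLS with the two-sided t-test on the slope; each subpathway is
one point. Binned summaries (equal-count quantile bins, default 10) are
reported separately for plotting and are never what the regression runs
on. Coexpression is mean pairwise Pearson correlation (Spearman behind a
flag) over unordered distinct gene pairs; genes missing from the matrix or
flat across tissues are dropped, and a group with no admissible pair
yields `NA`, never a silent zero. The all–all pair group is the random
control; group medians across subpathways are compared to it with
two-sided Wilcoxon rank-sum tests. "Other" genes are those in none of the
four label sets.

## The synthetic study design

`simulation_design()` fixes the study conditions for all offline testing:

| knob | default | why |
|---|---|---|
| pathways | 50, 8–20 enzymes, edge density 0.25 | small enough for sub-minute runs; spanning-tree + random edges keeps graphs connected |
| background | 2000 genes, 1–3 per enzyme | stable hypergeometric tails away from degenerate counts |
| diseases | 120 in 12 classes, 10–40 genes | enough subpathway nodes (~40–50) for trend and rank tests |
| planted signal | 60 diseases, signal fraction 0.6 | strong but not deterministic enrichment |
| class assortativity | 0.8 | same-class diseases usually share a target → plants BD structure |
| class base rates | disease .19, essential .17, HK .10, TS .07 | proportions of real curated list sizes relative to a ~15k-gene universe |
| trend strengths | +1.5 / −1.5 / 0 / +1.5 per SD | logistic in subpathway degree score; directions disease+, essential−, HK flat, TS+ |
| expression | 36 tissues, block r = 0.7 | blocks over a subpathway's disease+TS genes; HK genes never join a block (constitutive expression) |

Reaction realization guarantees parse→build fidelity: every simulated
graph edge becomes one shared compound between two enzymes' reactions, so
writing KGML and re-parsing reproduces the topology exactly. All
generators are pure functions of (design, seed).

What the generator does **not** emulate: real pathway topology statistics
(hub enzymes, pathway size skew), overlapping disease vocabularies,
expression tissue structure, or annotation noise. Passing tests therefore
demonstrate that the pipeline recovers what it is designed to detect under
known conditions — not that any particular biological claim holds on a
given real dataset.

## Numerical and scale choices

Hypergeometric tails come from `phyper`; the test suite pins them to
exhaustive draw enumeration on small universes and pins the mining to
brute-force subset enumeration on graphs of up to 12 nodes. Empirical
P-values are add-one. Degenerate inputs fail loudly: inconsistent counts,
empty backgrounds, zero degree variance, undefined BD/BH classes, and
groups with no admissible coexpression pair all raise errors or `NA`
sentinels rather than silently coercing. Default problem sizes (the design
above; 100–200 null replicates; 100 label simulations in the acceptance
checks) keep a full offline validation run in the low minutes on one CPU
while leaving comfortable statistical margins.

## Limitations

- Subpathway IDs are positional and snapshot-specific; they cannot be
  matched across different pathway database versions.
- The BD/BH bipartite adaptation is one of several defensible
  constructions; absolute values are construction-specific.
- Enrichment treats gene sets as unstructured; no topology weighting
  inside a subpathway, no GSEA-style ranked statistics.
- The resampling null preserves set sizes but not gene-level annotation
  biases (e.g. multifunctional genes); a gene-degree-preserving null would
  be stricter and is not implemented.
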