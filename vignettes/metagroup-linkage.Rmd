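---
title: "From enrichment output to non-redundant metagroups: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From enrichment output to non-redundant metagroups: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termlinker)
```

## The problem

Functional enrichment analysis of a gene list returns long tables of
significant term/gene associations that are heavily redundant: the same
biological function is annotated under near-synonymous terms within one
vocabulary, repeated across databases (GO, KEGG, InterPro, ...), and
diluted by promiscuous generic terms ("protein binding", "regulation of
biological process") that cover large fractions of a genome. termlinker
post-processes such output into a small number of *metagroups*: sets of
genes linked to the co-annotations that describe one coherent function,
ranked by significance and internal coherence. The linkage is *fuzzy* —
a gene, or a whole gene combination, may legitimately belong to several
metagroups.

## The element: GeneTerm-sets as closed itemsets

The unit the pipeline manipulates is the GeneTerm-set
$E_i = (G_i, A_i, p_i)$: a set of genes $G_i$, the terms $A_i$ every one
of those genes is annotated with, and the enrichment p-value $p_i$. In
frequent-itemset language the terms are items, genes are transactions,
and $|G_i|$ is the support of the itemset $A_i$. Singular enrichment
(SEA) produces elements with $|A_i| = 1$; concurrent/modular enrichment
(MEA) produces $|A_i| \ge 1$.

`concurrent_enrichment()` enumerates **closed** frequent itemsets only
(an LCM-style prefix-preserving search, verified in the tests against a
power-set oracle). Closedness is the right granularity here: two terms
annotated to exactly the same query genes are synonymous evidence and
must travel in one element, not spawn duplicates. A consequence worth
stating is that a singleton $\{t\}$ whose closure is larger does *not*
appear alone in MEA output, while SEA emits it — the two modes agree on
every element they share (same genes, same p-value) but are not
set-equal by construction.

The p-value of an itemset $A$ with query support $G$ is the exact
hypergeometric tail
$P(X \ge |G|)$, $X \sim \mathrm{Hypergeom}(N, K, M)$, with $M$ the query
size, $K$ the number of universe genes carrying *all* terms of $A$, and
$N$ the universe size. The universe defaults to the full organism gene
list of the loaded spaces; `population = "annotated"` restricts it to
genes with at least one annotation (the literature is silent on this
choice, so it is a flag).

## Generic-term tagging

For each annotation space the per-term gene counts $N_g$ are profiled
and a term is tagged *generic* when

$$N_g > \bar{x} + n\,\sigma_x$$

with $n = 4$ by default. $\sigma_x$ is the sample standard deviation
(n−1 denominator) across the terms of one space — the conservative
reading where the convention is unstated; `sd_type = "population"` is
available. Tagging is strict (`>`), monotone in $n$, and never removes a
term: generic terms stay usable in co-occurrence with specific ones.

Note the rule's operating regime: because the outliers themselves
inflate $\sigma_x$, a promiscuous term is only detectable when such
terms are *rare* relative to specific ones (roughly fewer than 1 in 16
terms at $n = 4$). Real GO/KEGG spaces satisfy this comfortably; the
synthetic generator's defaults were chosen to satisfy it too (see
below).

## The four linker steps

1. **Filter.** Drop every element whose *entire* term set is generic;
   elements mixing generic and specific terms are kept intact.
2. **Cluster (reciprocal linkage).** Each element becomes a vector of
   length $M + 1$: binary occurrence of each query gene, plus
   $p_i \times M$ as a strength component (the literal reading of
   "p-value weighted by factor M"; the multiplier is configurable and
   `p_weight_mode = "off"` zeroes it). Pairwise distances are
   $1 - \cos(v_i, v_j)$, in $[0, 1]$ for these non-negative vectors.
   Ward agglomeration is applied to these cosine dissimilarities
   directly — the classical `ward.D` Lance–Williams convention. Cosine
   distances are not guaranteed Euclidean-embeddable, so this is the
   defensible variant and is implemented in-package with a fixed
   tie-break (smallest pair of cluster indices), making the tree a pure
   function of the matrix. The tree is cut at 20% of its depth (maximum
   merge height); if no cluster reaches `min_elements` (default 2) the
   cutoff escalates by absolute 10-point steps until one does, or the
   whole tree becomes one pre-metagroup at 100%. Singleton clusters are
   carried forward. Pre-metagroups sharing non-generic terms are then
   merged greedily (largest shared count first, fixed point), which
   restores cross-database synonymy that gene-space clustering alone
   can split.
3. **Complete cover.** Within each metagroup, elements are visited from
   least to most significant and removed when both their genes and
   their terms are covered by the union of the remaining elements. The
   gene/term unions are provably preserved and no single retained
   element is still removable (both properties are asserted on every
   call and stress-tested on 1,000 random metagroups). With tied
   p-values the lexicographically larger element id is considered for
   removal first, so smaller ids are preferentially retained — an
   arbitrary but documented and tested total order that makes the
   result independent of input order.
4. **Score.** Per metagroup: the exact hypergeometric tail of its gene
   union against the universe genes annotated with at least one of its
   terms (union semantics for $K$; intersection semantics is degenerate
   for large term unions and is available behind a flag), adjusted by
   Benjamini–Hochberg across metagroups; silhouette width
   $s(i) = (b - a)/\max(a, b)$ averaged per group; diameter (maximum
   within-group cosine distance); similarity coefficient (1 − mean
   within-group distance). Score-stage geometry uses gene-only vectors
   (p component off). Ranking is by adjusted p, then silhouette, then
   id.

Conventions for degenerate geometry: a singleton-element group
contributes silhouette 0, has diameter 0 and similarity 1; with a single
metagroup the silhouette is reported `NA`, never fabricated. Queries
below 7 genes warn (reciprocal linkage rarely finds traction there) but
run.

One self-inflicted subtlety of union-semantics scoring: a metagroup that
absorbed an element co-annotated with a generic term inherits that
term's huge carrier population $K$, and its hypergeometric p-value goes
conservative (toward 1). Ranking then falls through to the silhouette
tie-break. This is the faithful reading of "tested with all the genes
and terms" and is left as-is; excluding generic terms from $K$ would be
a behavioural change this package deliberately does not make.

## The synthetic benchmark: what it emulates, what it does not

`generate_space()` plants disjoint gene modules (default: 5 modules of
10 genes in a 1000-gene universe), annotates each with small specific
terms (4 per module) duplicated across pseudo-databases (`SRC1`,
`SRC2`), and adds promiscuous generic terms covering a random half of
the universe. This reproduces the three features the method exists for:
skewed term-size distributions with heavy outliers, cross-database
synonymous terms, and uninformative generic annotation. Defaults were
fixed analytically before any acceptance run: with 20 specific terms
and 1 generic term per space, the generic term sits just past the
$\bar{x} + 4\sigma_x$ threshold (the 1-in-16 rarity condition above),
which is the regime real annotation spaces occupy.

The generator does **not** emulate: hierarchical term structure and
partial term overlap (specific terms annotate *exactly* their module),
incomplete or erroneous annotation, overlapping modules, or realistic
p-value correlation structure. A green recovery test therefore
establishes that the pipeline separates well-annotated disjoint modules
under 20% random noise and cross-source synonymy — not performance on
curated genomic annotation, which depends on database snapshots this
package neither ships nor downloads.

Benchmarking statistics mirror standard practice: all-pairs Rand
accuracy and Jaccard coefficient over gene-pair co-membership (a pair is
co-grouped when it shares *any* group, the natural extension to fuzzy
groupings), gene-level precision/recall/F-score in percent, and a noise
protocol that appends `round(0.2 * |ref|)` random non-reference genes to
the query. Noise counting uses round-half-up; the canonical 10-gene
example (2 noise genes) is exact either way.

## Numerical and design choices

* Exact `phyper` tails everywhere; no normal approximation.
* All tie-breaks are total and documented (Ward: smallest cluster-index
  pair; cover: decreasing p then decreasing id; ranking: adjusted p,
  silhouette, id), so identical inputs give byte-identical reports —
  there is no RNG anywhere in the linker, only in noise injection and
  the generator, both behind explicit seeds.
* Tree-cut comparisons use a `1e-12` absolute epsilon so merges at
  exactly the cut height (e.g. height-0 merges at a 0 cut) are included.
* Small-universe edge cases: spaces need ≥ 2 terms for outlier
  statistics; a 1-term space contributes an empty policy in the
  pipeline rather than failing.
* Config files: YAML or JSON (TOML was dropped — no parser in the
  supported dependency set).

## Known limitations

* No GO-graph awareness: term similarity is purely extensional
  (shared genes/terms), by design — that is what makes the method
  applicable to KEGG, InterPro and other non-hierarchical sources.
* The closed-itemset search is exponential in the worst case; it is
  intended for enrichment-scale inputs (a few hundred query genes,
  tens-to-hundreds of frequent terms), not for genome-wide transaction
  mining.
* Union-semantics metagroup p-values are conservative in the presence
  of generic co-annotation, as discussed above.
* Identifier handling is deliberately dumb: exact string match after
  whitespace trimming. Orthology and alias resolution belong upstream.
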