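---
title: "Scoring GO overrepresentation results by biological informativeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring GO overrepresentation results by biological informativeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orabench)
```

## The problem

Overrepresentation analysis (ORA) asks whether the genes in a study list are
annotated to a Gene Ontology (GO) term more often than a background would
suggest. Dozens of tools implement the same hypergeometric core, yet their
outputs differ substantially: they disagree on the testing universe, the
correction procedure, filtering rules, and the ontology release. Comparing
tools by raw statistics (how many terms reach significance) misses the point
of the analysis, which is biological interpretability. `orabench` scores an
enrichment result by how *informative* it is relative to known target terms:
are the significant terms semantically close to the targets, are the targets
ranked near the top, are the reported terms specific or generic, and do the
significant terms organise into coherent semantic clusters?

Every metric operates on a plain table of (term id, raw p, adjusted p), so
the output of any tool can be ingested and scored against the same targets
under identical rules.

## Models and procedures

### Ontology and annotations

The GO Biological Process namespace is a directed acyclic graph whose edges
are typed `is_a` or `part_of`. `parse_obo()` reads OBO 1.2/1.4; obsolete
terms are retained but stripped of edges, and `alt_id`/`replaced_by` map to
primary ids so stale identifiers in foreign result tables still resolve.
Annotations (GAF 2.x or GMT) are propagated by the true-path rule: a gene
annotated to a term is annotated to every ancestor. Two term properties
serve as specificity proxies throughout:

* **annotation size** — the number of distinct genes annotated to the term
  after propagation (large = generic);
* **depth** — the number of edges on the *longest* path from the root
  (deep = specific). Longest-path depth is chosen over shortest-path depth
  because it reflects the maximal level a term occupies in the hierarchy;
  in a multi-parent DAG the shortest path systematically understates how
  specialised a term is.

Whether annotation sizes should be computed on direct or propagated
annotations is genuinely open in the field; this package always propagates
before counting, because the testing universe of the reference ORA is the
propagated one and mixing conventions would make sizes incomparable across
modules.

### Reference ORA engine

For a study list of $n$ mapped genes and a background of $N$ genes, a term
with $K$ annotated background genes and $k$ study hits is scored by the
upper hypergeometric tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

computed through the survival function for numerical stability. The EASE
variant replaces $k$ with $k - 1$, which is never anti-conservative. Every
term with at least one background gene is tested; terms with fewer than 2
study genes are then removed (the conventional minimum-gene filter), and
Benjamini–Hochberg correction is applied over exactly the emitted records.
Tools disagree on whether correction happens before or after this filter —
that disagreement is part of what the benchmark measures — so the reference
fixes correction-after-filter as the default and offers
`adjust_before_filter = TRUE` for the other convention. Results are ordered
by the deterministic key (adjusted p, raw p, term id); ranks are 1-based
positions in that order. Ordering by adjusted rather than raw p is a
documented choice (`order_by = "raw"` gives the alternative); with BH the
two orders only differ in tie regions.

### Wang semantic similarity

Term similarity uses Wang's graph-based measure. A term $A$ assigns each
ancestor $t$ a semantic contribution (S-value)

$$S_A(A) = 1, \qquad
S_A(t) = \max_{c \,:\, t \in \mathrm{parents}(c)} \; w_{t \leftarrow c} \cdot S_A(c),$$

with edge weights $w = 0.8$ for `is_a` and $0.6$ for `part_of`. Similarity
between $A$ and $B$ sums the shared contributions, normalised by the total
semantic values $SV(A) + SV(B)$:

$$\mathrm{sim}(A, B) =
\frac{\sum_{t \in T_A \cap T_B} \big(S_A(t) + S_B(t)\big)}{SV(A) + SV(B)}.$$

S-values are computed by a single memoized pass over the anchor's ancestor
closure in decreasing-depth order (a valid reverse-topological order,
because every child is strictly deeper than each of its parents); the
result is independent of iteration order since `max` is order-free. Only
`is_a` and `part_of` edges are traversed; regulates-type edges are ignored.
Similarity across namespaces is an *error*, not zero, so upstream filtering
bugs surface instead of silently deflating scores.

### Confusion matrix, target report, specificity profiles

Given target terms (the processes planted in a benchmark list), each record
of a result receives $m$ = its maximum Wang similarity to any target, and a
significance flag (adjusted p strictly below $\alpha = 0.05$). Records with
$m \ge 0.7$ are "expected" (true positive if significant, false negative if
not); records with $m < 0.3$ are "unexpected" (false positive if
significant, true negative if not). The mid-band $0.3 \le m < 0.7$ is
excluded from accuracy $=(TP+TN)/(TP+TN+FP+FN)$ and FPR $=FP/(FP+TN)$ but
reported, never silently dropped: the two-sided threshold design
concentrates the metrics on clearly expected and clearly unrelated terms.
Zero denominators yield `NA` markers rather than NaN propagation.

A target is *identified* when its exact term id is significant; its rank is
its position in the full ordered table (ranking within significant records
only is available by flag). The median over identified targets uses the
mean-of-central-ranks rule for even counts, so half-integer medians occur.

Specificity profiles take the first $\min(k, \#\text{significant})$
significant records in result order ($k = 20$ and $100$ by default) and
report median and mean annotation size and depth — small sizes and large
depths near the top of a ranking indicate informative output.

### Term networks and Markov Clustering

Significant terms form a network whose edge weights are pairwise Wang
similarities; edges below 0.5 are pruned (inclusive cutoff — the
convention is stated as "cutoff of 0.5" without strictness, and inclusive
keeps the worked boundary cases stable). Markov Clustering runs on the
weighted adjacency with unit self-loops: column-normalise, then alternate
expansion (matrix square) and inflation (entry-wise power $r = 5$,
pruning below $10^{-8}$, renormalisation) until the largest entry change
falls below $10^{-6}$ or 100 iterations. Self-loops are standard MCL
practice and prevent periodic flow on bipartite-ish structures.
Non-convergence interprets the current matrix with a warning rather than
failing, since late iterations change assignments negligibly. Clusters are
read from attractor rows; a node attracted by several attractors joins the
largest cluster (tie: the cluster with the lexicographically smallest
member) — overlaps are rare at inflation 5 and the tie-break keeps output
deterministic. Isolated nodes stay as singletons so every clustering is a
true partition of the input terms. Inflation 5.0 is the default
granularity; the planted two-block regression keeps the directional
property that higher inflation never merges clusters that 1.5 separates.

## The synthetic benchmark

`synthesize_ontology()` builds a miniature single-rooted BP-namespace DAG:
terms are placed at depths 1..5 (80 terms by default), each with one parent
in the previous layer and a 15% chance of a second parent anywhere
shallower; 20% of edges are `part_of`. Genes are annotated to leaf terms
with log-normal sizes (median 60, heavy right tail, mirroring the skewed
annotation-size distribution of the real GO) and propagated.

Scale choices, stated once:

* **Genome of 2000 genes** — a 1:10 miniature of the human protein-coding
  genome, so the benchmark's list sizes (500, 200, 100, 50) keep a
  realistic proportion to the background at 80 terms.
* **90% of the genome annotatable** — mirrors the high GO BP coverage of
  protein-coding genes. With a small annotated pool instead, *any* list
  drawn from annotations would be ~20-fold enriched for annotation per se
  and every annotated term would reach significance, a degenerate regime
  real data does not exhibit.
* **Shared leaf gene pool (2–3 direct terms per annotated gene)** — gene
  multifunctionality. Without it, a planted-target list touches no terms
  outside the target branches, results contain only significant records,
  and permutation baselines become ties by construction.

What the generator does **not** emulate: realistic term-name semantics,
evidence-code structure, inter-namespace links, annotation bias toward
well-studied genes, and the sheer scale of the live GO (tens of thousands
of terms). Tests passing on the miniature therefore validate the *metrics
and algorithms*, not any statement about specific GO releases or about the
behaviour of third-party tools.

Benchmark inputs mirror the standard designs: `make_random_lists()` draws
negative-control lists (5 replicates each of 500, 200, 100, 50 genes by
default) uniformly from the background; `make_target_lists()` builds
positive controls as deduplicated unions of target-term gene sets, with
proportional per-target quotas when truncation is needed and pairwise
Jaccard overlaps recorded so minimal-overlap target selection is auditable;
`downsample_series()` produces nested size series (nested by default — the
natural reading of building smaller lists *from* a larger one — with
`nested = FALSE` available). `select_branch_targets()` picks one deep,
moderately sized term per exclusive root branch, so targets share no
ancestor but the root. All generation is a pure function of (parameters,
seed); every generator derives a purpose-specific sub-seed internally, so
passing one seed to several generators never reuses overlapping RNG stream
segments.

## Numerical and degenerate-input conventions

* Significance is strict (`p < alpha`); `p = 0.05` is not significant.
* BH is the only correction exposed; "FDR" requests the same step-up.
* Unknown term ids: `annotation_size()` returns 0 (foreign tables with
  stale ids degrade gracefully, with counts reported); similarity and depth
  raise errors (internal misuse should fail loudly).
* Empty evaluable sets produce explicit `NA` markers (`accuracy`, `fpr`,
  `median_rank`, empty profiles), never silent NaN.
* Ties everywhere break lexicographically by term id, making every output
  deterministic and byte-reproducible under a fixed seed.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: exhaustive hypergeometric
enumeration up to population 12; Wang similarity against a path-enumeration
oracle on random DAGs of up to 30 terms; MCL against an independent dense
implementation on networks of up to 30 nodes; 200 random negative-control
lists (50 each of sizes 500/200/100/50) on the default 80-term ontology; and
planted-target runs of size 50 with 3 cross-branch targets, compared with 20
p-value permutations. These sizes keep every check exact or tightly seeded
while exercising the same code paths a full-scale analysis uses.

## Known limitations

* Only `is_a` and `part_of` edges carry semantics; regulates edges are
  dropped at parse time.
* No information-content similarity measures, no GO slim projection, no
  cross-namespace comparison: the Wang measure on one namespace is the
  package's single similarity currency.
* The reference ORA is deliberately plain (no topology-aware weighting à la
  topGO's decorrelation): it is the *yardstick* other tools are measured
  against, not a recommendation of statistical practice.
* Accuracy and FPR are the only confusion-derived summaries; sensitivity /
  F1 over the SS-thresholded matrix would mix the exclusion band into the
  denominator in ways the two-sided threshold design avoids.
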