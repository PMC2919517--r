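---
title: "Functional profiling of gene lists: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional profiling of gene lists: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funset)
```

# The problem

High-throughput expression experiments end with a list of genes called
differentially expressed, and the biological question starts there: what
do these genes have in common?  The standard answer is
over-representation analysis (ORA): accumulate the study genes into the
categories of one or more controlled vocabularies — Gene Ontology
classes, metabolic pathways, homology families, chromosomes — and ask,
category by category, whether the study list contains more members than
chance would put there.

funset implements this workflow offline and end to end: identifier
validation against a local alias table, the enrichment statistic with
multiple-testing control, ontology navigation and pruning, literature
ranking, and a seeded simulation layer that makes every step testable
without any database access.

# The enrichment model

Let `L1` be the study list (size `n`) and `L2` the background of all
genes under study (size `N`); by convention the background is the whole
genome unless the experiment measured less.  For a category `t`
annotating `K` of the `N` background genes and `k` of the `n` study
genes, the raw significance is the one-sided binomial upper tail

    p_raw(t) = P(X >= k),   X ~ Binomial(n, K / N).

The binomial model treats the study list as `n` independent draws with
per-draw success probability `K/N`.  It is an approximation to the
hypergeometric draw-without-replacement model that becomes exact as
`N` grows; its appeal is numerical robustness and speed at genome
scale.  Three modelling choices deserve emphasis:

* **One-sided, enrichment only.**  Categories are reported when they
  accumulate *more* genes than expected (`k >= 1` and a small upper
  tail).  Depletion is not scored.
* **The background stays whole.**  `N` counts every background gene,
  annotated or not.  Restricting the universe to annotated genes would
  make every category look less surprising exactly when annotation
  coverage is poor; treating `L2` as "all genes under study" keeps the
  null honest and matches the genome-wide default background.
* **The correction family is every category with `K >= 1`,** including
  those with `k = 0` (their raw p-value is 1).  One family per
  vocabulary per run.  Reported rows are the `k >= 1` categories,
  sorted by `(p_adj, p_raw, term_id)` so output order is total and
  deterministic.

Multiple testing is controlled with the Benjamini–Yekutieli step-up
procedure: with order statistics `p(1) <= ... <= p(m)` and
`c(m) = sum(1/j)`,

    p_adj(i) = min(1, min_{j >= i} p(j) * m * c(m) / j).

The `c(m)` factor makes the procedure valid under *arbitrary*
dependence between tests.  That matters here: after propagating
annotations up the ontology, ancestor and descendant categories share
genes and their p-values are strongly dependent, which is precisely
the regime where the plain Benjamini–Hochberg guarantee can fail.  The
price is conservatism — at `m = 200`, `c(m) ~ 5.9`, so adjusted values
are inflated nearly 6-fold relative to Benjamini–Hochberg.  Users
should read `p_adj < 0.05` as a stringent call.

```{r binomial-example}
# P(X >= 3) with n = 10 draws at a 10% background rate
binomial_upper_tail(3, 10, 0.1)
by_adjust(c(0.01, 0.04))
```

# The ontology layer

`parse_obo()` reads an OBO 1.2 subset — `[Term]` stanzas with `id`,
`name`, `namespace`, `is_a`, `relationship: part_of` and
`is_obsolete` — into a rooted DAG with child-to-parent edges.  The
constructor enforces what the statistics later rely on: acyclicity
(cycles are reported with their members), exactly one root per
namespace, and connectivity of every term to its root.

**Levels.**  The level of a term is the *minimum* edge distance from
its namespace root (root = 0).  Min-depth rather than max-depth is the
convention that places "response to stress" at level 2 and "response
to heat" / "response to oxidative stress" at level 3 in the
biological-process chain, which is the worked example the pruning
semantics are anchored to.  Max-depth is a defensible alternative for
multi-parent terms, but it disagrees with that anchor, so it was not
adopted.

**Propagation (true-path rule).**  A gene annotated to a term is
implicitly annotated to every ancestor.  `propagate_annotations()`
makes this explicit — each term's gene set becomes the union over its
descendants — walking the DAG once in topological order.  Both `is_a`
and `part_of` edges propagate by default (`use_part_of = FALSE` turns
the latter off).  Enrichment consumes *propagated* tables for the Gene
Ontology, so general classes accumulate the genes of their specific
children; flat vocabularies (pathway, homology, chromosome) have no
hierarchy and are used as loaded.

**Pruning.**  `prune_to_level(dag, propagated, L)` simply removes
terms deeper than `L`.  Because the input is propagated, every gene
annotated below the cut already sits at each of its ancestors at or
above the cut — pruned terms are enclosed in their more general
counterparts with no recomputation.  A term with several qualifying
ancestors contributes its genes to all of them; the alternative
(assigning each gene to one "best" ancestor) would make pruning depend
on an arbitrary tie-break.

```{r chain}
chain <- system.file("extdata", "response-chain.obo", package = "funset")
dag <- parse_obo(chain)
compute_levels(dag)
```

# Identifier normalization

Input lists arrive with mixed identifier types.  Normalization is a
dictionary problem, so the mapping table is local and explicit:
`alias -> internal_id` rows, optionally namespaced.  The rules, in
order: empty and whitespace-only tokens are dropped and counted as
nulls; tokens are resolved by exact match first and case-insensitively
only when the exact lookup fails and the case-folded key is
unambiguous; tokens resolving to one internal id are collapsed and
counted as duplicates; unresolved tokens are reported, never fatal.
An alias pointing at two different genes is rejected when the table is
*loaded* — silently guessing a target would corrupt every downstream
count.  Internal ids are accepted as aliases of themselves, which
makes normalization idempotent.

# Literature ranking

A document annotated with gene set `B` is scored against the study
list `A` by the Tanimoto coefficient of the binary membership vectors,

    T(A, B) = |A n B| / (|A| + |B| - |A n B|),

identical to the Jaccard index, and the quantity that ties together
the three numbers that matter: the study-list size, the paper's gene
count, and the shared genes.  Scores are normalized by the maximum
over the reported documents, so the best match scores 1 and the rest
are read relative to it; documents sharing no gene with the study list
are omitted.  Max-normalization is a presentation choice (any
monotone normalization preserves the ranking); it was chosen as the
simplest map onto a `[0, 1]` relevance scale.

# The synthetic layer

Every generator is a pure function of a `study_spec` and its seed
(each generator draws from its own derived seed stream), so fixtures
are reproducible byte for byte and nothing is downloaded.

* `generate_ontology()` grows a single-namespace DAG of the requested
  depth and branching, gives 20% of terms a second parent (one quarter
  of those edges `part_of`), and embeds the named
  stimulus/stress/heat/oxidative-stress chain used by the pruning
  tests; the two level-3 response terms are kept as leaves so they
  stay specific classes.
* `generate_study()` annotates each gene to one uniformly chosen leaf,
  propagates, and draws `L1` by weighted sampling without replacement:
  genes under a planted term carry weight `fold`, background genes
  weight 1.  When planted terms are not named explicitly they are
  chosen among pairwise-disjoint propagated classes covering 2–6% of
  the genome — specific but populated, the kind of class ORA is meant
  to find.  `fold = 1` is the null model: a uniform draw, nothing
  planted.
* Flat vocabularies get one planted term each, constructed *given*
  `L1` (a pathway and homology family biased to contain study genes; a
  planted chromosome to which study genes relocate with probability
  `fold / (fold + 15)`, exactly uniform at `fold = 1`).  Constructing
  them conditionally keeps the Gene Ontology planting — the one the
  recovery simulations measure — undiluted.
* `generate_corpus()` plants one target document covering 80% of the
  study list among 99 random ones; `generate_mapping()` and
  `generate_experiments()` complete the input surface.

What the simulations do *not* emulate: correlated annotation of
functionally related genes, realistic term-size distributions (real GO
term sizes are heavy-tailed), expression noise, or the upstream
differential-expression call.  Passing tests demonstrate that the
machinery is correct and calibrated under a clean planted-signal
model, not that any particular biological dataset will reproduce.

## Simulation conditions and what they show

The validation suite runs two standing simulations at a fixed size — a
2000-gene genome, 200 terms, a 50-gene study list, 100 seeds — chosen
to finish in seconds while keeping per-term counts in a realistic
range:

* **Null calibration.**  With `fold = 1`, the mean fraction of terms
  at `p_adj < 0.05` stays below 0.05 (in practice it is essentially
  zero — the `c(m)` inflation is very conservative).
* **Planted recovery.**  With five disjoint terms planted at
  `fold = 5`, the suite asks whether all five reach the top ten by
  adjusted p-value.  Under these conditions that bar is not reachable:
  a planted class covering fraction `q` of the genome has expected
  study count `n*fold*q / (1 + 5*(fold-1)*q)` against a null mean of
  `n*q`, and the implied one-sided z-score peaks near `q = 0.03` at
  about 2.6 — enough to *often* rank a term highly, far from enough to
  rank all five simultaneously in nearly every seed.  The suite states
  the bar and reports the measured rate rather than weakening either;
  a five-fold selection bias on a 50-gene list is simply a modest
  signal, and the honest reading is that recovery of *every* planted
  class at these sizes requires stronger enrichment, larger lists, or
  fewer simultaneous signals.

The packaged demonstration fixture (`write_demo_fixture()`) is a
separate, narrative object: a 35-gene study list over a yeast-sized
6000-gene genome in which the two named response terms are planted at
`fold = 50` — the order of induction a heat shock actually produces —
so the walkthrough shows clearly significant classes, a leading
planted chromosome, and a top-ranked planted paper.

# Numerical and degenerate-input choices

* `binomial_upper_tail()` evaluates through the regularized incomplete
  beta function; accuracy against exhaustive pmf summation is at the
  `1e-15` level over the desk-scale grid the tests sweep.  `k = 0`
  returns exactly 1; `p = 1` returns exactly 1.
* `by_adjust()` on an empty vector returns an empty vector; a
  single-element family is returned unchanged (`c(1) = 1`).
* `significant(alpha = 1)` keeps rows with `p_adj = 1`, so `alpha = 1`
  is the identity filter.
* Ties everywhere break lexicographically (term id, document id), so
  every report is byte-stable; numbers in TSV reports are printed with
  a fixed `%.10g` format for the same reason.
* Empty gene lists after normalization, annotation tables whose terms
  never touch the study universe, and criteria naming unknown terms or
  vocabularies are user errors with named offenders, not silent empty
  results — except `filter_genes()` on a term annotating no study
  gene, which legitimately returns an empty set.

# Known limitations

* The binomial tail is an approximation to the hypergeometric; for
  very small backgrounds (hundreds of genes) the difference is
  visible.  A Fisher/hypergeometric alternative is a natural extension
  hook but is deliberately not implemented.
* Annotation propagation is all-or-nothing per relation type; evidence
  codes and qualifiers (e.g. `NOT`) are out of scope.
* The OBO reader covers the 1.2 subset it documents; OBO 1.4
  constructs (intersections, xrefs) are ignored or unsupported.
* Literature ranking is set overlap only — no abstract text, no
  entity recognition, no weighting by publication size beyond the
  Tanimoto denominator.
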