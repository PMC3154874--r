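---
title: "maternet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maternet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maternet)
```

## The problem

During the mouse maternal-to-embryo transition, the transcripts stored in a
metaphase-II (MII) oocyte drive development until embryonic genome
activation. Developmentally competent (SN-derived, OCT4-expressing) and
incompetent (NSN-derived, OCT4-down-regulated) eggs differ in a
transcriptional network seeded by known OCT4-regulated genes, and part of
that network survives fertilisation into the 2-cell embryo. `maternet`
implements the full inference pipeline for this kind of analysis as
reusable, tested components:

1. **Expression calls** from BeadStudio-style tables (per-sample signal and
   detection p-value): a gene is *expressed* when its detection p-value is
   at or below a threshold (default 0.01, inclusive), and *differential*
   between the control and NSN condition when the ratio of mean signals
   reaches a fold-change threshold (default 1.5, inclusive), with direction
   stated NSN-relative-to-control.
2. **Annotation-similarity network**: genes are compared through their GO
   and MeSH term vectors; an undirected edge is created when the cosine
   similarity *strictly exceeds* a cutoff (default 0.7) in at least one
   namespace, and the edge records which namespaces support it
   (GO / MESH / BOTH).
3. **Bait-seeded expansion**: multi-source breadth-first search from a bait
   gene set, keeping genes within `max_hops` (default 2 — the reading of
   "fewer than 3 sequential connections") of the nearest bait; overlay of
   the two-stage expression calls yields the Venn partition
   (stage-1-only / stage-2-only / both / unexpressed), and clusters are the
   connected components of the expressed subgraph.
4. **Pattern statistics**: the joint (stage-1, stage-2) direction pattern
   per gene — the focal *reversal* pattern is (up, down), i.e. up in the
   incompetent oocyte contrast and down in the incompetent embryo
   contrast — with exact hypergeometric upper-tail tests for pattern
   enrichment in a bait set and for overlap with an external gene set.
5. **Term enrichment** with expert-supplied macro-category rollup.
6. A **synthetic-data generator** that plants all of the above structure
   with machine-readable truth, so each stage is testable end to end
   without any external downloads.

## Statistical model

All over-representation questions use one statistic: for a population of
`N` genes containing `K` "successes", drawing `n` genes and observing `k`
successes, the upper-tail probability

$$P[X \ge k] \;=\; \sum_{j \ge k} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}$$

reported one-sided and inclusive of the observed `k`, because every
question posed is about over-representation. No multiple-testing
correction is applied by default (matching the source analyses, which
report single tests); term-enrichment batches can be corrected upstream.

The parameterisation of each test is always reported alongside the
p-value (`population_N`, `successes_K`, `draws_n`, `observed_k`), so every
p-value is auditable. For pattern enrichment the universe defaults to all
genes with contrast calls at both stages; the motivating study never
states its population, which is exactly why its printed p-values are
documented but never asserted by this package's tests.

### Numerical evaluation

The pmf is evaluated in linear space: the mode term is computed as an
anchored product of `O(n)` bounded ratios (with power-of-two rescaling to
avoid under/overflow) and the remaining support follows the adjacent-`k`
ratio recurrence. We deliberately did **not** use differences of
log-factorials: a log-factorial near `N = 10^4` has magnitude ~8×10^4, so
even half-ulp rounding of the stored logs injects ~10^-11 of error — more
than the 10^-12 normalization bound we test against. The product form
keeps relative error near machine epsilon (verified against exhaustive
enumeration of all draws for every `N <= 12`, and by pmf normalization to
within 10^-12 up to `N = 10^5`).

## Similarity and network construction

Similarity is the cosine of per-namespace term-incidence vectors. With
binary weighting this is `|A ∩ B| / sqrt(|A| · |B|)`; an optional
inverse-document-frequency weighting (`log(N/df)` per term) is available
to down-weight ubiquitous terms. Two choices deserve emphasis:

* **Unannotated is not dissimilar.** A gene with no terms in a namespace
  has *undefined* similarity there (`NA`), not 0, and that namespace can
  never support an edge for it. This keeps sparsely annotated genes from
  being scored as actively unrelated.
* **Strict cutoff.** An edge requires similarity strictly greater than the
  cutoff ("exceeded"); a pair at exactly 0.7 is not linked. The similarity
  is computed as `s / sqrt(|A| · |B|)` (one square root of the product),
  so constructed rational cases such as 7/√100 evaluate exactly and the
  boundary test is deterministic.

Edge support follows the three-colour convention of published annotation
networks: a namespace supports an edge iff its own similarity exceeds the
cutoff; `BOTH` requires both. Edge weight is the maximum of the defined
namespace similarities. All-pairs computation uses a sparse
genes-by-terms incidence matrix and `tcrossprod`, which scales to
universes of tens of thousands of genes because only pairs sharing at
least one term produce entries; `annotation_similarity()` computes single
pairs by direct set arithmetic, so the two routes cross-check each other
in the test suite.

The hop limit is interpreted as shortest-path distance from the *nearest*
bait: "fewer than 3 sequential connections" means at most 2 edges, so
`max_hops = 2` keeps distance-2 genes and drops distance-3 genes. Baits
missing from the network are skipped with a warning (mirroring baits that
could not be annotated); clusters are connected components — the only
stated algorithmic reading — numbered by decreasing size with ties broken
by the lexicographically smallest member. Whether each cluster contains a
core ("both"-compartment) gene is reported, not enforced.

The expansion operates annotation-first (build the network over all
corpus genes, then intersect with expression), matching the source
order: an annotation network is retrieved first and only then reduced to
its expressed components. An `expression_first` flag provides the
alternative order.

## The synthetic world

The generator's defaults are a stated world, fixed once:

| parameter | default | why |
|---|---|---|
| `n_genes` | 500 | desk-scale stand-in for the regulated-gene lists |
| `n_modules`, `module_size` | 3 × 8 | a few tight functional modules, small enough to audit |
| `core_terms_per_module` | 20 | core large enough that 90% subsets still overlap strongly |
| `within_module_term_overlap` | 0.9 | members share ~18/20 core terms → within-module cosine ≈ 0.85, comfortably above 0.7; between modules ≈ 0 |
| `background_term_rate` | 1 per namespace | sparse Zipf-distributed noise terms, as in real corpora where a few terms are very common |
| `reversal_fraction` | 0.1 | a minority reversal signature |
| `effect_ratio` | 3 | clearly above the 1.5 threshold, as for confidently called genes |
| `noise_cv` | 0.2 | typical microarray intensity CV; log-normal keeps signals positive |
| `detection_noise` | 0.01 | occasional dropout of a truly expressed gene |
| `n_samples` | 2 | the source hybridized 1–2 chips per condition |
| venn fractions | 0.15 / 0.05 / 0.05 | stage-1-skewed compartments (most degradation happens after fertilisation), remainder expressed at both stages |
| `seed` | 7 | the reference scenario's seed |

Planting is by deterministic assignment of seeded-shuffled gene indices,
not Bernoulli sampling, so realized counts equal `round(fraction * n)`
exactly and tests can be sharp. Detection noise is modelled per
gene-condition (a flipped gene fails the threshold in all of that
condition's samples): under the min-across-samples detection rule,
per-sample noise would vanish quadratically and the parameter would be
inert. Detection p-values are drawn directly rather than derived from
signal, because the pipeline consumes only the threshold decision.

What the generator does **not** emulate: probe-level effects, the GO DAG
topology (terms are exchangeable identifiers; no propagation), correlated
noise between conditions, batch structure, and realistic annotation
sparsity gradients. A green planted-recovery test therefore establishes
that the pipeline's logic is correct on data shaped like its assumptions —
not that the thresholds are optimal for any particular real dataset.

## Degenerate inputs and tie-breaks

* Genes present in only one expression table are treated as undetected
  (detection p = 1, mean 0) in the other, not as an error.
* Mean signals are floored (default 1 unit) before ratio computation,
  because background subtraction can produce non-positive values.
* A gene expressed in one condition only still gets a fold change (against
  the floored absent mean); equal floored means give ratio 1 → unchanged.
* Determinism everywhere: nodes, edges, calls and reports are sorted
  (gene, then partner gene); cluster ids by size then smallest member;
  file writers use fixed numeric formatting so seeded bundles are
  byte-identical.
* `extract_clusters` on an empty kept set returns an empty list, not an
  error; an empty network cannot be exported.

## Open choices made here

* **Detection summary across replicates: minimum.** A gene detected in any
  replicate counts as expressed — a presence semantic, configurable by
  swapping the summary.
* **Similarity formula: cosine.** The source delegates its formula to a
  citation; cosine over annotation-term vectors is the standard reading of
  a term-vector text-mining similarity, with Jaccard-style alternatives
  possible behind the same interface.
* **Per-namespace cutoff.** The cutoff applies to each namespace's
  similarity separately (not a pooled score), because the published
  network legend distinguishes GO-only, MeSH-only and both edges.
* **Simulation configs in JSON**, mirroring `simulation_config()`
  field-for-field; no YAML dependency is assumed.

## Limitations

* Clusters are connected components; no edge-weight community detection.
* No GO-DAG semantic similarity (Resnik/Lin) or term propagation —
  propagation can be applied upstream of the annotation file.
* The hypergeometric universe for pattern enrichment is a modelling
  choice the user should state; defaults are conventional, not canonical.
* Array normalization, background subtraction and probe-to-gene collapsing
  are out of scope; inputs are assumed normalized.
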