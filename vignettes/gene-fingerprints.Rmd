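---
title: "Gene fingerprints from literature co-occurrence: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene fingerprints from literature co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefp)
```

## The model

A disease's literature is a sample of articles; a gene's literature is
another. If the two overlap more than chance allows, the gene is part of the
disease's molecular story. `genefp` quantifies this with the hypergeometric
over-representation test on a 2×2 contingency table per (disease, gene)
pair: among the `N` articles annotated with at least one disease of the
chosen family, `n` mention the disease, `K` mention the gene and `k`
mention both. The disease is then represented as its **gene fingerprint**,
the vector of `-log10(p)` enrichment weights over its directly co-occurring
genes (`k >= 1`; genes never co-mentioned are excluded so that indirect
evidence cannot inject noise at this stage — indirect similarity is
recovered later, by the low-rank step).

Fingerprints are stacked into a disease × gene matrix, truncated by SVD,
converted to Spearman correlation distances between disease rows, and
clustered spectrally. Diseases sharing the query's cluster are "related".

## Conventions that needed a decision

**Tail of the test.** The contingency formulation prints the point mass
`P(X = k)`, but an over-representation test is conventionally the upper
tail `P(X >= k)`; the upper tail is the default (`tail = "upper"`), with
`tail = "pmf"` available for literal reproduction. The two agree at the top
of the support and diverge elsewhere; the upper tail is monotone in `k`,
which the point mass is not.

**Counting universe.** `N` is the number of distinct articles carrying at
least one disease of the family, and `K` is counted within that same set
(`build_corpus(..., restrict_universe = TRUE)`, the default). The
alternative — counting over every article seen in the inputs — is one flag
away; it changes `K` and `N` jointly and mostly rescales p-values.

**Log base.** Weights are `-log(p)` with base 10 by default (`log_base`
argument). The base is a monotone rescaling of single weights, but *not* of
the matrix as a whole once columns mix magnitudes, so it is recorded in run
metadata.

**Underflow.** p-values that underflow to zero are floored at the smallest
positive double before the log; the event is messaged.

**Cutoffs.** Fingerprint construction applies no p-value cutoff by default
(every co-occurring gene enters). The separate "highly relevant genes"
selection (`select_highly_relevant_genes`) uses a strict `p < cutoff`
comparison, configurable to `<=`.

## Matrix filters

Two filters are stated as properties of the final matrix, so they are
iterated to a fixed point: genes supported by fewer than two retained
diseases are dropped, and diseases with fewer than `min_genes` fingerprint
genes are dropped. A disease's gene count is measured on its raw
fingerprint (the natural reading of "genes in the fingerprint"), so the
disease filter fires once and only the gene filter can cascade; a
`count_post_filter` flag measures on the filtered matrix instead. Fewer
than three surviving diseases is an error — distances and clustering are
undefined there.

## Rank selection and the energy rule on flat spectra

`select_rank` returns the smallest rank whose leading singular values hold
an energy target (default 95%), with two energy conventions: the plain sum
of singular values (`mode = "sum"`, the literal reading of "eigenvalues'
summation") and the sum of squares (`mode = "sum_of_squares"`, the
variance-explained convention). Both are exposed because the phrase is
genuinely ambiguous for a rectangular matrix.

A finding worth knowing before trusting the 95% rule on your own data: on
the synthetic corpora the `-log10(p)` weight matrix has a *flat* singular
spectrum — 95% of the plain sum is not reached until rank 17 of 18, at
which point essentially no denoising has happened, and cluster recovery is
poor; truncating to any small rank (2–12) recovers the planted clusters
exactly. Whether 95% energy lands in the useful regime depends entirely on
the spectrum of the data at hand. The robust protocol, and the one the
evaluation module implements, is supervised: `tune()` searches ranks (an
explicit `r` grid and/or energy targets) and keeps the configuration
maximising F on the labelled training split, breaking ties toward the
smaller rank, then the smaller `k`.

The full-rank case is short-circuited in `run_pipeline`: reconstruction at
full rank is mathematically the identity, but its ~1e-16 floating-point
fuzz would break the *ties* among the exact zeros of the matrix, and
Spearman ranks are discontinuous in ties — a nominally identical matrix
produced visibly different distances. Skipping the identity reconstruction
makes "energy 1.0" equal the no-SVD pipeline bit for bit.

## Distance and clustering

Spearman distance is `1 - cor(ranks)` with average ranks on ties, in
`[0, 2]`; constant rows are an error naming the disease (upstream filters
prevent them in practice). Spectral clustering uses the standard
ingredients, each a documented default rather than a tuned constant:
Gaussian affinity `exp(-d^2 / (2 sigma^2))` with `sigma` the median
off-diagonal distance; symmetric normalised affinity `D^{-1/2} A D^{-1/2}`;
top-`k` eigenvector embedding, row-normalised, signs fixed; `kmeans` with
50 restarts under a caller-supplied seed (best within-cluster sum of
squares wins). Labels are canonicalised by first appearance, making results
deterministic given (distances, k, seed) and equivariant under permuting
the disease order.

**Why k is not identifiable from query-centric F.** Relatedness is
same-cluster membership with the query. At `k = 2` the partition
\{query's cluster\} vs \{everything else\} produces *exactly* the same
related set as a perfect `k = 3` recovery, so F on the labels cannot
distinguish them, and the tie-break (which prefers smaller `k`) would pick
the merged partition. When the number of disease families is itself of
interest, fix `k` from domain knowledge (as the planted-recovery analyses
here do, `k = 3`) or validate the partition with an unsupervised index; F
against a single query's labels is blind to structure away from the query.

## The synthetic world

`synthetic_spec()` states the world the tests run in: 3 clusters × 6
diseases, 40 signature ("pool") genes per cluster with 20% shared between
adjacent clusters (disease families overlap in reality), 200 background
genes, and per-article sampling where each gene mention comes from the
disease's pool with probability `q = 0.8`. The free parameters not fixed by
that statement were chosen once for realism at family scale and left alone:
30–60 annotated articles per disease (small disease literatures), 2–5 gene
mentions per article (typical of curated gene2pubmed coverage), and 20% of
non-query diseases hidden as "undefined" when labels are derived.

What the generator emulates: disease-specific gene enrichment, shared genes
across adjacent families, a common background vocabulary, expert labels
derived from true structure with a hidden subset. What it does not: MeSH
hierarchy depth, citation-count skew, publication dates, multi-disease
articles (each synthetic article carries exactly one disease), and
annotation errors. A green planted-recovery test therefore establishes that
the pipeline recovers block structure of this kind at this signal strength
— not that real MeSH/PubMed data carries such structure.

One behaviour of the enrichment statistic surfaced by this world is worth
stating: a background gene that co-occurs with a disease just once can be
*more* enriched than a typical pool gene, because its total count `K` is
tiny while pool genes accumulate `K` across their whole cluster. Planted
genes dominate in the sense that matters for the matrix — median weight
over all genes, counting absent genes as 0 — not necessarily among the
co-occurring genes alone.

## Evaluation protocol

Five experts vote related/non-related per disease; a disease is labelled
related on 4+ votes, non-related on 3+ opposite votes, undefined otherwise
(both rules can hold for no vote pattern; 3R/2N satisfies neither and is
undefined). Undefined diseases stay in the matrix and clustering — the
unsupervised stages see all diseases — but are excluded from confusion
counts; they are the prediction target (`predict_undefined`). F is F1, the
harmonic mean of precision and recall, with zero-division yielding 0 and a
warning.

## Numerical notes

- Hypergeometric mass is computed on the `lchoose` scale; out-of-support
  counts are an error, never a silent 0.
- The SVD sign convention (largest-magnitude entry of each left vector
  positive) plus canonical cluster labels make pipeline outputs
  byte-identical across reruns with the same seed.
- PMF normalisation, tail/enumeration agreement, the Eckart–Young error
  identity and the Spearman oracle are asserted exhaustively at small
  sizes in the test suite rather than assumed.

## Limitations

- Co-occurrence is not causation: a fingerprint records reporting bias as
  faithfully as biology.
- The universe restriction makes p-values conditional on the disease
  family; fingerprints are not comparable across differently chosen
  branches.
- No multiple-testing correction is applied inside fingerprints (by
  design); downstream consumers of single p-values should correct.
- Dense matrices cap practical scale at hundreds of diseases × tens of
  thousands of genes; this covers a MeSH branch comfortably but not all of
  MeSH.
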