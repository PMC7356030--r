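---
title: "Mining research trends from bibliographic exports: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining research trends from bibliographic exports: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`beemine` implements a complete literature-trend analysis for the honey
bee (*Apis mellifera*) research corpus: from a Scopus-style CSV export
to publication-growth curves, keyword-usage clustering of years,
co-occurrence networks, topic models, and a quantitative comparison of
the author's view (keywords) with the computer's view (topics). This
vignette explains each method, the tunable parameters with their
defaults, and the design decisions taken where more than one reasonable
choice existed.

## The data model

One publication record carries a year, a title, an abstract, and an
ordered list of author-assigned keywords. The keyword cell of a Scopus
export is split on `"; "` (a bare `";"` is tolerated, since real
exports vary). Rows whose year does not parse are skipped and counted
in a load report rather than aborting the read: exports are routinely
pre-curated, and robustness here is plumbing, not science. A
minimum-publications-per-year threshold (default 5) defines which years
enter the analysis at all; retained years need not be contiguous.

## Keyword normalization

Author keywords are free text, so a single concept appears under many
surface forms. Normalization proceeds in a fixed order:

1. **lowercase**;
2. **synonym mapping** — a curated two-column table (variant →
   canonical) applied by case-insensitive exact match;
3. **Porter stemming** of each whitespace token ("foraging" and
   "forage" both become "forag"; "colony" and "colonies" become
   "coloni");
4. **deduplication** within the record (set semantics).

Synonymization precedes stemming because curated maps are written
against surface forms, not stems. Stop-tokens inside multi-word
keywords are preserved ("division of labor" stems to "divis of labor")
so normalized keywords stay recognizable in tables and network plots.
The stemmer is a full implementation of the classic five-step Porter
algorithm; it reproduces the published test vocabulary exactly (see
the test suite). Fuzzy synonym matching is deliberately absent: maps
of this kind are curated by hand, and silent fuzzy hits would be
harder to audit than missed variants.

Whether keyword sets should be deduplicated after stemming is a
genuinely open choice; set semantics are used because all downstream
counts are publication-level (a keyword either occurs in a publication
or not), which makes within-record multiplicity meaningless.

## Publication growth

Annual counts are fitted with `y = a·e^{bx}` by ordinary least squares
of `ln(y)` on `x = year − origin`. The log-scale OLS fit (rather than
nonlinear least squares on the raw counts) matches how growth rates
and R² are conventionally reported for publication counts and is fully
deterministic. Zero-count years cannot enter a log fit and are dropped
with a warning rather than offset: any `ln(y + c)` shift would bias
the rate estimate. The doubling time is `ln(2)/b` (infinite for a flat
series); it is invariant to the choice of origin, which therefore
defaults to the first fitted year without loss. A rate of 0.087/yr
implies doubling every 7.97 years.

## Year clustering

Each retained year is represented by its keyword profile: the
proportion of that year's publications containing each selected
keyword. Using relative frequencies rather than raw counts prevents
the exponential growth of the corpus from dominating the distances.
The keyword set is built per the analysis convention: top 50 keywords
by publication count in each period, minus the search term itself
(which trivially tops both lists, leaving 49 per period), unioned
across periods.

Years are clustered agglomeratively on Euclidean distances with the
classical `ward.D` convention — the Lance–Williams update applied to
the distance matrix *as given*, without squaring. This convention is
chosen because it is what the analysis tradition in this literature
names explicitly; `ward.D2` (which squares internally) is available
behind a flag. The distance metric is not dictated by that tradition;
Euclidean is the natural companion of a variance-minimizing criterion,
and no standardization is applied because all features are already on
the common [0, 1] proportion scale.

Cluster stability is assessed by bootstrapping the clustered
observations (the years): columns are resampled with replacement,
re-clustered, and each original cluster records its maximal Jaccard
similarity with any bootstrap cluster, computed over the distinct
years present in the resample; the mean over replicates (default
1000) is the stability score. Values near 1 mean the cluster
reappears essentially intact in every resample.

Dominant keywords per cluster are scored by observed/expected
enrichment on the raw counts matrix: the expected count of keyword *i*
in year *j* under independence is `row_i · col_j / total`, the cell
ratio is observed/expected, and a cluster's score for a keyword is the
geometric mean over its years of (ratio + 0.001). The 0.001 shift is
applied to each ratio *before* the geometric mean: that placement is
the only one that stops a single zero cell from annihilating the
product while leaving nonzero ratios essentially untouched. The top
three keywords per cluster are reported. By construction the expected
matrix conserves the observed total exactly — a property the test
suite checks to 1e-9.

## Keyword co-occurrence networks

For keywords *i*, *j* over *N* publications, with `n_i` publications
containing *i* and `n_ij` containing both: the observed co-occurrence
probability is `O = n_ij / N` and the independence expectation is
`E = p_i · p_j` with `p_i = n_i / N`. All counts are publication-level
(a keyword counts once per publication). Normalizing O by N is
essential: only then are O and E commensurable probabilities and the
edge criterion dimensionally valid.

An edge is drawn iff `O > E` strictly, weighted `O − E`, so edge
weight reads directly as observed excess over chance; thicker edges
mean pairs that travel together more than independence predicts.
Isolated keywords remain in the node set. No multiple-testing
correction is applied to edges — the criterion is the raw comparison,
reproduced as-is; the network is descriptive, not inferential.

Global transitivity — 3 × triangles / connected triplets, weights
ignored, 0 when no triplet exists — summarizes how clique-like the
network is. Its sampling variability is quantified by bootstrapping
the *publications* (the sampling units) with the keyword node set held
fixed; re-selecting the top keywords inside each replicate would
conflate selection noise with network noise. The percentile interval
of the replicate transitivities (default 1000 replicates, 95%) is
reported.

## Topic modeling

Documents are the concatenation of title, keywords, and abstract:
lowercased, split on any non-alphanumeric character, with numeric
tokens (including decimal/exponent fragments), tokens shorter than two
characters, and standard English stop words removed, and the remainder
Porter-stemmed. Stop-word removal defaults to on: topic models fitted
to raw scientific prose are otherwise dominated by function words. A
configuration flag restores the literal no-stop-list reading.

LDA is fitted by collapsed Gibbs sampling (implemented in C++ for
speed) with symmetric priors: document-topic concentration `1/k`,
topic-word concentration 0.01. The sampler keeps a private RNG stream
keyed by its seed, so results are reproducible regardless of R's
global RNG state. Point estimates of the topic-word and document-topic
distributions are posterior means averaged over the final 20 sweeps of
a single chain (default 200 sweeps total) — within-chain averaging
avoids label switching while damping sweep-to-sweep noise.

The number of topics is chosen over a grid (default 20, 50, 70, 90,
110, 140) by the c_v coherence of each model: boolean sliding-window
co-occurrence counts (window width 110, the metric's defining value;
shorter documents contribute one window) yield NPMI vectors for each
topic's top words over the top-word set, and coherence is the mean
cosine similarity between each word's vector and the vector sum of the
set, averaged over topics. A top word absent from every window
receives a +1 smoothed count rather than raising an error. The default
downstream model uses k = 20 — grid selection in this kind of analysis
conventionally blends the coherence score with manual topic
inspection, so the chosen k is an explicit config value with the
coherence argmax as the automatic fallback.

Top words are ranked by the LDAvis relevance form
`λ·log p(w|t) + (1−λ)·log[p(w|t)/p(w)]` with λ = 1 by default (plain
within-topic probability); λ = 0 promotes topic-exclusive words.
Topic networks connect each topic's top five words into a clique;
cliques sharing a word merge through it, and edge weight counts the
topics in which a pair co-occurs.

Exact reproduction of any particular published topic set is not a
goal: LDA outcomes depend on sampler seeds and hyperparameters that
such analyses rarely report. The package instead guarantees
reproducibility under its own recorded seeds and demonstrates
recovery of planted topics on synthetic corpora.

## Comparing topic networks with keyword networks

Topic-network nodes are single stems; keyword-network nodes are often
multi-word stemmed keywords. Overlap therefore accepts exact matches
and contiguous substring matches in either direction, with a minimum
matched length of three characters so two-letter stems cannot match
promiscuously. A subject (topic-network) node counts as matched if any
reference node accepts it; a subject edge counts as matched if some
reference edge can be aligned endpoint-to-endpoint under the node
rules (cases: both exact / one exact one substring / both substring).
Fractions are over the subject network — the question asked is how
much of the computer's view the author-keyword view already contains.
Matching is greedy first-match and no one-to-one constraint is
enforced: a reference node may legitimately absorb several subject
stems ("forag" and "foraging behavior" both belong to the same
concept).

## The synthetic corpus generator

The generator emulates the structural features the pipeline is
sensitive to, with defaults fixed at the emulated study conditions:

- **years 1957–2017**, expected annual counts `6.29·e^{0.087(y−1957)}`
  (rounded), about 14,000 publications in total — the scale and growth
  of the real corpus;
- **a regime change in 1992**: era-level topic weights shift from
  behavior/taxonomy/pollination-heavy to health/genomics/toxicology-
  heavy, the kind of shift the year clustering is meant to detect;
- **8 planted topics** over bee-domain vocabularies (10 words each,
  1/rank word probabilities), with "bee" and "colony" shared across
  all topics the way ubiquitous terms are in real abstracts;
- **per-publication mixtures** drawn from a Dirichlet with
  concentration 0.8 over the era weights — documents lean on a few
  topics, as real abstracts do;
- **3–8 keywords per publication**, drawn from the mixture; with
  probability 0.1 a keyword is replaced by a registered lexical
  variant ("honey bee X", "X in apis mellifera") and the
  variant→canonical pair recorded in the emitted synonym map, making
  normalization exactly invertible — a ground-truth test that manual
  curation of real data can never provide;
- **the search-term keyword** "apis mellifera" attached to 90% of
  publications, so it dominates the keyword ranking exactly as a
  query term does in a real export;
- titles (5–12 tokens) and abstracts (40–80 tokens) sampled i.i.d.
  from the same mixtures, so keyword networks and topic networks are
  built over comparable vocabularies.

What the generator does **not** emulate: natural-language syntax,
citation structure, author metadata, multilingual text, and the slow
vocabulary drift of real fields within an era. Passing recovery tests
therefore demonstrates that the pipeline's statistics detect the
structures they claim to detect at realistic sample sizes — not that
any particular real-world corpus contains them.

## Numerical choices and degenerate inputs

- Ties in keyword rankings and top-word rankings break
  lexicographically, making every ranking deterministic.
- A fitted growth rate below 1e-12 in magnitude is reported as exactly
  0 (doubling time ∞), and an essentially perfect fit reports R² = 1.
- Transitivity of a graph with no connected triplet is 0, not NaN.
- Enrichment ratios where the expectation is 0 are set to 0.
- Empty documents keep their document-topic row at the prior mean.
- Percentile CIs warn below 100 bootstrap replicates.
- `O = E` exactly yields no edge (the criterion is strict).

## Problem sizes used in the shipped analyses

The package's own test corpora are scaled-down versions of the default
conditions chosen so that each recovery property is tested at adequate
statistical power: the regime-change recovery runs on 30-year corpora
of roughly 2,000 publications (about 30–130 per year, comparable to
the real corpus's mid-range years — at much smaller annual samples the
split is statistically invisible, which is a property of the data, not
the method), and LDA recovery on ~300 documents over three planted
topics. The acceptance script runs the full default conditions for
counts, trends, clustering, and networks, with the LDA grid reduced to
k ∈ {5, 10, 20} at 150 sweeps to keep the topic stage proportionate.

## Known limitations

- The O > E edge rule has no significance filtering; at small N many
  edges reflect sampling noise (the bootstrap CI on transitivity is
  the provided guard).
- c_v coherence is computed from the modeled corpus itself, not an
  external reference corpus.
- Substring matching can still produce semantically wrong matches at
  length ≥ 3 ("bee" matches "beekeeping" — intended — but also any
  stem containing "bee").
- The Gibbs sampler reports a single-chain posterior mean; multi-chain
  diagnostics are out of scope.
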