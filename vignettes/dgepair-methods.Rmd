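---
title: "Methods: two-library digital gene expression with the Audic-Claverie test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library digital gene expression with the Audic-Claverie test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgepair)
```

## The problem

Digital gene expression compares transcript abundance between conditions by
counting sequencing reads ("hit counts") per assembled contig, one library
per condition, rather than by hybridisation intensity. The motivating
application is a two-library EST survey of light-induced sporulation in the
plasmodium of *Physarum polycephalum*: one cDNA library from
sporulation-competent plasmodia (library D, 125,456 reads) and one from
plasmodia sampled six hours after a far-red light pulse (library L, 99,632
reads), assembled into 13,169 contigs with count data. The analysis
questions are: which transcripts changed abundance after photoinduction,
which functional (GO) categories separate the up- and downregulated sets,
and how the changed transcripts hang together in a prior-knowledge
interaction network.

## The conditional count test

For a single contig with `x` reads in a library of total size `n1`, the
probability of seeing `y` reads in a second library of size `n2`, under the
null hypothesis of equal underlying abundance, is

$$p(y \mid x) \;=\; \left(\frac{n_2}{n_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,\left(1+\frac{n_2}{n_1}\right)^{x+y+1}},$$

which is a negative binomial pmf with size $x+1$ and success probability
$n_1/(n_1+n_2)$ (a flat prior on the underlying rate, integrated out). The
test statistic for differential expression is the one-tailed lower sum
$P = \sum_{y'=0}^{y} p(y' \mid x)$, where the **conditioning side is the
library with the larger raw count** and `y` is the other library's count.
This convention — rather than a two-tailed or fixed-side variant — is the
one that reproduces the published per-transcript p-values of the motivating
study on both directions of change, and it is frozen by test fixtures.

Numerics:

* `ac_pmf()` evaluates the pmf through `lgamma` in log space;
  `ac_test()` accumulates the tail with log-sum-exp. The smallest published
  value in the motivating study is 5.4e-250, far below where a term-by-term
  product underflows; the log-space route is exact there, and results carry
  `log10_p` as the primary record (`p_value` underflows to 0 only below
  ~1e-308 while `log10_p` stays finite).
* An independent check against `pnbinom(..., log.p = TRUE)` (regularised
  incomplete beta) and against frozen 60-digit arbitrary-precision sums is
  part of the test suite; agreement is required to 1e-9 relative error in
  `log(p)` over a 201 x 201 count grid at three totals configurations.
* Fold-change ratios are computed from integer cross products
  `(hits_d * n_l) / (hits_l * n_d)`, so transcripts whose ratios are
  mathematically equal (say counts 18:1 and 90:5) are *exactly* tied in
  floating point; ranked tables then have well-defined tie groups.

Three deliberate conventions where the design was open:

* **Ties in raw counts** condition on the library with the larger total
  (library D when totals are equal too). A label-based rule ("always D")
  would break the exact library-swap symmetry
  `P(a,b; N1,N2) = P(b,a; N2,N1)` whenever the totals differ — at counts
  (1,1) with the study's totals the two label choices give 0.74 vs 0.26 —
  while the larger-total rule keeps the test exactly symmetric and agrees
  with every published row (none of which is a tie).
* **Direction** (up/down) is decided on relative frequencies
  `hits/total`, the quantity the scatter and ranking are defined on, while
  the conditioning side follows raw counts. With unequal totals the two can
  disagree (e.g. 5 vs 4 hits); both facts are kept and a summarising
  warning is emitted.
* **Significance** is the strict inequality `p < alpha`, default
  `alpha = 0.05`, with no multiple-testing adjustment of the per-contig
  p-values — matching the reporting convention of the motivating study.

### Operating characteristics

Because the tail side is chosen from the data (the smaller count's lower
tail), the procedure is *not* uniformly conservative: the exact null
rejection rate at nominal 0.05, computed by enumerating the binomial split
of a contig's total between the two libraries, reaches 0.07–0.15 for
moderate per-contig totals, and the simulated null significant fraction at
the study's scale sits slightly above 0.05 (the acceptance property suite
measures this; two of its nominal bounds fail for exactly this reason and
are documented as such). Consequently the significant set at unadjusted
`alpha = 0.05` is a *screening* set: when ~80% of contigs are null, the
empirical false discovery rate within it is large even when power on
well-expressed changes is essentially 1. The ranked top-N tables mitigate
this in practice by sorting on fold-change ratio among annotated
significant transcripts, which pushes marginal calls far down the list.

## Quantitation and summaries

Relative frequency is `hits / library total` per library; all totals are
the **full** library totals even when a subset of contigs is analysed
(`count_table(totals = )` override), since the test depends on `n1, n2`
and not on subset sums. `summarize_libraries()` counts detection (>= 1
hit), "at least 5 hits" (>= 5), "at most 5 in both" (<= 5 in both — the
two phrases deliberately overlap at exactly 5), singletons, and the strict
relative-frequency comparison between libraries. `hit_histogram()` bins
detected contigs into adjacent upper ranges (a count falls in the first
bin whose upper bound >= it, so 2 hits land in the 2–5 bin); the default
uppers 1, 5, 10, 50, 100, 500, 1000, Inf anchor the first two bins to the
published histogram and continue in round numbers.

## GO-term overrepresentation

`go_enrichment()` compares the upregulated (test) against the
downregulated (reference) contig sets. Only contigs carrying at least one
GO term participate; each contig counts once per term; terms are tested
exactly as annotated, with no ontology-ancestor propagation (the upstream
annotation pipelines this consumes already emit expanded term lists, and
no propagation rule is part of the contract). Each term's 2x2 table is
tested with the standard two-tailed Fisher exact convention — the sum of
hypergeometric point probabilities not exceeding the observed one (with
the usual 1e-7 relative slack), delegated to `stats::fisher.test()` and
oracle-checked against exhaustive enumeration — followed by
Benjamini–Hochberg step-up adjustment (`stats::p.adjust`), reporting terms
with adjusted value strictly below 0.01. BH was chosen as the standard
step-up FDR procedure of this workflow family; note BH adjustment is not
idempotent on re-application, so adjusted values are never fed back in.

## Ranked reporting and networks

`top_ranked()` filters to one direction, significance, and (by default)
non-empty ortholog accession, sorts by ratio descending with ties broken
by p-value then contig id, and truncates to N (default 20). The ratio —
not the p-value — is the ranking key, matching the "most up-/downregulated"
reading of the published tables; published tie orders follow no stated rule
and are not reproduced. `high_abundance()` selects contigs whose relative
frequency strictly exceeds 0.005 in either library; `scatter_export()` and
`de_partition()` provide the scatter table and the global
significant/up/down split.

`build_network()` implements guilt-by-association assembly only:
interaction *prediction* is out of scope, and prior edges (accession pair,
probability in [0,1]) are consumed as an input table, undirected and
deduplicated at read time keeping the maximum probability. Selected
contigs (significant, top-N, or high-abundance) with accessions become
nodes labelled by expression direction; a prior edge between two selected
accessions becomes an edge, flagged significant when its probability
strictly exceeds 0.9. Export formats are SIF and GraphML (via igraph).

## The synthetic generator

`simulate_libraries()` stands in for the study's raw data. It emulates:

* fixed library totals (125,456 and 99,632) by **multinomial** sampling —
  not Poisson — because the test conditions on totals;
* the heavy-tailed abundance profile via log-normal baseline weights
  (`abundance_log_sd = 1.8`), which reproduces the published regime where
  roughly two thirds of contigs have <= 5 hits in both libraries and a few
  reach hundreds;
* true fold changes on a configurable fraction of contigs
  (defaults `pi_up = 0.12`, `pi_down = 0.09`, anchored to the study's
  observed 1,623 up / 1,149 down of 13,169), with folded-normal log-fold
  magnitudes (mean 1, sd 0.5) applied to the L-side weights and
  renormalised;
* GO annotation on a configurable fraction of contigs (default 0.19,
  the study's GO-annotated fraction among contigs with counts), ~4 terms
  per annotated contig from a 50-term vocabulary, with one planted
  "cell death"-style term whose assignment probability is multiplied by 4
  on upregulated contigs;
* full determinism: one seeded RNG stream in a fixed draw order, with the
  caller's RNG state restored afterwards.

It does **not** emulate: assembly artifacts or chimeric contigs,
sequencing error, within-library biological overdispersion beyond the
multinomial, correlated annotation structure (GO DAG hierarchy), or
normalised-library contigs without counts. Passing recovery tests
therefore demonstrate correctness of the statistical machinery under the
model's assumptions, not robustness to real-data artifacts.

Problem sizes in the test and acceptance suites are the package's chosen
working points: full-scale runs at m = 13,169 for partition properties,
m = 10,000 for the null calibration, m = 2,000 with 100+100 planted
changes for enrichment recovery, and 10-seed repetitions for all
stochastic claims.

## Known limitations

* The per-contig p-values are not multiplicity-adjusted (by design, to
  match the published convention); the significant set's empirical FDR is
  correspondingly high in null-dominated settings — see *Operating
  characteristics*.
* The test is mildly anti-conservative for moderate totals, as measured
  above; users wanting strict type-I control at `alpha` should halve the
  threshold or treat the output as ranking evidence.
* Published ratio columns in the motivating study were computed through
  rounded intermediates and differ from full-precision ratios by ~0.1–0.5%;
  this package computes ratios from totals and does not chase printed
  digits (one published extreme p-value, 5.40e-250, likewise carries a
  third-digit rounding error; the exact value of the stated formula is
  5.3779e-250).
* Enrichment assumes term assignments are independent across contigs;
  planted-term recovery rates quantify behaviour only under that
  assumption.
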