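---
title: "Predicting phage hosts from shared genomic k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage hosts from shared genomic k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r}
library(phagehost)
```

## The model

Bacteriophages that infect the same bacterial host exchange and retain
genetic material far more often than phages with different hosts, so two
phages sharing long exact substrings are likely to share a host. phagehost
turns this observation into a classifier: the genome of a phage with an
*unknown* host is decomposed into all overlapping k-mers (k = 16 by
default, step 1), these are matched against a reference database of phages
with *annotated* hosts, and the hosts of the best-matching references are
transferred to the query.

Reference genomes contribute k-mers from both the forward strand and the
reverse complement, so matches are found regardless of which strand a
shared region was sequenced from; queries are decomposed on the forward
strand only, which is sufficient because the reference side already covers
both orientations. Windows containing an ambiguous base (`N`) are skipped.

```{r}
extract_kmers("ACGTACGT", k = 4)
reverse_complement("AAGGT")
```

## Similarity measures

For a query $u$ against reference $i$ the package computes five measures.
With $S_i$ the number of distinct shared k-mers, $l_{u,i}$ the reference's
distinct k-mer count over both strands, $L_{u,tot}$ the sum of $l_{u,i}$
over the database, $q_u$ the query's distinct k-mer count,
$q_{matched,i}$ the multiplicity-weighted count of query k-mers found in
the reference, $l_i$ the reference's total (multiplicity-weighted)
both-strand k-mer count, and a pseudocount $\eta = 0.001$:

* **score** $S_i$, and its expectation under a null in which hits
  distribute across references proportionally to their size,
  $E_i = N_{hits} \, l_{u,i} / L_{u,tot}$ where
  $N_{hits} = \sum_i S_i$;
* **z-score** $z_i = (S_i - E_i)/\sqrt{S_i + E_i + \eta}$, a
  Poisson-style standardization, converted to a two-sided normal p-value
  and Bonferroni-corrected across the $N_{ref}$ references
  ($p_{corr} = \min(1, p \cdot N_{ref})$); only hits with
  $p_{corr} < 0.05$ are retained;
* **frac_q** $= S_i/(q_u+\eta)$ — how much of the query matched;
* **frac_d** $= S_i/(l_{u,i}+\eta)$ — how much of the reference matched
  (between 0.5 and 1 for identical pairs, because the reference's
  reverse-complement k-mers may or may not coincide with the forward
  ones);
* **coverage** $= 2\,q_{matched,i}/(l_i+\eta)$, the measure used for
  ranking; it can exceed 1 when query k-mers match repeated reference
  k-mers.

Two formula details are deliberate choices. The z-score uses a square
root in the denominator — without it the statistic degenerates to a
bounded constant for large counts and the 0.05 filter could never fire.
The coverage denominator is the *total* (multiplicity-inclusive)
both-strand k-mer count, not the distinct count, which is what makes the
"can exceed 1" behavior meaningful.

```{r}
corpus <- simulate_phage_corpus(n_hosts = 3, phages_per_host = 2,
                                genome_length = 4000, seed = 1)
db <- build_host_db(corpus, k = 16)
db
hits <- score_query(corpus[1, c("id", "sequence")], db)
dplyr::select(hits, ref_id, host_genus, S, z, p_corr, frac_q, coverage)
```

Hits are always sorted by coverage (descending), then score, then
reference id, so every downstream rule is deterministic.

## From hits to a host call

Four selection criteria turn a significant-hit list into one host:

1. host of the top-coverage hit;
2. majority vote among the ten highest-coverage hits;
3. majority vote among hits with coverage at least $f \cdot$ (top
   coverage), default $f = 0.8$; $f = 1$ reduces to criterion 1 and
   $f = 0$ votes over all significant hits;
4. per hit, $(\text{coverage}/\text{coverage}_1)^\alpha$ summed per host,
   the host with the largest sum winning; $\alpha = 6$ is the deployed
   default, and large $\alpha$ approaches criterion 1.

Criterion 4 is the default because it weights every significant hit while
still letting near-top hits dominate. Each prediction also carries a
confidence tier from the top hit's coverage: `poorly-reliable` (≤ 0.1),
`reliable` (> 0.1), `highly-reliable` (> 0.8), or `no-prediction` when no
hit survives the significance filter.

```{r}
predict_host(corpus[1:2, c("id", "sequence")], db)
```

## Redundancy clustering and host-balanced partitions

Evaluating on randomly split data overstates accuracy when near-identical
genomes land on both sides of the split. `hobohm_cluster()` applies the
Hobohm-1 algorithm: genomes are visited in a seeded random order, each one
is compared (as a query, by `frac_q`) against the representatives found so
far, and it either joins the first-ranked representative exceeding the
0.7 similarity threshold or founds a new cluster.
`partition_clusters()` then deals cluster representatives round-robin into
partitions, stratified by host so that each partition sees every host, and
cluster members always follow their representative — no cluster ever
straddles a partition boundary.

```{r}
cl <- hobohm_cluster(corpus, shuffle_seed = 1)
table(is_seed = cl$is_seed)
pt <- partition_clusters(cl, corpus, n_parts = 3)
table(pt$partition)
```

## Evaluation

`cross_validate()` predicts each partition's genomes from a database built
on all the others and reports accuracy over predicted queries (a query
with no significant hit abstains rather than guessing).
`bootstrap_accuracy()` resamples the per-query records to attach a
standard error. `tune_selection_parameter()` runs a nested grid search
for $f$ or $\alpha$ — for each held-out partition it tunes on inner
cross-validation over the remaining partitions only, so the reported
optimum is never chosen on the data it is evaluated on — and reports, per
outer set, the best value together with the contiguous range of values
within 99% of the best accuracy. `truncation_experiment()` re-predicts
queries from genome prefixes (or random windows) of decreasing length,
probing how much sequence the method actually needs.

```{r}
cv <- cross_validate(corpus, pt, level = "genus")
cv
```

`tidy()` and `glance()` methods expose per-query records and one-row
summaries as tibbles, and `autoplot()` methods draw the
accuracy-by-coverage-bin and grid-search profiles.

## The synthetic corpus generator

Real phage corpora cannot ship with the package, so
`simulate_phage_corpus()` plants the causal structure the method relies
on: each host gets a private pool of signature segments, and each phage
genome interleaves (mutated copies of) segments from its host's pool with
genome-specific random filler. `signature_fraction` sets how much of each
genome is signature, `snp_rate` mutates signature copies, and
`mosaic_swap_rate` occasionally borrows a segment from a foreign pool,
mimicking horizontal transfer. At the default settings (five hosts, six
phages each, 40 kb genomes, 60% signature, 0.5% SNPs) within-host pairs
share large exact k-mer sets while between-host pairs share essentially
none, and — importantly for evaluation — within-host similarity stays
below the Hobohm threshold, so families spread across partitions instead
of collapsing into single clusters. The generator is deliberately
unrealistic in every other respect (no gene structure, uniform base
composition); it exists to make signal recovery, null behavior and
dose-response testable offline.

## Numerical and engineering notes

* All k-mer matching runs on keyed `data.table` joins over an inverted
  k-mer index; profiles are computed once per genome and reused across
  cross-validation folds.
* Expectation products are computed in double precision (counts of
  40 kb genomes overflow 32-bit integers when multiplied).
* Every ordering in the package uses radix (C-locale) sorting, and
  `data.table` runs single-threaded, so results are identical across
  platforms and locales.
* Databases serialize to a versioned plain-text format with a canonical
  record order; saving the same database twice is byte-identical.
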