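# phagehost

Predict the bacterial host of a bacteriophage from its genome sequence.

Phages that infect the same bacterial host exchange and retain genetic
material far more often than phages with different hosts. `phagehost`
exploits this: a query genome is decomposed into all overlapping 16-mers
(step 1), matched against a reference database of phages with annotated
hosts (references contribute both strands; queries the forward strand
only), and the hosts of the best-matching references are transferred to
the query. Everything needed to *evaluate* such a predictor honestly is
included: Hobohm-1 redundancy clustering with host-balanced partitioning,
cross-validation with bootstrap errors, nested parameter tuning, a
genome-truncation robustness experiment, and a synthetic corpus generator
with planted host signatures so the whole pipeline is testable offline.

## Method in brief

For a query *u* against reference *i*, with η = 0.001 a pseudocount:

| measure | definition | meaning |
|---|---|---|
| `S` | distinct shared k-mers | raw similarity score |
| `E` | `N_hits · lu_i / Lu_tot` | expected `S` under a size-proportional null |
| `z` | `(S − E) / sqrt(S + E + η)` | standardized score; two-sided p, Bonferroni-corrected over references; hits with `p_corr ≥ 0.05` are discarded |
| `frac_q` | `S / (qu + η)` | fraction of the query matched |
| `frac_d` | `S / (lu_i + η)` | fraction of the reference matched |
| `coverage` | `2·q_matched / (l_i + η)` | ranking measure; multiplicity-weighted, may exceed 1 |

Here `lu_i` / `l_i` are the reference's distinct / total both-strand
k-mer counts, `qu` the query's distinct k-mer count, and `q_matched` the
multiplicity-weighted count of query k-mers found in the reference.

Significant hits, sorted by coverage, are reduced to one host call by one
of four criteria; the default (criterion 4) sums
`(coverage/coverage₁)^α` per host with α = 6. Each call carries a
confidence tier from the top hit's coverage: ≤ 0.1 `poorly-reliable`,
> 0.1 `reliable`, > 0.8 `highly-reliable`, no surviving hit →
`no-prediction`.

## Worked example

```r
library(phagehost)

# a corpus with planted per-host signatures (3 hosts x 4 phages, 20 kb)
corpus <- simulate_phage_corpus(n_hosts = 3, phages_per_host = 4,
                                genome_length = 20000, seed = 42)
db <- build_host_db(corpus, k = 16)
db
#> <host_db> genus-level, k=16: 12 reference phages, 479623 unique k-mers (3 host genera)

hits <- score_query(corpus[1, c("id", "sequence")], db)
dplyr::select(hits, ref_id, host_genus, S, z, p_corr, coverage, significant)
#> # A tibble: 9 × 7
#>   ref_id               host_genus      S     z p_corr  coverage significant
#>   <chr>                <chr>       <int> <dbl>  <dbl>     <dbl> <lgl>
#> 1 phage_Hostgenus01_01 Hostgenus01 19985 102.       0 1.000     TRUE
#> 2 phage_Hostgenus01_04 Hostgenus01 10123  49.7      0 0.507     TRUE
#> 3 phage_Hostgenus01_03 Hostgenus01 10033  49.1      0 0.502     TRUE
#> 4 phage_Hostgenus01_02 Hostgenus01  8666  39.6      0 0.434     TRUE
#> 5 phage_Hostgenus02_01 Hostgenus02  1298 -38.9      0 0.0649    TRUE
#> 6 phage_Hostgenus02_02 Hostgenus02     1 -64.6      0 0.0000500 TRUE
#> 7 phage_Hostgenus02_03 Hostgenus02     1 -64.6      0 0.0000500 TRUE
#> 8 phage_Hostgenus02_04 Hostgenus02     1 -64.6      0 0.0000500 TRUE
#> 9 phage_Hostgenus03_04 Hostgenus03     1 -64.6      0 0.0000500 TRUE

predict_host(corpus[1, c("id", "sequence")], db)
#> # A tibble: 1 × 8
#>   query_id    level host  criterion_score top_coverage best_p_corr n_significant
#>   <chr>       <chr> <chr>           <dbl>        <dbl>       <dbl>         <int>
#> 1 phage_Host… genus Host…            1.04        1.000           0             9
#> # ℹ 1 more variable: tier <chr>
```

(The single-shared-k-mer hits with large *negative* z survive the
two-sided significance test by matching far *less* than expected; the
coverage weighting of criterion 4 makes them irrelevant to the call.)

Evaluation never splits near-identical genomes across train and test:

```r
cl <- hobohm_cluster(corpus, shuffle_seed = 1)   # Hobohm-1, frac_q > 0.7 joins
pt <- partition_clusters(cl, corpus, n_parts = 4)
cv <- cross_validate(corpus, pt, level = "genus")
cv
#> <phagehost_cv> criterion 4, genus level: accuracy 1.0000 over 12/12 predicted queries
glance(cv)
#> # A tibble: 1 × 6
#>   level criterion n_queries n_predicted prop_predicted accuracy
#>   <chr>     <int>     <int>       <int>          <dbl>    <dbl>
#> 1 genus         4        12          12              1        1
```

`tidy()` exposes per-query records, `bootstrap_accuracy()` attaches a
standard error, `tune_selection_parameter()` runs a nested grid search
for `f` (criterion 3) or `alpha` (criterion 4),
`truncation_experiment()` probes how much genome the method needs, and
`autoplot()` methods draw the standard diagnostics. See the vignette
(`vignettes/kmer-host-prediction.Rmd`) for the full methods description.

## Command line

`inst/cli/phagehost.R` wraps the package for shell pipelines
(subcommands `build-db`, `predict`, `cluster`, `evaluate`, `simulate`;
every run writes a JSON manifest of its parameters):

```sh
Rscript inst/cli/phagehost.R simulate --hosts 3 --per-host 4 --length 20000 --seed 42 --out fixtures
Rscript inst/cli/phagehost.R build-db --in fixtures/corpus.fasta --hosts fixtures/hosts.tsv --out db
Rscript inst/cli/phagehost.R predict --db db.genus.txt --query fixtures/corpus.fasta --out predictions.tsv
```

Inputs are multi-record FASTA (genomes) and TSV with columns `id`,
`host_genus`, `host_species` (hosts); host names of the form
`"<Genus> sp. <code>"` carry no species information and are collapsed to
genus. Reports are TSV with fixed column order; databases serialize to a
versioned plain-text format that round-trips byte-identically.

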