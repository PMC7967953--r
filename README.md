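# granora

Over-representation analysis (ORA) with explicit attention to **pathway
database granularity**.

ORA is the workhorse of transcriptomics, metabolomics, and microbiome
interpretation: given the set of significantly changed genes, find the
pathways they concentrate in. The score is the exact one-tailed
hypergeometric probability that a pathway of size *n*, in a universe of *N*
pathway-assigned genes, captures *k* or more of the *K* significant genes:

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$$

What practitioners rarely account for is that this score depends as much on
the *annotation* as on the data. Fine-grained databases (EcoCyc-style:
small, single-process pathways) and coarse ones (KEGG-map-style "mosaic"
pathways that union many processes) assign the same biological signal
p-values that differ by up to **nine orders of magnitude** — far more than
the one-to-two orders moved by multiple-testing corrections. Large mosaic
pathways can even reach significance from scattered single-gene hits when
no individual process is perturbed at all.

`granora` is for bioinformaticians who use or evaluate enrichment tools and
want that sensitivity quantified rather than assumed. It provides:

* an exact log-space hypergeometric engine (`enrichment_pvalue()`,
  `enrich()`) with Bonferroni and Benjamini-Hochberg corrections, accurate
  to six significant figures down past 1e-300;
* paired fine/coarse comparisons that regenerate the published
  EcoCyc-vs-KEGG p-value tables cell by cell and verify them at printed
  precision (`build_comparison()`, `verify_reference_tables()`);
* a **critical subset size** solver — the minimum number of a pathway's
  genes that must be significant to clear a fixed adjusted threshold —
  profiled across sample sizes (`critical_subset_size()`,
  `profile_database()`, `ratio_profiles()`);
* analogous-pathway matching across two databases by significant gene-set
  overlap, with deterministic smallest-combined-size tie-breaking
  (`match_pathways()`);
* a seeded synthetic generator of dual-granularity annotations with known
  fine-to-coarse containment, so every stage is testable without downloads
  (`generate_fine_db()`, `coarsen_db()`, `sample_significant_genes()`);
* an end-to-end driver (`run_full_study()`).

Everything takes and returns tibbles, pipes cleanly, and has
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Build a fine annotation at the published scale (354 pathways, sizes 3–13),
coarsen it into ~3.5× larger mosaics, perturb one fine pathway, and score
the same gene set against both annotations:

```r
library(granora)

fine   <- generate_fine_db(synthetic_scenario(), seed = 1)
coarse <- coarsen_db(fine, grouping_factor = 3.5, seed = 2)
sig    <- sample_significant_genes(fine, "F010", within_fraction = 0.8,
                                   background_count = 20, seed = 3)

head(enrich(fine, sig), 3)
#>   pathway_id name               k     n     K     N   p_raw p_bonferroni    p_bh
#> 1 F010       fine pathway F010  4     5    24  2792 2.09e-8   0.00000740 7.40e-6
#> 2 F302       fine pathway F302  1     4    24  2792 3.40e-2   1          1
#> 3 F059       fine pathway F059  1     5    24  2792 4.23e-2   1          1

head(enrich(coarse, sig), 3)
#>   pathway_id name                 k     n     K     N   p_raw p_bonferroni
#> 1 C095       coarse pathway C095  4    21    24  2792 2.28e-5      0.00231
#> 2 C054       coarse pathway C054  2    24    24  2792 1.74e-2      1
#> 3 C056       coarse pathway C056  2    29    24  2792 2.50e-2      1
```

Both annotations rank the truly perturbed signal first (C095 is the mosaic
containing F010), but the fine pathway scores `2.1e-8` where its
3.5×-larger mosaic manages only `2.3e-5` — three orders of magnitude lost
to granularity on identical input.

The published EcoCyc/KEGG comparison is built in. For the cysteine pair
(3-gene fine pathway vs 34-gene coarse pathway, totals 1096/1686,
multiplicities 354/119):

```r
library(dplyr)
build_comparison() |> filter(label == "cysteine")
#>   label        k  p_fine_raw p_fine_corrected p_coarse_raw p_coarse_corrected log10_ratio
#> 1 cysteine     3     4.57e-9          1.62e-6      7.50e-6           8.93e-4        3.22
#> 2 cysteine     2     5.00e-6          1.77e-3      3.95e-4           4.70e-2        1.90
#> 3 cysteine     1     2.74e-3          9.69e-1      2.02e-2           1              0.868

glance(verify_reference_tables())
#>   n_cells n_mismatch all_match
#> 1     204          3 FALSE
```

201 of the 204 published cells reproduce exactly at printed precision; the
three flagged cells differ from the exact statistic by one unit in the last
printed digit and are discussed, with their exact recomputed values, in the
methods vignette (`vignettes/pathway-granularity.Rmd`).

The full study — table verification, synthetic generation, critical-subset
ratio profiling, matching recovery, and the mosaic false-positive
demonstration — runs in a few seconds:

```r
run_full_study(seed = 1)
#> <granora_study>
#>   published tables : 204 cells, 3 mismatch(es)
#>   headline log10(coarse/fine) : 10.22
#>   matching precision/recall   : 1.000 / 1.000
#>   median critical-subset ratio: 1.62
#>   mosaic false positive       : coarse significant = TRUE, any fine = FALSE
```

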