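---
title: "Pathway granularity and over-representation statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway granularity and over-representation statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granora)
library(dplyr)
```

## The statistical model

Over-representation analysis (ORA) treats a significant-gene set as a draw
without replacement from a gene universe. For a pathway of size $n$ in a
universe of $N$ pathway-assigned genes, with $K$ significant genes of which
$k$ fall in the pathway, the null probability mass is hypergeometric,

$$P(X = k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},$$

and the enrichment score is the one-tailed probability of observing $k$
*or more* pathway genes by chance,

$$P(X \ge k) = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

`enrichment_pvalue()` implements exactly this upper tail: one-tailed, no
mid-p adjustment, no depletion test. Those variants exist in the literature,
but the point of this package is the comparison of the *same* simple exact
statistic across annotations, so the simplest analytically tractable test is
the right instrument.

Two conventions matter and are deliberate:

* **The universe is the pathway-assigned genes.** $N$ counts genes assigned
  to at least one pathway, not the genome. For E. coli this is 1096 genes
  under EcoCyc and 1686 under KEGG. `enrich(universe = "declared")` switches
  to a caller-declared universe when a different reference is wanted.
* **$K$ is restricted to the universe.** Significant genes outside the
  universe are dropped with a warning and $K$ reduced, since the null model
  only draws from the universe.

### Why granularity moves p-values

If two pathways cover the same $k$ significant genes in the same universe,
the smaller pathway always attains the smaller tail probability, and the gap
widens as $k$ grows. Fine-grained annotations (EcoCyc-style: small,
single-process pathways, typically 3–13 genes) therefore systematically
out-score coarse annotations (KEGG-map-style "mosaic" pathways that union
many processes, routinely 3–8 times larger) on identical input. The package
treats this not as a theorem to state but as a property to test: the suite
checks strict size monotonicity on $10^4$ randomized parameter tuples with
$N \le 5000$, and checks the engine itself against exhaustive enumeration of
every significant-gene subset for every parameter combination with
$N \le 12$.

At the published scale the effect is large: for the pyrimidine pair (fine
pathway of 13 genes vs a 51-gene mosaic), thirteen significant genes give
raw p-values of $2.03\times10^{-30}$ vs $3.49\times10^{-21}$ — nine orders
of magnitude from the annotation choice alone, several times more than the
two orders contributed by multiple-testing correction.

```{r headline}
build_comparison() |>
  filter(label == "pyrimidine", k == 13) |>
  select(k, p_fine_raw, p_coarse_raw, log10_ratio)
```

## Reference-table verification

`granularity_pairs()` ships the six published fine/coarse pair definitions
(sizes 3/34, 12/18, 4/17, 9/16, 10/78, 13/51; totals 1096/1686;
multiplicities 354/119) as data, and `verify_reference_tables()` recomputes
all 204 published cells and compares at printed precision — two significant
figures for the four amino-acid tables, three for the purine/pyrimidine
tables. Bit-exact string matching is meaningless across typography, so the
verifier rounds the computed value to the cell's printed figures.

Two points about this verification deserve documentation:

* The published tables print the coarse-side Bonferroni column from the
  native KEGG total ($N = 1686$, $m = 119$), although the surrounding prose
  describes an apples-to-apples column at $N = 1096$. We verify against the
  printed numbers; both readings are computable because $N$ and $m$ are
  plain parameters.
* Under strict printed-precision comparison, 201 of 204 cells reproduce.
  Three cells (the selenocysteine pair at $k=4$, coarse raw and corrected;
  the valine pair at $k=1$, coarse raw) differ from the exact statistic by
  one unit in the last printed digit, and the selenocysteine pair's raw and
  corrected cells are mutually inconsistent at printed precision
  ($7.2\times10^{-9} \times 119 = 8.6\times10^{-7}$, printed
  $8.5\times10^{-7}$). The verifier reports them as mismatches rather than
  special-casing them; the test suite pins all three together with their
  exact recomputed values.

```{r verify}
glance(verify_reference_tables())
```

The correction multiplicity $m$ defaults to the pathway count of the
database under test (354 and 119 for the shipped pair specs), never an
ontology-class count: class hierarchies inflate $m$ without adding tests.

## The critical-subset inverse problem

A p-value is a property of an outcome; study design needs the inverse: at a
fixed adjusted threshold, how many of a pathway's genes must be significant
before the pathway is called enriched? `critical_subset_size()` finds the
minimum $k$ with $P(X \ge k) \le$ threshold by binary search (the tail is
strictly decreasing in $k$), returning a typed `NA` sentinel — never 0 or
$n+1$ — when even complete coverage cannot reach the threshold, so
downstream medians can exclude unreachable cells explicitly.

The threshold is built as `rank * alpha / m`. For a minimum-detectable
computation the rank of the eventual hit among the $m$ tests is unknown, and
the step-up FDR procedure always charges the smallest p-value the full
multiplicity, so the rank-1 threshold $\alpha/m$ (identical to the
Bonferroni bound) is the defensible default; `rank` is exposed for
sensitivity analysis. The default sample-size grid is 50 to 500 significant
genes in steps of 50 — the grid has no canonical step, and 50 resolves the
ratio curves without inflating runtime.

Because the computation needs only pathway *sizes*, `profile_pathway_sizes()`
accepts annotations distributed as two-column id/size tables (a common
supplementary-material format) without memberships.

## Analogous-pathway matching

To compare granularity between two databases pathway-by-pathway, analogous
pathways are defined as unique, significantly overlapping gene sets. The
overlap statistic is the same hypergeometric tail with
$k = |A \cap B|$, $K = |A|$, $n = |B|$, $N$ the joint universe (the union of
both databases' assigned genes). No canonical choice of test, universe, or
cutoff exists for "highly significant overlap", so all three are parameters:
the default applies a Bonferroni correction over all candidate pairs at
$\alpha = 0.05$ (conservative, appropriate for real annotations), while
ground-truth recovery tests on synthetic nested databases use the
uncorrected tail at $10^{-4}$ — with a few hundred disjoint pathways the
containment p-values sit around $10^{-5}$–$10^{-9}$, and the corrected
default would discard genuine containments of the smallest (3-gene)
pathways. Note the cutoff is scale-dependent: the same containment in a
40-pathway toy universe has $p \sim 10^{-3}$.

One-to-one resolution is a greedy pass over a total order: ascending overlap
p-value rounded to 2 significant figures (so "comparable" p-values tie,
mirroring printed precision), then ascending combined gene count — two
candidates explaining the same overlap equally well resolve to the leaner
pair — then lexicographic ids. The total order makes matching deterministic
and independent of input row order, which the suite asserts.

Recovery against a known fine-to-coarse mapping is scored as: precision =
fraction of accepted pairs present in the truth; recall = fraction of true
pairs recovered (uniqueness off), or fraction of coarse pathways matched to
one of their true members (uniqueness on, where one pair per coarse pathway
is the ceiling).

## The synthetic generator

`generate_fine_db()` + `coarsen_db()` build the dual-granularity structure
the analysis assumes: many small fine pathways, and coarse mosaics formed as
unions of randomly grouped fine pathways, with the containment retained as
ground truth. Defaults mirror the published fine-annotation scale: 354
pathways, sizes uniform on 3–13, and a grouping factor of 3.5 so the
coarse/fine mean-size ratio matches the ~3.5× ratio observed between
matched KEGG and EcoCyc gene sets (the coarse side then has ~101 pathways,
near KEGG's 119).

One sizing decision is worth spelling out. Real EcoCyc assigns ~1096 genes
across 354 pathways, which is only possible because real pathways share
genes: 354 pathways of mean size 8 represent ~2800 assignments. The
generator's default keeps pathways *disjoint* (`overlap_noise = 0`,
universe = exactly the assigned genes, N ≈ 2830), because disjointness is
what makes containment ground truth, critical-ratio pairing, and the mosaic
construction exactly interpretable. Setting `universe_size = 1096` with
`overlap_noise ≈ 0.7` reproduces the re-use density of the real annotation;
the generator refuses infeasible packings by name rather than silently
overlapping. The `m` values and pathway sizes — the quantities that drive
every statistic here — are at the published scale either way.

Perturbations (`sample_significant_genes()`) mark a fraction of chosen
pathways' genes significant plus uniform background. `mosaic_gene_set()`
builds the diagnostic failure case: one gene from *each* process inside a
single mosaic. Run through `enrich()` on both annotations, the mosaic
pathway is called enriched while no fine process comes close — the
false-positive mode that makes large mosaic pathways hard to interpret:

```{r mosaic}
st <- run_full_study(seed = 1)
st$mosaic
```

All generation is seed-deterministic through `withr::local_seed()`; no
global RNG state leaks.

### What the synthetic data does and does not emulate

It reproduces the *structural* contrast (size ratio, nesting, pathway
counts) and therefore supports the qualitative claims: critical-subset
ratios above 1, fine pathways reaching significance at higher representation
rates, perfect containment recovery, the mosaic effect. It does not emulate
real annotations' gene sharing across sibling pathways, their heavy-tailed
size distributions, cross-database identifier mismatches, or the actual
EcoCyc/KEGG memberships — so passing synthetic tests says the *method*
behaves as the model predicts, not that any particular real pathway will
show a particular ratio. Published per-pathway figures (the 69 matched
pairs, the "2× fewer genes on average" summary) require the real membership
files, which this package accepts as inputs but does not bundle. For the
same reason the package reports both the median-of-ratios and the
per-pair-median summaries — the published averaging procedure is not fully
specified — without privileging either.

## Numerical choices

* **Log-space tails.** Each mass is computed as
  `exp(lchoose(K,i) + lchoose(N-K,n-i) - lchoose(N,n))`; the tail sum
  factors out the largest log term, preserving ≥ 6 significant figures down
  to ~$10^{-300}$. The suite cross-checks against `stats::phyper` and
  against exact enumeration.
* **Exact endpoints.** $P(X \ge k) = 1$ exactly (not `1 - tiny`) whenever
  $k$ is at or below the support lower bound $\max(0, n+K-N)$; sums are
  capped at 1.
* **Near-1 comparisons.** When an upper tail is within double-precision
  rounding of 1, strict inequalities between tails are verified in tests on
  the complementary (lower-tail) side in log space, where the information
  lives.
* **Degenerate inputs.** Empty gene sets, duplicate pathway ids, genes
  outside a declared universe, comment-only gene lists, infeasible packings,
  and empty significant sets all raise typed errors naming the violated
  constraint; within-pathway duplicate genes deduplicate with a warning.
* **Identifiers** are opaque, case-sensitive strings. A trim/uppercase
  normalizer exists but is off by default; reconciling namespaces between
  two databases is the caller's responsibility.

## Problem sizes used by the test suite

The suite runs the monotonicity property at $10^4$ tuples ($N \le 5000$),
the enumeration oracle over all ~1.6k tuples with $N \le 12$, the solver
cross-check at $10^3$ tuples, and the full synthetic study at the default
354-pathway scale with the 50–500 grid — sizes chosen so every claim is
exercised at the scale it is made about, with the whole suite completing in
well under a minute.

## Known limitations

* The package compares annotations; it does not judge which annotation is
  biologically *correct* for a given organism.
* No GSEA-style rank statistics, permutation nulls, or depletion tests.
* No live retrieval from KEGG/BioCyc; databases arrive as GMT files or size
  tables.
* The matching stage assumes a shared gene namespace; it will not cross-map
  identifiers.
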