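---
title: "trailkit: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trailkit: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailkit)
```

trailkit identifies potentially deregulated biological processes — and the
molecular factors that may drive them — in bulk, time-series, and
single-cell gene expression data. This vignette explains the statistics the
package implements, the assumptions behind them, the tunable parameters
that matter, and the design decisions taken where several defensible
options existed. Everything shown here is computed by the package at
rendering time; the companion test suite checks the same properties
against independent brute-force oracles.

## The data model

All analyses speak a small shared vocabulary:

* a **score list** — a tibble with columns `gene`, `score`, always sorted
  by descending score with a lexicographic gene tie-break. Scores mirror
  the degree of deregulation (log fold changes, t statistics, rank-sum z).
* a **gene set collection** (`gene_sets()`, `read_gmt()`) — named
  biological categories, e.g. pathways or ontology terms.
* an **expression matrix** (`expr_mat()`) — genes × samples or genes ×
  cells, with a column-metadata tibble (group labels, sample ids,
  time-points).
* a **directed gene network** (`gene_network()`) — an edge tibble used by
  the path search.

Gene identifiers are opaque, case-insensitive tokens, upper-cased on
entry. No organism-specific identifier mapping is attempted; users who
need cross-database mapping should apply it before import. The same rule
holds for proteins and miRNAs — any token works.

## Differential scoring

Three two-group scores are provided; each produces a full score list.

* `score_log_fold_change()` — `log2((mean_A + c) / (mean_B + c))` with
  pseudocount `c >= 0`. The default `c = 1` is the usual stabilizer for
  counts; for pre-normalized data without zero means, `c = 0` gives the
  plain log ratio.
* `score_t_test()` — the Welch (unequal-variance) t statistic. Genes with
  zero variance in both groups are scored 0 and reported, rather than
  producing infinities.
* `score_wilcoxon()` — the rank-sum z with tie correction and no
  continuity correction, positive when group A ranks higher. The normal
  approximation is used even at small n; the tests verify it stays within
  0.15 of exhaustive enumeration at 4 + 4 samples.

`transform_abs()` folds the sign away when only the magnitude of change
matters, and `select_deregulated()` implements the three filter rules
used to cut a score list down to a deregulated gene set: `top_k`,
`upper_lower_percent` (rank-based cutoffs, `ceiling(q/100 * n)` genes per
tail, not interpolated quantiles), and `abs_threshold`. Ties are always
broken by gene token so results are bit-reproducible.

Count-model methods (DESeq2-style shrinkage estimators and friends) are
deliberately out of scope: they are mature external tools, and trailkit's
score interface accepts any externally computed score list via
`read_scores_tsv()`.

## Enrichment statistics

`run_enrichment()` drives two families over a gene set collection.

**Over-representation analysis (ORA).** For a preselected gene set of
size $n$ inside a reference universe of size $N$, a category with $K$
members in the reference and $k$ in the test set is scored with exact
hypergeometric tails: enrichment $P(X \ge k)$, depletion $P(X \le k)$,
two-sided $\min(1,\, 2\min(\text{tails}))$. The doubled-tail two-sided
rule was chosen for monotonicity and simplicity over minimum-likelihood
alternatives. Reported direction follows the sign of $k - nK/N$.

**Functional class scoring (FCS).** Four statistics operate on the full
sorted score list:

* `gsea_es()` / `gsea_pvalue()` — the running-sum enrichment score. At
  each rank the sum gains $|s_i|^p / N_R$ on category members
  ($N_R = \sum_{hits} |s_i|^p$) and loses $1/(N - N_h)$ otherwise; the ES
  is the maximum deviation from zero, signed. $p = 0$ recovers the
  unweighted Kolmogorov–Smirnov-like statistic, $p = 1$ (default) weights
  hits by their scores. When all hit weights are zero the unweighted step
  is used as a fallback.
* `fcs_wilcoxon()` — rank-sum z of member versus non-member scores.
* `fcs_ttest()` — Welch t of member versus non-member scores.
* `fcs_mean()` — mean or median member score with a membership-permutation
  p-value.

Because the input is a single ranked list (not a sample-level matrix),
the permutation null for the running sum is **gene-label permutation**:
category membership is reassigned to random ranks, keeping the member
count. Sample-level (phenotype) permutation is a deliberate non-goal. The
p-value uses the add-one estimator
$(1 + \#\{|ES_b| \ge |ES|\}) / (B + 1)$, which can never report zero and
is bounded below by $1/(B+1)$. Defaults: $B = 1000$, seed 42, both
recorded in outputs.

Categories are intersected with the reference (ORA) or the ranked list
(FCS) before testing, and the recorded `category_size` is the size
*after* intersection; categories outside `[min_size, max_size]` (defaults
3–700, configurable) are skipped with a reason. Adjusted p-values
(`adjust_pvalues()`: Benjamini–Hochberg step-up by default, Bonferroni
and Benjamini–Yekutieli available) are computed across tested categories
only.

One numerical subtlety: when the positive and negative running-sum
deviations tie in magnitude, floating-point accumulation order would
decide the sign of the ES. The extremum is therefore chosen as the first
position whose |running sum| comes within 1e-12 of the maximum, making
the statistic stable across arithmetically equivalent implementations.

```{r running-sum, fig.width = 6, fig.height = 3}
ranked <- tibble::tibble(gene = paste0("g", 1:40), score = seq(3, -3, length.out = 40))
plot_running_sum(ranked, paste0("g", c(1:6, 12, 18)), weight_p = 1)
```

## Deregulated paths in directed networks

`best_paths()` searches a directed gene network for, at every length
$\ell = 2, \dots, k_{max}$, the node-simple path whose gene set is most
enriched near the top of a ranked score list. The path score is the
unweighted running-sum maximum (enrichment direction only); finding
down-deregulated cascades is done by negating or abs-transforming the
score list upstream. Only simple paths are considered — revisiting a gene
has no biological reading here.

The search engine is an exact depth-bounded depth-first enumeration of
simple paths, with the score computed in closed form from the member
rank set. Because the running-sum score of a path depends on its whole
rank set, a best-predecessor dynamic program is not exact; exhaustive
enumeration is, and at the intended scale (curated pathway topologies,
path lengths up to ~8) it is fast. Correctness is defined — and tested —
by agreement with an independent brute-force oracle on random DAGs.

Significance per length comes from permuting the rank positions of an
equal-sized gene set ($B$ draws, add-one estimator), i.e. the null keeps
the network fixed and randomizes where the path's genes sit in the
ranking; network rewiring nulls answer a different question. P-values are
BH-adjusted across the returned lengths. Score ties between paths are
broken by the lexicographically smallest node sequence.

## Regulator prioritization

`reggae_analyze()` ranks transcriptional regulators by their influence on
a sorted gene list (typically the most upregulated genes of a contrast),
combining three ingredients: experimentally validated regulator–target
interactions, the expression matrix, and the list order. For each
regulator with at least `min_targets` (default 5) targets in the list,
the statistic is a **correlation-weighted running sum**: hit increments
proportional to $|r|$ (Pearson, regulator row versus target row), miss
decrements uniform, statistic the signed maximum deviation. Membership
permutation with weight reshuffling gives the p-value; BH adjustment runs
across tested regulators. The activator/repressor call follows the sign
of the *signed* mean regulator–target correlation (`split_roles()`
partitions the significant regulators accordingly; a regulator with mean
correlation exactly zero or incomputable is "undetermined" and belongs to
neither list).

This statistic is a re-derivation from the method's described
ingredients, not a bit-level port of any existing tool; its contract is
defined by the package's oracle tests and the planted-fixture recovery
study (a causal regulator with generating correlation 0.8 to its targets
is recovered at rank 1 with the activator role in ≥ 95 of 100 seeded
runs). Pearson rather than Spearman correlation is the default simply
because the fixtures and the intended pseudo-bulk inputs are
approximately log-scale linear; it is an explicit parameter of the
interpretation, not of the API (apply rank-transforms upstream if
preferred).

## The single-cell workflow

`qc_filter()` → `normalize_cells()` → `top_n_genes()` → `per_cell_ora()`
→ `group_activity_test()` mirrors the per-cell enrichment strategy for
droplet-style counts:

1. **QC**: keep cells whose detected-gene count lies in
   `[min_genes, max_genes]` (defaults 200 and 6000) and whose total
   counts do not exceed `max_total`; genes left undetected everywhere are
   dropped. The bounds are deliberately "adjustable first, opinionated
   second" — they are data-set properties, not constants of the method.
2. **Normalization**: counts-per-10k per cell, then `log(1 + x)`. CP10k
   is one conventional choice among several; `scale_factor = 1e6` gives
   CPM. The pre-log scaled column sums equal the scale factor to 1e-6.
3. **Top-N selection**: each cell's `n` most highly expressed detected
   genes (default 500, the conventional order of magnitude for
   transcriptome-wide data; scale it with the panel size). Boundary ties
   break lexicographically; cells with fewer detected genes use them all
   and are flagged.
4. **Per-cell ORA**: enrichment-sided hypergeometric test of each cell's
   top-N set against each surviving category, with the full filtered gene
   universe as the reference (the least assuming background choice). The
   per-cell **activity** is $-\log_{10} p$; raw p-values are retained.
   The category filter is computed once, so every cell is tested against
   the identical category list.
5. **Group testing**: per category and group, one-vs-rest rank-sum z on
   the activity scores, two-sided p with the direction (`more_active` /
   `less_active`) from the sign, BH across all (category, group) pairs.
   One-vs-rest matches the three-group clinical design the synthetic
   fixture emulates; two-sided testing with a reported direction was
   preferred over a one-sided "more active" test so depletion is equally
   visible.

`pseudo_bulk()` sums counts per sample for downstream bulk-style
analyses (e.g. scoring + regulator prioritization); total counts are
conserved exactly. Clustering and 2-D embeddings are consumed as
optional metadata columns, never computed — those belong to dedicated
single-cell toolkits.

## Time-series analysis

`change_score()` ranks genes by the aggregated absolute expression
difference between consecutive time-points, $\sum_t |x_{t+1} - x_t|$ —
absolute rather than signed differences, so oscillating genes score as
changing (the two readings of "expression difference" differ exactly
there; the absolute reading was chosen because a transient spike is a
change worth clustering). `filter_changing()` keeps the strongest
changers by threshold or top fraction. `cluster_timecourses()` is a
seeded k-medoids: medoids start as k distinct random genes and alternate
nearest-medoid assignment with within-cluster medoid updates until the
assignment stabilizes (at most 100 iterations); the objective — the sum
of distances to assigned medoids — is non-increasing by construction and
asserted at run time. K-medoids was preferred over k-means so both
supported distances (z-normalized Euclidean and 1 − Pearson) share one
engine; constant courses have undefined Pearson distance and are
assigned by a zero-distance convention and flagged. `k` is a user choice;
no automatic model selection is attempted. `cluster_ora()` then runs an
ORA per cluster, adjusting within cluster.

## Synthetic data with known truth

Every pipeline has a seeded generator whose defaults are the package's
reference study conditions, chosen once:

* `make_bulk()` — log-normal intensities (log2 scale, baseline uniform in
  4–10, Gaussian noise sd 1), 10 + 10 samples, 50 planted genes shifted
  +2 log2 units in group A. Effect 2 at sd 1 and n = 10 per group gives
  comfortably but not trivially separable planted genes.
* `make_genesets()` — 50 uniform decoy sets (10–60 genes) plus one
  planted set: the planted genes padded by 10% random members, so its
  overlap with the truth is ≥ 80% by construction.
* `make_network()` — an Erdős–Rényi DAG over a random topological order
  with the known most-deregulated path injected through the top-ranked
  genes.
* `make_single_cell()` — negative-binomial counts (dispersion 2,
  log-normal gene means averaging 2 counts/cell), three groups named
  after the clinical design it emulates (ARDS / NonVent / Healthy), 120
  cells per group over 1200 genes, a 40-gene program up-shifted 4-fold in
  one group, two sample labels per group for pseudo-bulk, and 3
  deliberately low-coverage cells per group (2% coverage) that must fail
  QC. 1200 genes × 360 cells is a deliberately desk-scale rendering of a
  transcriptome-wide data set; the *structure* (three groups, planted
  program, QC failures) is what the tests exercise, and the package's
  per-cell defaults (top 500 genes) should be scaled down in proportion —
  the verification studies use top-150.
* `make_rti()` — 20 regulators, one causal whose targets are the planted
  bulk genes and whose expression row is generated at correlation 0.8
  with its targets' mean profile; decoys get random targets and
  independent expression.
* `make_timecourses()` — monotone-up, monotone-down, and transient-peak
  shapes (amplitude 4) plus flat noise genes (sd 0.3) over six
  time-points.

What these fixtures *do not* emulate is worth stating: no batch effects,
no ambient RNA or doublets, no library-size confounding between groups,
no correlated gene-gene noise, and decoy categories are exchangeable with
the null by construction. Passing the recovery studies therefore shows
the statistics and their implementation behave correctly under the
claimed model — not that any particular real data set satisfies that
model.

## Verification strategy and problem sizes

The test suite pins every statistic to an independent oracle: exhaustive
enumeration for hypergeometric tails (all test-set draws up to N = 12)
and rank statistics, a brute per-rank evaluation for the running sum
(500 random cases at 1e-12), the step-up definition for BH (1000 random
vectors), exhaustive simple-path enumeration for the path search (100
random DAGs of up to 12 nodes), and Monte-Carlo calibration for the
permutation nulls (200 random categories at B = 1000, mean p within
0.47–0.53). The recovery studies run 100 seeded replicates of each
planted fixture at the reference conditions above. These sizes were
chosen so the full verification runs in a few minutes on one core while
keeping the Monte-Carlo standard errors well inside the asserted bands.
`scripts/acceptance.R` recomputes all of these quantities from scratch
against the installed package and writes them as JSON.

## Known limitations

* Normal approximations for rank statistics are used at all sizes; exact
  rank tests are not implemented (error ≤ 0.15 at n = 4 + 4, shrinking
  fast with n).
* The path search is exponential in the worst case; it is intended for
  curated pathway graphs, not genome-scale interactomes.
* Permutation p-values are granular at 1/(B+1); increase `n_perm` when
  adjusting many hypotheses at strict thresholds.
* The regulator statistic treats targets symmetrically; sign-aware
  (activating vs repressing edge) enrichment is future work.
* Paired designs, batch correction, and count-model normalization beyond
  per-cell scaling are out of scope by design.
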