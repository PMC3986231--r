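---
title: "Methods: meta-analysis of D. mccartyi transcriptome compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of D. mccartyi transcriptome compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhcmeta)
```

*Dehalococcoides mccartyi* couples growth to reductive dehalogenation of
halogenated pollutants. Its transcriptome compendia — absolute-intensity
microarrays collected over electron-donor/acceptor regimes, corrinoid
(B12) supply, growth phases, and community contexts — can be pooled and
read against the organism's pan-genome-scale metabolic network. This
vignette documents the methods implemented here, their numerical
conventions, and the design of the synthetic generators used for testing.
All study-specific constants live in one place, `pipeline_config()`.

## Probe assignment by three-way consensus

Community arrays carry probes from many organisms. A probe is attributed to
*D. mccartyi* by consensus of three alignment analyses — nucleotide
database, protein database, and composite community genome — each
represented as a tabular hit table (`read_hit_table()`).

- **Best hit** per query: highest bitscore; ties broken by higher percent
  identity, then lexicographically smallest subject id (`best_hit()`). The
  tie-break makes the selection order-independent.
- **Verdict** per analysis: *pass* iff the best hit's taxon is
  *D. mccartyi* **and** its identity **strictly** exceeds the cut-off
  (85 nucleotide / 95 amino acid / 95 composite). A nucleotide hit at
  exactly 85.0 fails: the rule is `> threshold`, chosen so the two
  verdict regions partition the identity scale without double counting.
- **Consensus** (`consensus_assign()`): in the default `"majority"` mode a
  probe is assigned when *no* analysis that produced a hit contradicts it
  and at least two affirm it — probes may lack protein hits by design
  (e.g. intergenic shotgun probes), and a missing hit is not treated as
  contradiction. `"strict"` mode requires all three analyses to pass.

## On/off transcription calls

Absolute intensities are binarized per sample: *on* iff
`intensity > threshold`. Equality is *off* — the threshold itself is read
as "not distinguishable from background". Each gene is then summarized
across all samples as `on_in_all`, `on_in_some`, or `off_in_all`
(`call_on_off()`); the three classes partition the gene set by
construction, and raising the threshold can only move genes away from
`on_in_all` (both properties are tested).

Two threshold strategies exist (`select_threshold()`):

- `"fixed"`: the dataset-specific configured value (800 for pure-culture
  strain 195 arrays, 100 for community KB-1 arrays, whose *D. mccartyi*
  signal is diluted).
- `"distribution"`: the antimode (minimum) between the two modes of the
  pooled log10-intensity histogram, using 50 bins and 3-point mean
  smoothing. Guards make the rule refuse rather than guess: a mode must
  reach at least 5% of the dominant peak, the two modes may not be
  adjacent bins, and the valley must fall below half of the smaller mode;
  otherwise the function errors and advises the fixed strategy.

`cross_tabulate()` crosses the per-gene summary with a proteomic evidence
list (3 x 2 counts), reporting evidence genes absent from the array as an
attribute rather than silently dropping them.

## Normalization and ordination

`row_zscore()` computes `(x - mean(x)) / sd(x)` per gene, with the
sample standard deviation (`n-1` denominator; `"n"` available). Degenerate
(constant) rows cannot be standardized; they are flagged and written as
zeros rather than NA so downstream matrix consumers need no special cases.
`pca_samples()` runs principal component analysis over samples
(genes as variables, centered, not scaled) — its role here is diagnostic:
replicate arrays should group by condition.

## QT clustering under Spearman distance

Expression profiles are compared by
`d(i, j) = 1 - rho_s(i, j)`, Spearman's rank correlation with average
ranks for ties (`spearman_distance()`), ranging over [0, 2]. Constant
profiles have no defined rank correlation and receive the maximal
distance 2, keeping the partition total. At least 3 samples are required.

`qt_clustering()` implements quality-threshold clustering:

1. For every remaining gene as seed, grow a candidate by repeatedly adding
   the gene whose inclusion gives the smallest **new diameter** (maximum
   pairwise distance among members), while the diameter stays within
   `max_diameter`. Ties go to the earliest gene in input order.
2. Extract the largest candidate (ties: earliest seed in input order),
   remove its members, repeat.
3. Stop when the largest candidate falls below `min_size`; the rest stay
   unclustered.

Both tie-break rules are deterministic on purpose: together with the
seed-deterministic generators they make entire pipeline runs byte-identical.
The study settings `max_diameter = 0.06`, `min_size = 7` mean every gene
pair inside a cluster has `rho_s >= 0.94`. Within-cluster display order
comes from average-linkage (UPGMA) agglomeration on the same distance
(`hierarchical_order()`, `cluster_newick()`); average linkage matches the
diameter-style, whole-cluster reading of the QT criterion better than
single linkage would.

## Enrichment

For a cluster of size `n` containing `k` genes of a category with `K`
members in a universe of `N` genes, `enrich_clusters()` computes the
hypergeometric upper tail `P(X >= k)` via the numerically stable
distribution routine (`hypergeom_upper_tail()`, evaluated as
`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`), which is exact to
~1e-14 against rational enumeration. A cluster is *enriched* if any
category reaches `p <= alpha` (raw p-values, study convention); a
Benjamini–Hochberg column is emitted for reference but does not drive the
flag. The default universe is `"clustered_genes"` — the question asked is
"which functions co-occur within the co-expressed fraction", not "is this
cluster unusual relative to the whole genome"; `"all_genes"` is available
when the latter is wanted.

## Comparative operon prediction

For adjacent genes on one contig, the intergenic distance is
`start(downstream) - end(upstream) - 1` under 1-based inclusive
coordinates (negative for overlaps). The naive Bayes model
(`train_operon_model()`) combines:

- a distance likelihood, histogrammed in 10-bp bins on [-50, 600) with
  open terminal bins, Laplace (+1) smoothed;
- per-reference conserved-adjacency ("barcode") likelihoods over
  `R` reference genomes (27 in the study setting), Bernoulli with
  Laplace-smoothed class-conditional conservation probabilities.

Training needs no experimental labels: same-strand pairs conserved in at
least `R/2` references serve as operonic seeds, opposite-strand pairs as
boundary proxies, and the prior is the fraction of adjacent pairs on the
same strand. The posterior is evaluated in log space (`pair_posterior()`);
opposite-strand pairs get posterior 0 by definition. A pair is
co-transcribed iff it is same-strand with posterior `>= 0.5` (equality
included: at even odds the evidence favors neither class and the study
convention reads the pair as operonic), and operons are maximal runs of
consecutive positive pairs (`call_operons()`), so
`sum(operon length - 1)` always equals the positive-pair count.

## Synthetic generators

The generators produce study-shaped data with recorded ground truth; their
defaults are fixed design choices of this package, not fitted values.

`simulate_expression()` (defaults: 1560 genes, 9 conditions x 3
replicates): every gene draws a stable base level from a between-gene
log-normal law (off component centred at 50, on component at 2000, on
either side of the 800 threshold) plus smaller within-gene per-sample
noise. Planted clusters share a standardized latent profile built from a
condition-level signal plus a per-sample component, entering each member
through the Gaussian rank-correlation identity `r = 2 sin(pi rho_s / 6)`
with a small overshoot for sampling noise, so realized pairwise Spearman
correlations match the target. Because realization is stochastic, the
generator records both *intended* and *realized* on/off classes; tests
always score against realized truth.

`simulate_genome()` (defaults: 1500 genes, 27 references) lays out
transcription units with `1 + Geometric` sizes (mean 2.4), within-unit
distances `N(25, 15^2)` truncated at -20, boundary distances
`N(150, 80^2)` truncated at 1, strand flips at unit boundaries with
probability 0.5, and Bernoulli conservation barcodes (0.75 operonic /
0.15 boundary). This plants roughly 58% operonic adjacent pairs and ~80%
of genes in multigene units.

`simulate_hit_tables()` fabricates the three analysis hit tables with
known probe origins, decoy lower-bitscore rows to exercise best-hit
selection, and deliberately missing protein hits for a fraction of probes.

What the generators do **not** emulate: probe-level intensity bias,
cross-hybridization, genome rearrangement hot spots (HPRs), horizontal
transfer of *rdhA* regions, or correlated conservation between reference
genomes (barcode columns are independent given the class).

## Limitations

- On/off calling assumes comparable absolute-intensity scales within a
  dataset; no between-array normalization is applied beyond the design of
  the compendium itself.
- QT clustering is O(n^3)-ish in the worst case; at the study scale
  (~1600 genes, 27 samples) a full run takes on the order of a second in
  pure R, which is why no compiled code is used.
- The naive Bayes operon model assumes conditional independence of the
  distance and each reference's conservation bit.
- Enrichment uses raw p-values for the enriched flag by study convention;
  consult the emitted BH column when scanning many clusters.

## End-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 7)
res <- run_pipeline(cfg, stage = "all", outdir = "out")
```

The output directory receives TSVs for every stage plus `manifest.tsv`
(configuration echo, package version, md5 of every output; no timestamps),
and reruns with the same configuration are byte-identical.
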