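---
title: "Scoring cellular senescence and deriving response thresholds with senindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cellular senescence and deriving response thresholds with senindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senindex)
```

## The problem

Cellular senescence — a stable, stress-induced cell-cycle arrest with a
secretory phenotype — accumulates in the immune compartment of cancer
patients and is a candidate determinant of immune-checkpoint-inhibitor
failure. Given single-cell RNA-seq of immune cells from treated patients
labelled responder (R) or non-responder (NR), the question is whether the
burden of senescent-like T cells predicts response, and at what threshold.

`senindex` implements that analysis as a reusable pipeline: per-cell
directional signature scoring, quality control, removal of cells in a
distinct dysfunctional (exhausted) state that mimics low senescence, a
per-patient senescence index, and a grid search over percentile threshold
pairs scored by ROC AUC with a Youden-index cutoff.

## Per-cell rank-based scoring

Scores are computed per cell from expression ranks, the construction used
by rank-based single-cell gene-set scorers. Within a cell, genes are ranked
by decreasing expression with average ties; ranks beyond `max_rank` are set
to `max_rank + 1` so the long tail of undetected genes cannot dominate.
For a direction with $n$ matched genes and capped ranks $r_i$,

$$U = \sum_i r_i - \frac{n(n+1)}{2}, \qquad s = 1 - \frac{U}{n \cdot
\text{max\_rank}},$$

the Mann–Whitney statistic of the signature genes against the rest. $s$ is
1 when the signature occupies the top ranks and near 0 beyond the cap. A
directional signature combines as $s_\text{up} - s_\text{down} \in [-1,1]$;
we deliberately do not floor at zero because depletion of genes expected to
be down-regulated is part of the senescence signal (a `floor_at_zero`
option exists). Rank scores are invariant to any strictly monotone
transform of a cell's profile, so counts, TPM and log-TPM give identical
scores; this is the property that lets one score datasets shipped in
different units side by side.

`max_rank` defaults to 1500, a conventional choice that roughly matches the
number of confidently detected genes in a typical scRNA-seq cell; raising
it dilutes the score with drop-out noise, lowering it saturates the score
for broadly expressed signatures. Scoring is stratified by cell type
(`score_by_celltype`) so ranks never mix, e.g., T cells with B cells.

## Quality control

Three filters reproduce a standard immune scRNA-seq QC sequence, each with
strict inequalities at its printed boundary:

* **Detected genes** — cells with fewer than 1000 genes at nonzero
  expression are dropped (a cell with exactly 1000 is kept).
* **Mitochondrial genes** — genes whose symbol starts with `MT-`
  (case-insensitive, so mouse `mt-` matches) are removed from the gene
  axis. We read this as dropping the genes, not filtering cells by
  mitochondrial fraction: no fraction threshold exists in the protocol.
* **Housekeeping expression** — after conversion to log2(TPM + 1), cells
  whose mean expression over a housekeeping list is not strictly above 2.5
  are dropped; on the linear TPM scale the equivalent threshold is
  $2^{2.5}-1 \approx 4.66$. A compact default list
  (`default_housekeeping()`) ships with the package; any curated list can
  be supplied.

Without per-gene lengths, TPM degrades to counts-per-million (each cell
scaled to $10^6$ total) with a warning; droplet protocols have no length
normalization, so this is the appropriate surrogate there.

## Dysfunction filtering

Exhausted T cells score low on senescence and high on exhaustion markers
and would otherwise inflate the low-senescence denominator of the index.
Two mechanisms remove them, mirroring how such cells present in real data:

* when they form their own cluster, `exclude_clusters` drops any cluster
  whose median senescence falls below the cell type's 25th percentile
  while its median exhaustion exceeds the 75th;
* when they do not separate, `joint_percentile_filter` removes cells below
  the 20th percentile of senescence **and** above the 80th of exhaustion
  within their cell type (expected removal under independence: 4%).

The quantiles for the cluster rule are not fixed by the protocol we
implement; medians against global quartiles are the package's choice and
both are parameters. Percentiles throughout the package use the
linear-interpolation convention (R's type 7) for cross-backend
determinism, and the joint filter runs per cell type because every other
quantity in the pipeline is computed per cell type. Scoring happens before
any exclusion: the exclusions consume the scores, so the reverse order is
not computable.

## The per-patient index

Within a cell type, cells are classified against two percentile cutoffs of
the pooled score distribution (all patients together): high if score ≥ the
upper cutoff, low if ≤ the lower. Pooling is essential — per-patient
percentiles would fix every patient's high/low fractions by construction
and destroy discrimination. For a patient with $H$ high, $L$ low and $T$
total cells,

$$\text{index} = \frac{H/T + ps}{L/T + ps}, \qquad ps = 0.01,$$

a pseudocount that keeps the ratio finite when $L = 0$; the index is 1 when
neither class is present and 101 when all cells are high. Patients
contribute only where they have strictly more than 10 cells of the cell
type — fewer cells make $H/T$ too granular to rank reliably.

## Threshold optimization

The upper cutoff ranges over the 55th–95th percentiles and the lower over
the 5th–45th, step 5: a 9 × 9 = 81-pair grid. Each pair yields per-patient
indices whose R-vs-NR discrimination is summarized by ROC AUC with NR as
the positive class (higher senescence index ⇒ non-response). The optimum is
the argmax-AUC pair; ties break toward the pair retaining the larger
fraction of classified cells ($\sum(H+L)/\sum T$), then toward more
included patients. We chose a tie-break rather than a hard retention
constraint because no retention threshold is part of the protocol and a
tie-break preserves the argmax rule. The Youden cutoff
($\max(\text{sens}+\text{spec}-1)$ over midpoints between adjacent index
values) is derived at the selected pair; its ties prefer higher
specificity, then the smaller cutoff.

The best-of-81 AUC is an in-sample maximum and carries selection optimism:
on null cohorts (no R/NR difference) the mean best AUC sits near 0.6, not
0.5, for 48-patient cohorts. `grid_result$n_pairs` records the multiplicity
so users can calibrate against it; no cross-validated AUC is offered, and
`auc_bootstrap_ci` brackets only sampling noise of the selected pair, not
the selection itself.

## Comparative statistics

* **Wilcoxon rank-sum** (`wilcoxon_rank_sum`) compares R and NR score
  distributions per cell type, exact for tie-free combined n ≤ 12, with BH
  adjustment reported alongside nominal p-values
  (`compare_groups_by_celltype`) since multiple cell types are tested.
* **Timepoint trends** (`timepoint_trend`) regress the mean score per
  timepoint on time — the aging-atlas question of whether enrichment grows
  linearly with age.
* **Segmented regression** (`segmented_fit`) models induction time courses
  with two slopes joined at a breakpoint, fitted by exhaustive SSE
  minimization over a dense candidate grid spanning the interior design
  points. The exhaustive grid is deterministic and exactly checkable
  against brute force, which we preferred over iterative breakpoint
  updating; fits improving on a single line by less than 1% are flagged
  unidentifiable.
* **Pre-ranked GSEA** (`preranked_gsea`) tests a signature's up- and
  down-genes separately against a per-gene ranking metric — typically the
  Pearson correlation of expression with age (`rank_by_correlation`). The
  null uses random same-size gene sets rather than phenotype permutation
  because age series of a handful of donors cannot support the latter;
  weight 1 (classic weighted KS) is the default, weight 0 exposes the
  analytic limits (top-$k$ set → ES = 1) used in tests.
* **Shapiro–Wilk gate** (`shapiro_gate`) routes two-group comparisons to
  t or Wilcoxon at α = 0.05.

## Functional-module clustering

`reduce_and_cluster` decomposes a signature into functional modules from a
binary gene × term matrix: PCA keeps the smallest leading set of components
explaining > 90% of variance, k-means (seeded restarts) scans a k range
with the silhouette argmax choosing k — the elbow curve is returned for
inspection rather than folded into an automatic rule, since no tie rule
between the two criteria exists — and a Ward dendrogram accompanies the
partition. Genes touching several clusters' terms are assigned where their
cumulative enrichment score is highest; the score source defaults to the
per-association scores when given, else association counts, with ties to
the larger cluster. Term retrieval from GO/KEGG is out of scope: databases
drift, so the computation starts at the user-supplied matrix.

## The synthetic cohort generator

`generate_scores` and `generate_expression` produce cohorts with known
truth so every accuracy claim in the test suite is computable. Defaults
encode the study conditions the pipeline targets: 48 patients, responder
fraction 18/48, per-patient cell counts NB(mean 120, size 5) — a realistic
per-cell-type yield after QC for cohorts of this kind. Scores draw from
Beta distributions (support [0,1], matching the scoring contract):
baseline mean 0.15, concentration 12; senescent cells are shifted up by
`score_effect`, exhausted cells get exhaustion mean 0.6 and slightly
depressed senescence, and by default the exhausted subset is drawn from
the non-senescent pool (mutual exclusivity). Expression mode plants a
signature into NB counts (lognormal baseline means, meanlog 1.5 so
ordinary cells clear the 1000-detected-genes filter while planted
low-complexity cells fall far below it; housekeeping genes constitutive at
mean 50).

Presets fix the effect sizes once: `strong` (senescent fraction 0.45 in NR
vs 0.15 in R, shift 0.25), `weak` (0.30 vs 0.20, shift 0.15), `null`
(0.25 in both).

What the generator does **not** emulate: batch effects, ambient RNA,
doublets, cell-type misannotation, patient-level covariates (age, sex,
stage), or correlated gene modules beyond the planted signature. Passing
the recovery benchmarks therefore shows the pipeline's statistical
machinery is correct under its own assumptions — not that real cohorts,
where annotation and integration dominate the error budget, will reach the
same AUCs.

## Numerical conventions and problem sizes

All percentiles are linear-interpolation (type 7). Boundary inclusion is
≥ upper / ≤ lower for classification and strictly > / < for the QC and
dysfunction filters, matching each rule's stated form. Degenerate strata
(coincident cutoffs) classify everything intermediate rather than
double-labelling. The test suite runs its oracle comparisons at desk
scale — 200 random matrices up to 50 × 20 for the scoring oracle, 200
random small cohorts for the ROC/Youden oracles, 100 generator replicates
per preset for recovery and null calibration — sizes at which the
brute-force oracles are exact and the full suite completes in about a
minute.

## A worked run

```{r example, eval = FALSE}
co <- generate_scores(cohort_preset("strong"), seed = 7)
res <- run_pipeline(scores = co$scores, meta = co$meta, cell_type = "CD8T")
res$grid
#> grid_result [CD8T]: 81 pairs; best (upper 65, lower 45) AUC = 1.000
#>   Youden cutoff 0.6204 (J = 1.000, sens 1.000, spec 1.000)
```

## Known limitations

The AUC selection is in-sample by design; apply the derived thresholds to
an independent cohort before claiming predictive value. The cluster
exclusion rule depends on upstream clustering, which is an input, not a
package responsibility. Signature files shipped under `inst/extdata/` are
synthetic placeholders that validate structure only; real analyses must
supply the authoritative signature gene lists.
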