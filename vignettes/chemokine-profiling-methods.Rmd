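---
title: "Methods: vote-counting chemokine profiling across disease-stage cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vote-counting chemokine profiling across disease-stage cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoatlas)
```

## The statistical model

`chemoatlas` treats a disease-course compendium as a collection of
*independent* cohorts, each a probe × sample intensity matrix with
free-text stage annotations. Nothing is ever pooled at the expression
level: platforms, normalizations and batch structures differ too much
across public cohorts for a merged matrix to be trustworthy, and the
vote-counting design sidesteps that entirely. The only quantities that
cross dataset boundaries are per-dataset summaries — a log2 fold change and
a significance call per gene — which are then averaged.

Within a dataset, expression on the log2 scale is modeled as approximately
normal with equal variance across the two arms of a contrast, which is why
the pooled-variance Student t-test (not Welch) is used for unpaired designs
and the paired t-test for cohorts sampling the same patient at two stages.
Equal variance is an explicit modeling commitment, not an oversight: the
synthetic generator produces homoscedastic Gaussian noise to match, so the
test's assumptions hold exactly on generated data. P-values are converted
to Q-values by Benjamini–Hochberg within each dataset-contrast, over
exactly the gene panel analyzed there (see below).

The vote for gene $g$ in dataset $d$ at stage $s$ is

$$v_{gds} = \begin{cases} +1 & Q_{gds} < q^\* \text{ and } \mathrm{Log2FC}_{gds} > f^\* \\
-1 & Q_{gds} < q^\* \text{ and } \mathrm{Log2FC}_{gds} < -f^\* \\
0 & \text{otherwise} \end{cases}$$

and the *ratio of significant difference* is the arithmetic mean of
$v_{gds}$ over the datasets measuring $g$ at $s$. The signed mean (rather
than an unsigned percentage) is used so that one matrix can encode both
direction and consistency: a cell of $-1$ means unanimous down-calls. A
gene measured by no dataset at a stage yields a *missing* cell, never a
zero — zero means "measured, not significant".

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fc_threshold` | 1 | |Log2FC| gate (two-fold change), dimensionless log2 units |
| `q_threshold` | 0.05 | BH Q-value gate, equivalently −Log10Q > 1.3 |
| `k` | 4 | clusters cut from the score-profile dendrogram |
| `eps` (`to_log2`) | 1.0 | clamp for non-positive linear intensities |
| `panel` | both | ligands (39), receptors (22) or both (61) |

The two significance gates are deliberately conjunctive: genes with tiny
but ultra-significant shifts (|Log2FC| < 1, Q ≪ 0.05) score 0, which
biases the atlas toward biologically large effects and against
platform-sensitive small ones. Both gates are configurable, but the
defaults define the published-style analysis and all bundled tests.

## The quadrant classification

Each gene is placed at x = mean per-dataset Log2FC over IBD cohorts and
y = mean of (mean adenoma Log2FC, mean carcinoma Log2FC) — the two tumor
stages are averaged *after* within-stage averaging so a stage with more
datasets does not dominate. The four named groups occupy four cells of the
±1-threshold grid: i (x > 1, y > 1), ii (x > 1, |y| ≤ 1), iv (y < −1,
|x| ≤ 1), iii otherwise. Two conventions needed fixing where the grid has
cells no named pattern covers:

* genes *exactly at* a threshold fall on the |value| ≤ 1 side (the less
  extreme group), making classification stable under floating-point
  perturbations below 1e−9;
* the cell x > 1, y < −1 (up in colitis, down in tumors) is assigned by
  the nearest archetype — the larger absolute coordinate wins, an exact
  tie falls to iii. This is a deterministic completion of a 9-cell plane
  onto 4 labels.

If a gene is covered on only one of the two tumor stages, y is the mean of
the available stage means; a gene is unclassifiable only when an entire
axis (IBD, or both tumor stages) is uncovered, and such genes are reported
rather than dropped.

## Numerical choices

* **Probe collapse.** "Strongest probe" is defined as highest mean log2
  intensity across *all* samples of the dataset (not the maximum single
  value, not per-group means, which would bias fold changes). Ties are
  broken by the byte-wise (C-locale) smallest probe id, so results do not
  depend on the platform row order or the session locale.
* **Log transform.** Linear values are clamped at `eps = 1` before log2,
  mapping background-subtracted non-positive intensities to 0; the
  transform is idempotent via the dataset's scale flag, and a matrix whose
  maximum exceeds 50 is auto-detected as linear when no declaration is
  present (log2 microarray intensities rarely exceed ~20).
* **Zero-variance groups.** Identical arms give p = 1 outright. Otherwise
  a variance below 1e−12 (e.g. constant paired differences) is floored at
  1e−12 rather than producing an infinite t statistic; the resulting
  p-value is astronomically small but finite and reproducible. This is the
  reason the t-tests are closed-form rather than calls to `stats::t.test`,
  which refuses essentially-constant data; `stats::t.test` is the oracle
  the test suite checks against on non-degenerate inputs.
* **Missing values.** Complete-case throughout: probe means ignore NAs,
  unpaired tests drop missing observations per arm, paired tests drop
  incomplete pairs, and genes with fewer than two usable observations in
  an arm get NA statistics and leave the BH family. No imputation is ever
  performed on expression values; the single exception is clustering,
  where missing score cells are imputed as 0 ("no evidence of change")
  because the dendrogram needs complete vectors — the stored matrix keeps
  its NAs.
* **BH family.** Adjustment runs over the gene panel supplied to
  `run_contrast` (by default the 61 registry genes present on the
  platform), per dataset-contrast. This matches an
  extract-the-family-then-analyze workflow; a genome-wide family would
  give systematically smaller Q-values and is available by passing a
  larger panel.
* **Clustering.** Agglomerative, Euclidean distance, average linkage,
  k = 4, rows pre-sorted by gene symbol — fully deterministic. The
  algorithm is a reproducible stand-in for interactive statistics-package
  clustering; k is configurable.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a public compendium:
several independent datasets (default 4 IBD + 2 adenoma + 3 carcinoma),
each with its own noise draw, optional platform gene subsets, paired or
unpaired design, and heterogeneous publisher vocabulary ("UC", "normal
colonic mucosa", …) that must survive harmonization. Genes follow four
archetypes with true Log2FC effects chosen at the magnitude the headline
biology shows (IBD +2.5 to +3 for up-regulated patterns, adenoma/carcinoma
−2 to −2.5 for tumor-silenced ones; unchanged genes at 0), baseline
log2 abundances uniform in [6, 10], and additive Gaussian noise of SD 0.8
— a realistic per-gene array SD. Paired cohorts add a shared
Normal(0, SD/2) per-pair intercept, which cancels in paired differences
and therefore makes the paired test visibly more powerful than the
unpaired one on the same data. A per-dataset `null_genes` field zeroes
chosen genes' effects to emulate between-cohort heterogeneity (it is how
the 3-of-4 worked example is constructed). `generate_mouse_model()` builds
mouse true effects as $\rho z + \sqrt{1-\rho^2}\,\eta$ around the
standardized human effects and simulates a small two-arm model dataset
(default 5/arm, the scale of real rodent series) under mouse ortholog
names.

What the generator does **not** emulate: probe-level artifacts (dye bias,
spatial effects, cross-hybridization), heavy-tailed or heteroscedastic
noise, correlated genes, batch structure within a dataset, or annotation
errors. Passing tests therefore demonstrate that the pipeline's inference
and bookkeeping are correct under its own assumptions — not that any
particular public cohort satisfies those assumptions.

## Problem sizes in the bundled checks

The test suite runs the full 61-gene panel: archetype recovery over 20
generator seeds of the 9-dataset default cohort (classification recovers
the generating archetypes and the k = 4 clustering matches them by
adjusted Rand index), BH equivalence against a brute-force step-up on
1,000 random vectors, a 200-replicate global-null simulation checking the
q < 0.05 call fraction, and 500-replicate correlation-recovery runs at
ρ = 0.7 and ρ = 0 with 30 ortholog-paired genes. These sizes were chosen
so the whole suite completes in well under a minute on a laptop while
leaving the Monte-Carlo error far below the margins being asserted.

## Known limitations

* Vote counting discards effect-size precision and sample-size weighting;
  a dataset with 3 samples per arm votes like one with 186. That is the
  method's defining simplification, not an implementation artifact.
* The registry pins the 39-ligand / 22-receptor rosters to a canonical
  nomenclature list; a handful of peripheral ligands (e.g. CXCL17, CCL25,
  CCL27) are outside the default roster to keep the canonical counts, and
  the receptor count includes the four atypical receptors.
* The human→mouse map is deliberately injective and conservative: CXCL8,
  the CCL13–16/18/23 cluster and XCL2 have no clean one-to-one murine
  ortholog and are reported as unmapped rather than force-paired; CXCL6 is
  left unmapped because mouse Cxcl5 already pairs with human CXCL5.
* Cross-species correlations compare fold changes, not expression levels,
  and inherit every caveat of the ortholog map; the leave-one-out
  diagnostic flags influential genes but cannot decide whether excluding
  them is biologically warranted.
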