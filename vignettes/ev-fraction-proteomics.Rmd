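---
title: "Differential proteomics of CSF extracellular-vesicle fractions: methods"
author: "EVproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential proteomics of CSF extracellular-vesicle fractions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EVproteomics)
```

# The analysis problem

Cerebrospinal fluid (CSF) collected from extraventricular drains can be
separated into an unprocessed soluble fraction (`Tot`) and two
extracellular-vesicle fractions — microvesicles (`Mv`, 100–1000 nm) and
exosomes (`Ex`, 20–150 nm). Label-free mass spectrometry of the three
fractions yields a protein-group intensity matrix in which many
low-abundance proteins are not detected in every sample, and the question
of interest is which proteins distinguish the fractions, which small
protein panel suffices to classify a sample's fraction, which biological
annotations are differentially enriched between fractions, and whether a
candidate biomarker validates in an independent ELISA cohort.

`EVproteomics` implements that analysis end to end on a
`ProteomeExperiment` (a `SummarizedExperiment` carrying a log2 intensity
assay, a logical not-detected mask, and per-sample fraction and subject
annotations), together with a simulator that generates data with the same
statistical structure and known ground truth.

# Preprocessing

**Presence filtering.** Zeros and blanks in label-free protein-group
tables mean *not detected*, not zero abundance, so they are kept in a
dedicated mask rather than encoded as a magic value. A protein is
retained when at least one fraction detects it in at least
`presence_threshold` (default 70%) of that fraction's samples; a protein
reliably present in only one compartment is biologically informative and
must not be lost to missingness elsewhere.

**Left-censored imputation.** Missing values are assumed to sit below the
sample's detection limit (missing not at random). Each sample column
imputes its missing entries from
$\mathcal N(\hat\mu_j - d\,\hat\sigma_j,\ (w\,\hat\sigma_j)^2)$ with the
column's observed mean and sd, downshift $d = 1.8$ and width $w = 0.3$ —
the de-facto standard for label-free proteomics. Imputation is
per-column, preserving sample-specific detection limits, never alters
observed cells, and is seeded. Imputation runs *before* quantile
normalisation: normalising a matrix that still contains missing values
would estimate the reference distribution from different row sets per
column.

**Quantile normalisation** (via `limma::normalizeQuantiles`, ties
averaged) forces all columns onto the mean sorted profile; it is
idempotent and rank-preserving within columns.

**Sample QC.** Samples are embedded by classical metric MDS (2
components) on the distance $1 - \rho$ (Spearman), and partitioned by
seeded k-means with `k = 3` — the number of fraction labels — using 25
restarts. Agreement between clusters and fraction labels is summarised by
the adjusted Rand index. Outliers are samples whose median
within-fraction Spearman correlation falls below the lower Tukey fence
(Q1 − 1.5·IQR) of all such medians *and* at least 0.05 below their
median. The absolute margin is deliberate: in a homogeneous run the
medians cluster within roughly 0.005, where a bare Tukey fence flags the
lowest healthy sample in about a third of simulated runs, while a truly
aberrant sample (e.g. a scrambled column) loses far more than 0.05 of
rank correlation and is still caught.

# Differential statistics

Per protein, a fixed-effects one-way ANOVA across the three fractions
(samples treated as unpaired — pooled samples are not linked to their
contributing subjects) and two-sided **Welch** t-tests for each pairwise
comparison (`Tot` vs `Mv`, `Tot` vs `Ex`, `Ex` vs `Mv`; the log2 fold
change is second-minus-first). Welch rather than the pooled-variance test
because with 8 samples per fraction equal variances cannot be relied on.
P-values are Benjamini–Hochberg adjusted across proteins within each
comparison.

A protein is *significant* only when both `p_adj <= alpha` (default 0.05)
**and** its post-hoc power reaches `power_threshold` (default 0.80). The
power term is computed from the observed effect at the stated alpha using
the noncentral F (ANOVA, noncentrality $\lambda = F \cdot df_1$) or
noncentral t (Welch, noncentrality $= t_{obs}$) distribution. The
conjunction discards calls whose observed effect could not have been
detected reliably at the design's sample size.

**Volcano cutoff.** The significance curve on the
(|log2 FC|, −log10 p) plane is $y = |c/(x - x_0)|$: a protein passes
when $|log2\,FC| > x_0$ and $-\log_{10} p$ exceeds the curve. The pole at
$x_0$ acts as a hard minimal-fold-change gate. The curve constants are
configuration values (defaults $c = 0.5$, $x_0 = 1$); the pass set is
monotone in both.

# Feature selection and the core panel

Predictors are z-scored per protein. Two complementary rankings:

* **PLS-DA VIP.** A PLS2 discriminant model fitted by NIPALS against the
  one-hot fraction response, with
  `n_components = min(classes - 1, 5)`. The variable importance in
  projection is
  $VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\lVert w_a\rVert)^2 / \sum_a SSY_a}$,
  higher = more discriminating. The squared VIPs average exactly 1 over
  the modelled proteins — an identity the tests assert to 1e-9.
* **SVM-RFE rank.** Linear soft-margin SVMs (cost 1.0, a documented
  constant) are fitted on all class pairs; each surviving protein is
  scored by the summed squared hyperplane weights and the lowest-scoring
  half is eliminated per round (exactly tied scores — duplicated
  proteins — are never split across the elimination boundary). Rank 1 is
  the last survivor: the lowest rank means the highest discriminating
  power.

Classification accuracy is estimated by repeated stratified Monte-Carlo
splits: 65% of each class for learning, 35% for testing (default at
least 4 repetitions), one-vs-rest linear SVMs, prediction by largest
decision value, and repetitions continue until every sample has served in
at least one learn and one test set. The aggregated test confusion matrix
and mean accuracy are reported.

The **core panel** orders candidates by ascending SVM rank (ties broken
by descending VIP, then protein id, for deterministic output) and grows
the panel $k = 1, 2, \dots$ until the cross-validated confusion matrix is
diagonal; the smallest such $k$ defines the panel and the VIP of the
$k$-th protein is reported as the empirical VIP limit. By default the
search runs on the ANOVA-significant subset (a flag ranks all proteins
instead). Per-protein discrimination is additionally summarised by the
ROC AUC from the Mann–Whitney identity (ties at half credit), oriented so
values above 0.5 mean "higher in the second fraction".

# Annotation and kinase enrichment

For two differential comparisons $x$ and $y$, every annotation term is
scored on each axis by the centred mean rank of its members over the
signed log2 fold changes, rescaled to $(-1, 1)$:
$s = \tfrac{2}{n}(\overline{rank}_{members} - \tfrac{n+1}{2})$. The score
is rank-based, hence invariant to monotone transforms of the statistic,
antisymmetric under sign flips, and exactly 0 for the whole universe.
Its p-value comes from the Mann–Whitney U statistic (exact for up to 3
members without ties, otherwise the normal approximation with tie and
continuity corrections), BH-adjusted per axis across terms. A term is
significant at FDR `alpha` in at least one axis with at least
`min_members` (default 5) members in the universe. Terms on the $x = y$
diagonal are equally enriched in both comparisons; the signed diagonal
distance $(s_y - s_x)/\sqrt 2$ measures differential enrichment, and
`beyond_ci` marks terms beyond the 97.5th percentile of the null distance
from `n_permutations` (default 1000) random same-size memberships — the
band widens as terms shrink. The per-axis statistic is the signed fold
change; the member count and FDR enter through the `min_members` and
`alpha` gates.

Kinase enrichment tests each kinase's substrate set for
over-representation among significant proteins against the identified
universe with the one-sided hypergeometric distribution, BH across
kinases; direction is `up`/`down` when at least 60% of the significant
substrates share a sign, otherwise `mixed`.

# ELISA validation

Raw 450 nm absorbances reduce to relative units
$RU = (A - \bar A_{bg}) / (\bar A_{ref} - \bar A_{bg})$ against the
uncoated-background and reference-standard wells; the detection limit is
`mean(blank RU) + 3 sd(blank RU)`, operationalising "the lowest signal
distinguishable from blank". Group differences use the tie-corrected
Kruskal–Wallis test (exact permutation enumeration offered for total
n ≤ 8); summaries are medians with interquartile ranges (linear
interpolation quantiles). Controls versus pooled tumour groups are
compared by ROC: AUC by the Mann–Whitney identity, confidence interval
and p-value from the DeLong variance (chosen over the bootstrap for
determinism; a seeded bootstrap interval is available), the cutoff
maximising Youden's J over midpoints of adjacent observed values with
ties resolved toward higher specificity, reported with its direction
("<" when low values flag a case), plus LR+ = sens/(1 − spec) and the
conventional AUC quality bins (0.5 not discriminant, then fail / poor /
fair / good / excellent in 0.1 steps).

# The simulator: what it emulates and what it does not

`simulateFractionProteome()` generates the study design: 1622 proteins ×
3 fractions × 8 samples (6 individuals plus 2 pools, pools formed by
averaging two fresh subject draws). Baseline log2 abundances are
$\mathcal N(25, 4)$ — a wide dynamic range on the log2 scale; a
`frac_differential` share (default 15%) of proteins receives additive
shifts $\mathcal N(0,\ effect\_sd)$ (default 2) in one or two fractions;
within-group noise is $\mathcal N(0, 0.5)$; and detection follows a
logistic curve in abundance (scale 2 log2 units, location solved so the
overall censored share hits `missing_rate`, default 10%) — the
missing-not-at-random behaviour the downshifted imputation presumes.
The within-group sd, dynamic-range parameters and censor scale are
documented constants, not estimates of any real dataset.
`simulateAnnotations()` plants terms whose members oversample proteins
truly shifted upward in one comparison (at least 80% of members), so
their fold-change ranks are coherently high; `simulateElisaCohort()`
draws a 10/10/10 CTR/PA/MB cohort whose background-subtracted RU/mL
match requested group medians and interquartile range, with background,
reference and blank wells.

All draws flow from one seeded generator per call: the same seed and
parameters give byte-identical output, and the pipeline's file outputs
are byte-identical across repeated runs under one configuration.

The simulator does **not** model peptide-level effects, batch or plate
effects, subject pairing across fractions, correlated proteins
(co-regulation), or heavy-tailed intensity noise. Passing
parameter-recovery tests therefore demonstrates that the statistics
recover the effects this generative model plants — not that the pipeline
is robust to every artefact of real label-free data.

A consequence worth stating plainly: because planted shifts are drawn
from $\mathcal N(0, effect\_sd)$, a sizeable minority of "truly
differential" proteins carry shifts below what $n = 8$ per fraction with
sd 0.5 can detect at a BH-corrected level; with 10% left-censoring and
downshifted imputation, the sensitivity of the differential stage against
that truth settles around 0.70–0.74 (about 0.84 with complete data),
while the observed false discovery proportion stays below 0.1. The
package reports this honestly rather than easing the generator's
conditions.

# Problem sizes used in the tests and acceptance script

Monte-Carlo checks run at sizes chosen to make their expectations sharp
while keeping the default suite quick: null calibration on 2000-protein
simulations, parameter recovery at the full 1622 × 24 design, panel
recovery on 50-protein fixtures with three planted separators, oracle
equivalences on exhaustive small cases (all member subsets at n = 8, all
720 permutations at n = 6). `scripts/acceptance.R` re-runs the same
computations from scratch at comparable sizes and writes the resulting
numbers as JSON.

# Known limitations

* The "fourfold cross-validation with 65/35 splits" scheme is a repeated
  Monte-Carlo design with a coverage stopping rule, not k-fold; plain
  k-fold is not currently exposed.
* Post-hoc power from observed effects is anti-conservative for small
  effects; it is used here as a gate, as in the original analysis design,
  not as an estimate of true power.
* The 2D enrichment statistic (signed fold-change mean ranks) is one
  concrete choice among the rank constructions compatible with bounded
  [−1, 1] per-term scores; conclusions about individual borderline terms
  depend on it.
* No paired/mixed-model analysis: subjects contributing to several
  fractions are treated as independent samples.
* Moderated-variance (empirical-Bayes) testing is deliberately out of
  scope; with n = 8 per group the Welch test is adequate and keeps the
  significance rule transparent.
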