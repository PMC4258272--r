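---
title: "Constrained ordination of transcriptomes: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained ordination of transcriptomes: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccatx)
```

## The problem

A common situation in immunology and stem-cell biology: a transcriptome of
an *undefined* cell population (say, T cells from a knockout mouse) must be
interpreted against a panel of *well-defined* reference states (Th1, Th2,
Th17, iTreg, ...). Rather than eyeballing marker genes, ccatx asks a
constrained ordination to do the bookkeeping: how much of the variation in
the main data is explainable by the reference differentiation programmes,
and where does each sample fall along them?

## The model

Let $X \in \mathbb{R}^{k \times p}$ be the non-negative main expression
matrix ($k$ genes, $p$ samples) with grand total $n$, row masses
$r = X\mathbf{1}/n$ and column masses $c = X^\top\mathbf{1}/n$. The
chi-square standardization is

$$S = D_r^{-1/2}\left(\tfrac{1}{n}X - rc^\top\right)D_c^{-1/2},$$

whose squared Frobenius norm is the **total inertia** $I_T$ (Pearson
$\chi^2/n$). The explanatory matrix $Z \in \mathbb{R}^{k \times q}$ holds
one column per differentiation programme; each column is standardized to
weighted mean 0 and variance 1 in the $D_r$ metric. The constrained space
is the weighted regression of $S$ on $Z$:

$$Q = D_r^{1/2} Z (Z^\top D_r Z)^{-1} Z^\top D_r^{1/2}, \qquad S^* = QS,$$

and the axes come from the SVD $S^* = U D_\alpha V^\top$. Constrained
inertia is $I_C = \sum_i \alpha_i^2 = \lVert S^* \rVert_F^2$; the share
$I_C / I_T$ is the fraction of the data the programmes can explain.

Scores, in the usual correspondence-analysis vocabulary:

* **LC gene scores** $D_r^{-1/2}U$ (standard) and $D_r^{-1/2}U D_\alpha$
  (principal) — fitted coordinates, linear combinations of the explanatory
  columns;
* **WA gene scores** $D_r^{-1/2} S V$ (standard) and
  $D_r^{-1/2} S V D_\alpha$ (principal) — weighted averages of the sample
  scores through the data, the coordinates to plot genes at;
* **sample scores** $D_c^{-1/2}V$ and $D_c^{-1/2}V D_\alpha$;
* **biplot scores** — the $D_r$-weighted correlations of each explanatory
  column with the standard LC axes. Because both factors are standardized
  in the same metric they reduce to $Z^\top D_r^{1/2} U$ and always lie in
  $[-1, 1]$; they are drawn as arrows in the triplot.

A note on the WA definition: defining WA scores with the leading
$D_r^{-1/2}$ (rather than $SV$ alone) is what makes the classical
transition formula hold — in the unconstrained limit the standard WA gene
scores coincide exactly with the principal LC gene scores. The test suite
asserts this identity numerically.

With $q = 1$ (a single **differentiation variable**
$d = \mu_y - \mu_x$, the difference of two class-mean profiles) the
solution is one-dimensional and the principal sample scores form a scoring
system along the $x \to y$ axis of differentiation. This is the basis of
the automatic classifier.

## Weighted standardization of Z

Only "mean 0, variance 1" is inherent to the method; the weighting is a
genuine design choice. ccatx standardizes $Z$ with the row masses $r$ so
that centering, projection and biplot correlation all live in the same
$D_r$ geometry; `cca(..., weighted_z = FALSE)` switches to plain
standardization for sensitivity checks. In practice the two differ little
when row masses are nearly uniform (as for log-scale expression), but the
weighted form is the one under which the CA-limit identity below is exact.

## Rank handling and the CA limit

Weighted centering of $Z$ removes one dimension, so $q$ standardized
columns span at most $\min(q, k-1)$ directions. The projector is built by
pivoted QR on $D_r^{1/2}Z$, and a collinearity error is raised only when
the rank falls below $\min(q, k-1)$ — i.e. when two programmes are
genuinely linearly dependent. This makes the full-rank limit exact: with
$q = k$ independent columns the centered span is the whole orthogonal
complement of $\sqrt{r}$, which contains every column of $S$, so $S^* = S$
and the constrained solution reproduces plain correspondence analysis to
machine precision (asserted at $10^{-10}$ in the tests, and checked
independently against vegan's implementation).

## Determinism

SVD signs are arbitrary, so each axis is oriented so that its
largest-magnitude biplot score is positive (largest-magnitude sample score
for unconstrained CA). Axes with $\alpha_i < 10^{-10}\,\alpha_1$ are
dropped as numerical rank noise. Tied singular values leave the axis
order, and hence the orientation, unstable under permutation of the input;
exact ties essentially only occur in designed degenerate inputs. A matrix
with no association at all (all columns proportional) yields a single
all-zero axis rather than an error.

## The classifier

For a target class $t$ the one-vs-rest differentiation variable is
$d = \mu_t - \overline{\mu}_{\text{rest}}$, where the rest profile is the
*unweighted mean of the other class means* — not the pooled-sample mean —
so unequal replicate counts do not tilt the contrast. Test samples are
scored by the 1-D ordination and split by k-means with $k = 2$; the
higher-mean cluster is called positive.

Two choices deserve emphasis:

* **Sign canonicalization.** The score must not depend on whether the
  contrast was written as $x \to y$ or $y \to x$. `cca_score_1d()`
  therefore orients the axis by the canonical direction of $d$ — the sign
  that makes its largest-magnitude gene entry positive. For class
  contrasts the dominant entry of $d$ is an up-regulated marker of the
  target programme, so higher scores read as "more of that programme";
  swapping the contrast labels changes nothing downstream.
* **Exact k-means.** In one dimension the optimal two-cluster solution is
  a threshold partition of the sorted scores, so `kmeans_classify()`
  enumerates all $n-1$ splits with prefix sums and returns the global
  minimizer of the within-cluster sum of squares. Lloyd iterations from
  any fixed initialization can stall in local optima (we observed this on
  random score vectors); exact enumeration removes both that failure mode
  and any seed dependence. The test suite checks the partition against an
  independent brute-force oracle on a thousand random inputs.

Sensitivity is TP/(TP+FN) and reported as `NA` (not 0) when a test set
contains no condition positives. Uncertainty is attached by the jackknife:
the metric is recomputed on every leave-one-out replicate and the 95%
interval is $\bar\theta \pm 1.96\,\mathrm{SE}$ with
$\mathrm{SE}^2 = \frac{m-1}{m}\sum_i(\theta_i - \bar\theta)^2$. This is
the standard jackknife normal interval; replicates with undefined metric
are dropped with a warning.

## Gene filters

`select_de_genes()` combines a two-sample Welch t-test with
Benjamini–Hochberg correction (FDR < 0.01 by default) and a fold-change
filter keeping the top/bottom 1% of mean differences; both filters apply
to the same pairwise contrast. The Welch+BH combination is deliberately
self-contained rather than a moderated (shrinkage) test; with the few
replicates typical of these designs it is conservative, which the null
calibration test quantifies (mean false-positive count stays below
`fdr * k` under the complete null). `select_lineage_genes()` implements
the linear-scale rule for lineage-specific genes: class-mean RPKM ≥ 5 and
≥ 2-fold above every other lineage. `select_top_features()` ranks genes by
$|d|$ of the one-vs-rest variable with a lexicographic tie-break, so the
$n$-gene set is always a prefix of the $(n+1)$-gene set. Ranking by the
magnitude of the method's own contrast (rather than by a separate test
statistic) keeps feature selection inside the model the classifier uses.

## Cross-platform normalization

When the main and resource data come from different platforms
(microarray vs RNA-seq), `rank_normalize()` replaces each sample column by
its ranks mapped onto the mean sorted profile pooled across both datasets
(average ranks for ties, linear interpolation into the reference). Output
then depends only on within-column orderings, removing strictly monotone
platform distortions. Gene matching across platforms is by case-folded
symbol; probe-to-symbol mapping is assumed done upstream. Negative values
(possible in log-scale microarray exports) are clipped to zero by default
with a reported count, because the chi-square metric needs non-negative
mass; `clip_negative = FALSE` makes them an error instead.

## The synthetic generator

`synthetic_spec()` / `generate_pair()` emulate the structure the method
assumes: disjoint marker-gene sets per class, a common baseline, a large
between-class effect against small within-class Gaussian noise, and very
few replicates. The defaults — 1000 genes, 4 classes, 25 markers per
class, duplicates, effect 4, noise SD 1, baseline 4 on a log2-like scale —
are the study design used throughout the tests and the acceptance script;
the baseline of 4 keeps clipping at zero negligible. The optional
knockout construct adds a test-set class whose markers lose (a fraction
of) their effect, emulating a transcription-factor knockout that fails to
induce its programme.

What the generator does *not* emulate: count-level sampling noise
(Poisson/negative-binomial), mean–variance coupling, batch effects,
correlated marker modules, or partially overlapping programmes. Passing
the recovery tests therefore demonstrates correctness of the machinery
under the assumed variance structure, not robustness to real-data
pathologies.

## Problem sizes used in the checks

The property checks run at deliberately small scale: CA-limit and
conservation on random matrices of 4–10 genes × 3–6 samples; the
partition oracle on ≤ 12 points × 1000 draws; recovery and knockout runs
on the 1000-gene default design over 50 simulated experiments; null
calibration with 200 genes × 200 simulations. These sizes already pin the
algebra to 10–12 digits and the classifier behaviour exactly, and keep
the whole suite fast.

## Known limitations

* Partial CCA (covariate adjustment), detrended CA and permutation tests
  on the constrained inertia are not implemented.
* The explanatory columns for multi-programme analyses default to class
  means; per-sample resource profiles can be passed, but reference panels
  are expected replicate-free.
* Accuracy of cross-platform analyses depends on the upstream gene
  mapping; rank normalization cannot repair non-monotone platform
  effects.
* With tied singular values the axis order (and triplot) is not unique.
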