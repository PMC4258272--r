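# ccatx — canonical correspondence analysis of transcriptomes

`ccatx` interprets the transcriptome of an *undefined* cell population
against a panel of *well-defined* reference differentiation programmes
(e.g. Th1/Th2/Th17/iTreg helper-T subsets) by constrained ordination in
the chi-square metric. It is aimed at immunologists and computational
biologists who want a data-driven answer to "which differentiation
programme is disturbed in these cells?" instead of marker-gene
eyeballing, and at method developers who need a transparent, fully
deterministic reference implementation.

## The method in brief

Given a non-negative gene × sample matrix $X$ (grand total $n$, row
masses $r$, column masses $c$), the chi-square standardized matrix is

$$S = D_r^{-1/2}(\tfrac{1}{n}X - rc^\top)D_c^{-1/2},$$

whose squared Frobenius norm is the total inertia $I_T = \chi^2/n$. An
explanatory matrix $Z$ (one standardized column per differentiation
programme, weighted by $D_r$) defines the projector
$Q = D_r^{1/2}Z(Z^\top D_r Z)^{-1}Z^\top D_r^{1/2}$; the SVD of the
constrained space $S^* = QS = UD_\alpha V^\top$ yields gene scores
(LC: $D_r^{-1/2}U$; WA: $D_r^{-1/2}SV$), sample scores ($D_c^{-1/2}V$),
biplot arrows (weighted correlations of $Z$ with the LC axes) and the
inertia split $I_C = \sum\alpha_i^2$ vs $I_T$. With a single
**differentiation variable** $d = \mu_y - \mu_x$ (difference of
class-mean profiles) the solution is one-dimensional and scores every
sample along the $x \to y$ differentiation axis; k-means ($k = 2$,
solved exactly in 1-D) turns the scores into an automatic classifier,
with jackknife confidence intervals for sensitivity and accuracy.

## Worked example

```r
library(ccatx)

# a paired resource/test experiment with the assumed structure:
# 1000 genes, 4 classes, 25 markers each, duplicates, effect 4, noise 1
pair <- generate_pair(synthetic_spec(seed = 1))

# ordination of the test data constrained by the 4 reference programmes
fit <- cca(pair$test, class_means(pair$resource)$means)
fit
#> Canonical correspondence analysis
#> axes: 4   total inertia: 0.06669   constrained: 0.00751533 (11.3%)
#> per-axis inertia (% of constrained): Axis1 41.6%, Axis2 32.8%, Axis3 25.6%, Axis4 0.0%

# automatic classification: is each test sample a Th17 cell?
res <- classify_samples(pair$resource, pair$test, "Th17", n_features = 100)
res
#> tp=2 fp=0 tn=6 fn=0  sensitivity=1.000 accuracy=1.000
round(res$scores, 3)
#>   Th1_t1   Th1_t2   Th2_t1   Th2_t2  Th17_t1  Th17_t2 iTreg_t1 iTreg_t2
#>   -0.094   -0.150   -0.079   -0.092    0.239    0.249   -0.088   -0.052
```

Reading the output: the four reference programmes explain 11.3% of the
test data's inertia, most of it on the first three axes (the
between-class signal of four classes spans three directions, so the
fourth constrained axis catches only noise). The 1-D Th17 scores separate
the two true Th17 samples (0.24–0.25) cleanly from the six others
(≤ −0.05), so the two-group partition recovers them with sensitivity and
accuracy 1.

Triplots (`triplot()`), 1-D score plots (`score_plot_1d()`) and
axis-ordered heatmaps (`heatmap_by_axis()`) render the same numbers;
every figure is accompanied by TSV files with the plotted values. A thin
command-line front end with `simulate` / `cca` / `score` / `classify`
verbs is installed at `inst/cli/ccatx-cli.R`.

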