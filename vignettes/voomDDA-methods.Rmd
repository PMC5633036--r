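---
title: "Precision-weighted discriminant classification of RNA-seq counts: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-weighted discriminant classification of RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The package classifies samples from a $p \times n$ matrix of RNA-seq counts
$x_{gi}$ (genes $g$, samples $i$, classes $k = 1,\dots,K$). Counts are
discrete and overdispersed, so instead of modelling them directly we move to
log2 counts-per-million,

$$z_{gi} = \log_2\!\left(\frac{x_{gi} + 0.5}{X_{.i} + 1}\times 10^6\right),$$

with $X_{.i}$ the (effective) library size; the $0.5/1$ offsets keep the
ratio strictly inside $(0,1)$ so every $z_{gi}$ is finite. The price of the
log transform is strong heteroscedasticity: low-count observations are much
noisier. We therefore estimate, per observation, a precision weight — the
inverse predicted variance of $z_{gi}$:

1. fit, gene by gene, the ordinary-least-squares model
   $E(z_g) = D\beta_g$ with $D$ the class-indicator design
   (fitted values are the class means; residual sd $s_g$ with $n-K$
   degrees of freedom);
2. convert mean fitted log-cpm to mean log-counts,
   $\tilde x_g = \bar z_g + \log_2 \tilde X_{.n} - \log_2 10^6$, where
   $\tilde X_{.n}$ is the geometric mean of the $X_{.i}+1$;
3. smooth $s_g^{1/2}$ (standard deviation on the quarter-root-variance
   scale) against $\tilde x_g$ with lowess and store the curve as a
   piecewise-linear function $lo(\cdot)$;
4. set $w_{gi} = lo(\hat\mu_{gi})^{-4}$ at the fitted log-count
   $\hat\mu_{gi}$ of each observation.

All three classifiers assume genes independent given the class (diagonal
covariance) and plug the weights into weighted statistics: class centroids
$\bar z_{w_{gk}}$ (weighted means), the overall centroid
$\bar z_{w_g} = \sum_k n_k \bar z_{w_{gk}}/n$, unbiased weighted class
variances

$$s^2_{w_{gk}} = \frac{\sum_i w_{gi}}{(\sum_i w_{gi})^2 - \sum_i w_{gi}^2}
  \sum_i w_{gi}(z_{gi}-\bar z_{w_{gk}})^2,$$

and the pooled variance $s^2_{w_g} = \sum_k (n_k-1)s^2_{w_{gk}}/(n-K)$.
With equal weights every weighted statistic reduces exactly to its
classical counterpart, a reduction the test suite asserts.

**voomDLDA / voomDQDA** score a test observation by
$\delta_k = -\sum_g (z_{g*} - \bar z_{w_{gk}})^2/v_g + 2\log\hat\pi_k$
with $v_g$ the pooled ($s^2_{w_g}$, linear) or class-specific
($s^2_{w_{gk}}$, quadratic) variance and $\hat\pi_k$ the class priors
(class proportions by default). **voomNSC** standardizes centroid
contrasts, $d_{w_{gk}} = (\bar z_{w_{gk}} - \bar z_{w_g}) /
(m_k(s_{w_g}+s_{w_0}))$ with $m_k = \sqrt{1/n_k - 1/n}$ and $s_{w_0}$ the
median of the pooled weighted sds, soft-thresholds them at $\lambda$, and
rebuilds shrunken centroids. Its discriminant is
$\delta_k = -\tfrac12\sum_g (z_{g*}-\bar z'_{w_{gk}})^2/(s_{w_g}+s_{w_0})^2
+ \log\hat\pi_k$, summed over *all* model genes — fully shrunk genes
contribute identically to every class and thus cancel. Genes with a
non-zero shrunken score in at least one class are the model's signature.

## Train-to-test transfer

Everything estimated on the training set is frozen and reused: the
normalization model, the trend $lo(\cdot)$, the centroids and variances.
A test observation is (i) normalized — for DESeq median-ratio
normalization its size factor is the median of its counts over the stored
per-gene training geometric means; for TMM its log2 factor is the weighted
trimmed mean of M values against the stored reference sample — (ii)
converted to log-cpm with the same formula, and (iii) given weights by
evaluating the frozen trend at its own fitted log-counts. The mean-variance
relationship is never re-estimated; a training column passed back through
this path reproduces its training log-cpm values bit-for-bit.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `span` | 0.5 | lowess span of the trend; the value the established voom implementation uses |
| `lambda` | CV-selected | shrinkage threshold, in units of standardized centroid contrast |
| `n_lambda` | 30 | grid size; the grid is uniform on $[0, \max|d|]$ |
| `cv_folds` | 5 | stratified folds; the same folds (fixed by `seed`) are used for every threshold |
| `priors` | $n_k/n$ | class priors; user-overridable, must sum to 1 |
| `var_floor` | 1e-8 | added to variance denominators of the DLDA/DQDA rules to guard near-zero-variance genes |
| `trim_m`, `trim_a` | 0.30, 0.05 | two-sided TMM trim fractions on M and A; 0 gives the untrimmed weighted mean |
| `freq_cut`, `unique_cut` | 19, 0.10 | near-zero-variance filter thresholds (95/5 frequency ratio, 10% unique values) |

## Numerical and design choices

* **Threshold selection.** Among thresholds attaining the minimum CV error
  we take the largest (the sparsest solution). Cross-validation refits the
  entire pipeline — normalization, voom, moments — inside each fold and
  transforms held-out samples with fold-training parameters only, the
  leakage-free reading of "same parameters for training and test".
* **Trend evaluation.** Outside the training knot range the trend is
  extended as a constant (nearest knot); values are floored at $10^{-6}$
  before the $-4$ power so weights stay finite. Unbounded linear
  extrapolation can predict non-positive standard deviations.
* **Median-ratio details.** Size factors use the literal median of
  count/geometric-mean ratios. Genes with a zero in any training sample are
  excluded from the median (their geometric mean is zero). A documented
  `rescale` option renormalizes the $n{+}1$ factors (training + test) to
  geometric mean one; the default returns the plain median ratio, which
  already places the test sample on the training scale.
* **TMM details.** The reference is the training sample whose
  upper-quartile/library-size ratio is closest to the mean of those ratios
  (deterministic). M values are log2 ratios of count proportions; genes
  with a zero in either sample are dropped; the gene weight is the
  delta-method variance expression
  $(X_{.i}-x_{gi})/(X_{.i}x_{gi}) + (X_{.r}-x_{gr})/(X_{.r}x_{gr})$ used
  directly as stated for this method (note that edgeR's TMM weights by the
  *inverse* of this expression, so the two give different factors).
  Trimming is rank-based on M and A jointly. The reference's own factor is
  exactly 0.
* **Posterior sign.** voomNSC posteriors are
  $e^{-\delta_k}/\sum_l e^{-\delta_l}$ as stated for this classifier
  family, computed with max-subtraction. Because prediction maximizes
  $\delta_k$, this convention *anti-ranks* the predicted class;
  `posterior_sign = "softmax"` gives the conventional
  $e^{+\delta}$ form. The predicted class never depends on this choice.
* **Near-zero filter.** A gene is removed only when *both* criteria hold
  (dominant-value frequency ratio > 19 *and* unique-value proportion <
  10%); a gene with many distinct values is informative even if one value
  dominates. Constant genes are always removed.
* **Variance filter.** Genes are ranked by the variance of
  $\log_2(\text{count}/\text{size factor} + 1)$ — a monotone
  variance-stabilizing surrogate that needs no extra model fit — and the
  original counts of the winners are carried forward. Ties break by input
  order for determinism; borderline genes may rank differently than under
  a regularized-log transform.
* **Tie-breaking.** Class argmax ties resolve to the lowest class index
  everywhere.

## The simulator

`simulate_counts()` draws
$x_{gi}\,|\,y_i = k \sim \mathrm{NB}(\mu_{gi}e_{gk}, \phi)$ with mean
$\mu_{gi}e_{gk}$ and variance $\mu_{gi}e_{gk} + (\mu_{gi}e_{gk})^2\phi$
(`rnbinom` with `size = 1/phi`), $\mu_{gi} = g_g s_i$, sampling depths
$s_i \sim \mathrm{Unif}(0.2, 2.2)$, gene abundances $g_g \sim
\mathrm{Exp}(\text{mean } 25)$, and, for the Bernoulli(`de_prob`) subset of
differential genes, per-class fold changes $e_{gk} = \exp(\tilde z_{gk})$,
$\tilde z_{gk}\sim N(0,\sigma^2)$ drawn independently for *every* class of
a differential gene (no class is pinned at baseline). A constant
$\varepsilon = 1$ is added to every count. Samples are assigned to classes
in balanced blocks and shuffled by the seed.

This emulates depth variation, abundance skew, tunable overdispersion and
sparse class structure. It does **not** emulate gene-gene correlation,
batch effects, sample-quality heterogeneity, length bias, or zero
inflation beyond the NB — so passing tests demonstrate correctness of the
machinery and recovery under the stated generative model, not performance
on any particular real dataset. Note one consequence for truth-set
evaluation: because both classes redraw their fold change, a "differential"
gene can realize a negligible class difference, which bounds how enriched
even a perfectly selected small signature can look.

`run_scenario()` executes the evaluation protocol in order: stratified
70/30 split; near-zero filtering on the training set; top-variance
selection (counts of the winners fetched again); normalization factors
estimated from the *unfiltered* raw training set; voom transformation;
cross-validated fitting; prediction of each held-out sample with frozen
training parameters; misclassification and balanced error
($1 - (\text{sensitivity}+\text{specificity})/2$, averaged one-vs-all for
$K > 2$) plus sparsity.

## Problem sizes

The test suite runs desk-scale versions of everything: formula oracles on
hundreds of small random instances; pipeline tests at $p$ = 200–500 genes,
$n$ = 40–80; the recovery scenario at $p = 2000$ genes (500 kept),
$n = 100$, $K = 2$, 10% differential genes, $\sigma = 0.2$, over 10
repetitions at $\phi = 0.01$ and $\phi = 1$ — sizes chosen so the whole
suite completes in well under a minute while still exercising every stage
at realistic shapes.

## Known limitations

* Diagonal covariance ignores co-expression; correlated gene modules can
  dominate the vote.
* The generator's Bernoulli truth flags include effectively null fold
  changes (see above), so enrichment statistics on very small signatures
  are conservative.
* In a near-noise-free regime the CV error curve can be exactly zero over
  a wide threshold plateau; the sparsest-at-tie rule then legitimately
  selects one- or two-gene signatures. That is the intended behavior, but
  users wanting richer signatures can fix a smaller `lambda` directly.
* Variance ranking uses a log-based surrogate rather than a fitted
  variance-stabilizing transform; gene selection may differ at the margin.
* Single-sample classes are rejected; weighted variances need at least two
  samples per class.
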