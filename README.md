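# voomDDA

Precision-weighted discriminant classification and diagnostic biomarker
selection for RNA-seq count data.

## The problem

Gene-expression classifiers built for microarrays assume continuous,
roughly homoscedastic data. RNA-seq produces non-negative, integer,
overdispersed counts whose variance depends strongly on the mean, so those
classifiers cannot be applied directly. This package bridges the gap the
way the voom methodology does for differential expression: counts are
transformed to log2 counts-per-million (log-cpm) and each observation
receives a *precision weight* — its inverse predicted variance, read off a
lowess trend of the quarter-root variance against mean log-count. Gaussian
discriminant machinery is then rebuilt on weighted statistics:

* **voomDLDA** — weighted diagonal linear discriminant analysis
  (gene-wise weighted variances pooled across classes),
* **voomDQDA** — weighted diagonal quadratic discriminant analysis
  (class-specific weighted variances),
* **voomNSC** — a sparse weighted nearest-shrunken-centroid classifier.

voomNSC standardizes the contrast between each class centroid and the
overall centroid,

```
d_wgk = (zbar_wgk − zbar_wg) / (m_k (s_wg + s_w0)),   m_k = sqrt(1/n_k − 1/n),
```

soft-thresholds it (`d' = sign(d) max(|d| − λ, 0)`, the lasso operator),
and rebuilds shrunken centroids `zbar'_wgk = zbar_wg + m_k (s_wg + s_w0)
d'_wgk`. Genes shrunk to zero in every class drop out of the decision rule;
the survivors are a compact diagnostic gene signature. λ is tuned by
stratified cross-validation, taking the *largest* threshold that attains
the minimum CV error (the sparsest model among the error ties).

Training-set normalization (DESeq median-ratio or TMM against a stored
reference sample) and the fitted mean-variance trend are frozen and
transferred to test observations, so prediction never re-estimates
anything. A negative binomial simulator (`mean μ, variance μ + μ²φ`) and
an end-to-end evaluation protocol (70/30 split, near-zero-variance and
top-variance gene filtering, normalization, voom, CV, test prediction)
round out the package.

## Worked example

```r
library(voomDDA)

sim <- simulate_counts(sim_scenario(p = 2000, n = 100, K = 2, de_prob = 0.10,
                                    sigma = 0.2, phi = 0.01, seed = 1))
sim$data
#> count_matrix: 2000 genes x 100 samples
#> classes: class1 (n=50), class2 (n=50)

# stratified 70/30 split, then the two filtering stages on the training set
train <- rep(TRUE, 100); set.seed(1)
for (k in levels(sim$data$labels)) {
  idx <- which(sim$data$labels == k)
  train[sample(idx, round(0.3 * length(idx)))] <- FALSE
}
m_tr <- sim$data[, train]; m_ts <- sim$data[, !train]
nz <- near_zero_filter(m_tr)
mf <- variance_filter(nz$kept, 500, deseq_size_factors(nz$kept)$size_factors)

model <- fit_nsc(mf, normalization = "deseq", seed = 1)
model
#> voomNSC model: 500 genes, classes class1/class2
#> lambda = 4.665; 2 surviving genes

pred <- predict(model, m_ts)
evaluate_predictions(m_ts$labels, pred, length(model$survivors), 500)
#> test error 0.000 | balanced error 0.000 | relative sparsity 0.004
```

The cross-validated threshold (λ = 4.665) kept a 2-gene signature
(`g0035`, `g1076`), both of which are truly differential in the simulator's
truth table, and classified all 30 held-out samples correctly. Lower the
dispersion realism (`phi = 1`) and accuracy degrades — overdispersion is
exactly what the precision weights are fighting.

The same workflow is scriptable from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/voomdda.R", package = "voomDDA"))')
Rscript $CLI simulate --p 2000 --n 100 --seed 1 --out counts.tsv --truth truth.tsv --labels labels.tsv
Rscript $CLI train --counts counts.tsv --labels labels.tsv --method voomNSC --normalization deseq --out model.json
Rscript $CLI predict --model model.json --counts counts.tsv --out predictions.tsv
Rscript $CLI evaluate --pred predictions.tsv --truth labels.tsv
```

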