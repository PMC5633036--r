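# Shared front end of all three classifiers: normalization -> voom -> moments.
dda_pipeline <- function(m, labels, normalization, norm_model, priors, span) {
  if (is.null(labels)) labels <- m$labels
  if (is.null(labels)) stop("class labels are required")
  labels <- droplevels(as_class_factor(labels))
  if (nlevels(labels) < 2) stop("need at least two classes")
  if (is.null(norm_model)) norm_model <- norm_factors(m, normalization)
  mn <- apply_normalization(m, norm_model)
  lib <- effective_lib_sizes(mn, norm_model)
  fit <- voom_transform(mn, labels, lib, span = span)
  mom <- weighted_moments(fit$z, fit$w, labels, priors)
  list(norm = norm_model, voom = fit, moments = mom, labels = labels)
}

#' Fit a voom diagonal discriminant classifier (voomDLDA / voomDQDA)
#'
#' Runs the full training pipeline (normalization, voom transformation,
#' weighted moments) and stores the statistics of a diagonal Gaussian
#' discriminant rule: weighted class centroids with the weighted pooled
#' variances (`voomDLDA`, equal variances across classes) or the weighted
#' class-specific variances (`voomDQDA`).
#'
#' @param m a `count_matrix` of raw training counts (already gene-filtered)
#' @param labels class labels; defaults to `m$labels`
#' @param flavor `"voomDLDA"` or `"voomDQDA"`
#' @param normalization `"deseq"`, `"tmm"` or `"none"`
#' @param priors optional class priors (sum to 1); default class proportions
#' @param span lowess span of the voom trend
#' @param var_floor small constant added to variance denominators of the
#'   discriminant rule to guard genes with (near-)zero weighted variance
#' @param norm_model optional pre-computed `norm_model` (e.g. estimated on
#'   the unfiltered data); overrides `normalization`
#' @return object of classes `voom_dda_model`, `voomdda_model`; use
#'   [predict.voomdda_model()] on new count vectors
#' @export
fit_dda <- function(m, labels = NULL, flavor = c("voomDLDA", "voomDQDA"),
                    normalization = c("deseq", "tmm", "none"), priors = NULL,
                    span = 0.5, var_floor = 1e-8, norm_model = NULL) {
  flavor <- match.arg(flavor)
  normalization <- match.arg(normalization)
  pl <- dda_pipeline(m, labels, normalization, norm_model, priors, span)
  structure(list(flavor = flavor, moments = pl$moments, norm = pl$norm,
                 voom = pl$voom, var_floor = var_floor,
                 classes = pl$moments$classes, priors = pl$moments$priors,
                 genes = pl$voom$genes),
            class = c("voom_dda_model", "voomdda_model"))
}

#' Diagonal discriminant scores for one observation
#'
#' voomDLDA: `delta_k = -sum_g (z_g - zbar_wgk)^2 / s2_wg + 2 log(pi_k)`;
#' voomDQDA uses the class-specific variances `s2_wgk` in the denominator.
#' The predicted class maximizes the score; ties go to the lowest class
#' index.
#'
#' @param z_star per-gene log-cpm vector of the observation (training scale)
#' @param model a `voom_dda_model`
#' @return named per-class score vector
#' @export
dda_discriminant <- function(z_star, model) {
  mom <- model$moments
  dev2 <- (z_star - mom$class_means)^2
  v <- if (model$flavor == "voomDLDA") {
    matrix(mom$pooled_vars + model$var_floor, nrow(dev2), ncol(dev2))
  } else {
    mom$class_vars + model$var_floor
  }
  -colSums(dev2 / v) + 2 * log(mom$priors)
}

#' Weighted difference scores (standardized centroid contrasts)
#'
#' `d_wgk = (zbar_wgk - zbar_wg) / (m_k (s_wg + s_w0))`, where
#' `m_k = sqrt(1/n_k - 1/n)` is the standard-error adjustment and `s_w0`
#' (default: the median of the pooled weighted standard deviations across
#' genes) keeps the scores stable at low expression.
#'
#' @param moments a [weighted_moments()] object
#' @param s0 offset added to the pooled standard deviations; `NULL` for the
#'   median rule
#' @return list with `d` (p x K matrix), `s0`, `m_k`, `s_wg`
#' @export
difference_scores <- function(moments, s0 = NULL) {
  s_wg <- sqrt(moments$pooled_vars)
  if (is.null(s0)) s0 <- stats::median(s_wg)
  nk <- moments$class_sizes
  n <- moments$n
  if (any(nk == n)) stop("m_k is undefined when one class contains every sample")
  m_k <- sqrt(1 / nk - 1 / n)
  d <- (moments$class_means - moments$overall_mean) / outer(s_wg + s0, m_k)
  dimnames(d) <- dimnames(moments$class_means)
  list(d = d, s0 = s0, m_k = m_k, s_wg = s_wg)
}

#' Soft-threshold shrinkage
#'
#' `d' = sign(d) * max(|d| - lambda, 0)`, elementwise; the lasso-equivalent
#' shrinkage operator.
#'
#' @param d numeric vector or matrix of scores
#' @param lambda threshold, `lambda >= 0`
#' @return shrunken scores, same shape as `d`
#' @export
soft_threshold <- function(d, lambda) {
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0) stop("lambda must be a single value >= 0")
  out <- sign(d) * pmax(abs(d) - lambda, 0)
  if (!is.null(dim(d))) dimnames(out) <- dimnames(d)
  out
}

#' Threshold grid for shrunken-centroid tuning
#'
#' Equally spaced values from 0 to `max |d_wgk|` inclusive.
#'
#' @param d difference-score matrix (or the list from [difference_scores()])
#' @param n_points number of grid points (>= 2)
#' @return increasing numeric vector of length `n_points`
#' @export
lambda_grid <- function(d, n_points = 30) {
  if (is.list(d)) d <- d$d
  if (n_points < 2) stop("need at least 2 grid points")
  mx <- max(abs(d))
  if (mx == 0) warning("all difference scores are zero; the grid is degenerate")
  seq(0, mx, length.out = n_points)
}

#' Select the sparsest threshold attaining the minimum error
#'
#' Among thresholds whose error equals the minimum, returns the largest
#' (sparsest solution at an error tie).
#'
#' @param lambda candidate thresholds
#' @param errors misclassification error for each threshold
#' @return the selected threshold
#' @export
select_lambda <- function(lambda, errors) {
  stopifnot(length(lambda) == length(errors))
  max(lambda[errors == min(errors)])
}

#' Fit the sparse voomNSC classifier
#'
#' Training pipeline: normalization, voom transformation, weighted moments,
#' weighted difference scores, soft-threshold shrinkage at `lambda`, and
#' shrunken centroids `zbar'_wgk = zbar_wg + m_k (s_wg + s_w0) d'_wgk`.
#' Genes whose scores are shrunk to zero in every class have identical
#' centroids across classes and drop out of the decision rule; the remaining
#' `survivors` are the selected gene signature. When `lambda` is `NULL` it
#' is chosen by stratified cross-validation ([cross_validate_nsc()]).
#'
#' @inheritParams fit_dda
#' @param lambda shrinkage threshold (>= 0), or `NULL` to cross-validate
#' @param n_lambda grid size for cross-validation
#' @param cv_folds number of stratified folds
#' @param seed integer seed controlling fold assignment
#' @param s0 offset for the difference scores; `NULL` for the median rule
#' @return object of classes `voom_nsc_model`, `voomdda_model`
#' @export
fit_nsc <- function(m, labels = NULL, lambda = NULL,
                    normalization = c("deseq", "tmm", "none"), priors = NULL,
                    n_lambda = 30, cv_folds = 5, seed = 1, span = 0.5,
                    s0 = NULL, norm_model = NULL) {
  normalization <- match.arg(normalization)
  pl <- dda_pipeline(m, labels, normalization, norm_model, priors, span)
  ds <- difference_scores(pl$moments, s0)
  cv <- NULL
  if (is.null(lambda)) {
    grid <- lambda_grid(ds$d, n_lambda)
    cv <- cross_validate_nsc(m, pl$labels, grid = grid, d = ds$d,
                             normalization = normalization, folds = cv_folds,
                             seed = seed, priors = priors, span = span, s0 = s0)
    lambda <- cv$best_lambda
  }
  d_shrunk <- soft_threshold(ds$d, lambda)
  denom <- outer(ds$s_wg + ds$s0, ds$m_k)
  shrunk_centroids <- pl$moments$overall_mean + denom * d_shrunk
  dimnames(shrunk_centroids) <- dimnames(ds$d)
  survivors <- rownames(ds$d)[rowSums(d_shrunk != 0) > 0]
  structure(list(flavor = "voomNSC", moments = pl$moments, norm = pl$norm,
                 voom = pl$voom, d = ds$d, d_shrunk = d_shrunk,
                 shrunk_centroids = shrunk_centroids, lambda = lambda,
                 s0 = ds$s0, m_k = ds$m_k, s_wg = ds$s_wg,
                 survivors = survivors, cv = cv,
                 classes = pl$moments$classes, priors = pl$moments$priors,
                 genes = pl$voom$genes),
            class = c("voom_nsc_model", "voomdda_model"))
}

#' Shrunken-centroid discriminant scores and posteriors
#'
#' `delta_k = -1/2 sum_g (z_g - zbar'_wgk)^2 / (s_wg + s_w0)^2 + log(pi_k)`,
#' summed over all model genes (fully shrunk genes contribute identically to
#' every class). Posterior probabilities are `exp(-delta_k) / sum_l
#' exp(-delta_l)`, evaluated with max-subtraction for numerical stability;
#' `posterior_sign = "softmax"` exponentiates `+delta` instead. The
#' predicted class maximizes `delta_k` (ties to the lowest class index).
#'
#' @param z_star per-gene log-cpm vector of the observation (training scale)
#' @param model a `voom_nsc_model`
#' @param posterior_sign `"printed"` for `exp(-delta)`, `"softmax"` for
#'   `exp(+delta)`
#' @return list with `scores`, `posterior` (both named by class) and `class`
#' @export
nsc_discriminant <- function(z_star, model, posterior_sign = c("printed", "softmax")) {
  posterior_sign <- match.arg(posterior_sign)
  dev2 <- (z_star - model$shrunk_centroids)^2
  inv <- 1 / (model$s_wg + model$s0)^2
  scores <- -0.5 * colSums(dev2 * inv) + log(model$priors)
  t <- if (posterior_sign == "printed") -scores else scores
  e <- exp(t - max(t))
  list(scores = scores, posterior = e / sum(e),
       class = model$classes[which.max(scores)])
}

# Stratified fold assignment: within each class, a seeded random permutation
# of a balanced fold sequence.
make_folds <- function(labels, folds, seed) {
  labels <- droplevels(as_class_factor(labels))
  fold_id <- integer(length(labels))
  set.seed(seed)
  for (k in levels(labels)) {
    idx <- which(labels == k)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold_id
}

#' Cross-validate the voomNSC shrinkage threshold
#'
#' Stratified K-fold cross-validation over a threshold grid. For every fold
#' the FULL pipeline (normalization, voom transformation, weighted moments,
#' difference scores) is refit on the training folds; held-out samples are
#' normalized and transformed with the fold-training parameters only, and
#' classified at every grid threshold. The selected threshold is the LARGEST
#' one attaining the minimum cross-validation misclassification error (the
#' sparsest solution among the error ties). The same folds, fixed by `seed`,
#' are used for every threshold.
#'
#' @inheritParams fit_nsc
#' @param grid threshold grid; `NULL` derives a [lambda_grid()] from the
#'   full-data difference scores
#' @param d optional full-data difference-score matrix (used for the
#'   per-threshold sparsity column; recomputed when absent)
#' @param folds number of stratified folds; reduced with a warning when a
#'   class has fewer samples than `folds`
#' @return object of class `nsc_cv`: list with `lambda`, `cv_error`,
#'   `n_survivors`, `best_lambda`, `fold_id`, `seed`
#' @export
cross_validate_nsc <- function(m, labels = NULL, grid = NULL, d = NULL,
                               normalization = c("deseq", "tmm", "none"),
                               folds = 5, n_lambda = 30, seed = 1,
                               priors = NULL, span = 0.5, s0 = NULL) {
  normalization <- match.arg(normalization)
  if (is.null(labels)) labels <- m$labels
  labels <- droplevels(as_class_factor(labels))
  n <- ncol(m$counts)
  if (is.null(grid) || is.null(d)) {
    pl <- dda_pipeline(m, labels, normalization, NULL, priors, span)
    d <- difference_scores(pl$moments, s0)$d
    if (is.null(grid)) grid <- lambda_grid(d, n_lambda)
  }
  min_k <- min(table(labels))
  if (min_k < folds) {
    folds <- max(2, min_k)
    warning(sprintf("smallest class has %d samples; reducing to %d folds", min_k, folds))
  }
  fold_id <- make_folds(labels, folds, seed)
  errors <- numeric(length(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (nlevels(droplevels(labels[tr])) < nlevels(labels)) {
      stop(sprintf("fold %d training set lost a class entirely", f))
    }
    if (any(table(labels[tr]) < 2)) {
      stop(sprintf("fold %d leaves a class with fewer than 2 training samples", f))
    }
    pl <- dda_pipeline(m[, tr], labels[tr], normalization, NULL, priors, span)
    ds <- difference_scores(pl$moments, s0)
    denom <- outer(ds$s_wg + ds$s0, ds$m_k)
    inv <- 1 / (ds$s_wg + ds$s0)^2
    log_pri <- log(pl$moments$priors)
    for (j in which(!tr)) {
      tt <- transform_test(m$counts[, j], pl$norm, pl$voom)
      base <- tt$z - pl$moments$overall_mean
      for (li in seq_along(grid)) {
        resid <- base - denom * soft_threshold(ds$d, grid[li])
        scores <- -0.5 * colSums(resid^2 * inv) + log_pri
        pred <- pl$moments$classes[which.max(scores)]
        if (pred != as.character(labels[j])) errors[li] <- errors[li] + 1
      }
    }
  }
  cv_error <- errors / n
  structure(list(lambda = grid, cv_error = cv_error,
                 n_survivors = vapply(grid, function(l) sum(rowSums(abs(d) > l) > 0), integer(1)),
                 best_lambda = select_lambda(grid, cv_error),
                 fold_id = fold_id, folds = folds, seed = seed),
            class = "nsc_cv")
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat(sprintf("voomNSC cross-validation (%d folds): best lambda = %.4g (CV error %.3f, %d genes)\n",
              x$folds, x$best_lambda,
              x$cv_error[match(x$best_lambda, x$lambda)],
              x$n_survivors[match(x$best_lambda, x$lambda)]))
  invisible(x)
}

#' @export
print.voomdda_model <- function(x, ...) {
  cat(sprintf("%s model: %d genes, classes %s\n", x$flavor,
              length(x$genes), paste(x$classes, collapse = "/")))
  if (x$flavor == "voomNSC") {
    cat(sprintf("lambda = %.4g; %d surviving genes\n", x$lambda, length(x$survivors)))
  }
  invisible(x)
}

#' Predict classes of new count observations
#'
#' Each test sample is normalized with the frozen training normalization
#' model, transformed to log-cpm with the frozen voom parameters, and scored
#' by the model's discriminant rule.
#'
#' @param object a fitted `voomdda_model`
#' @param newdata a `count_matrix`, a gene x sample matrix, or a single
#'   named count vector; rows must cover the training gene universe
#' @param type `"class"` (factor of predictions), `"scores"` or
#'   `"posterior"` (sample x class matrices; posteriors for voomNSC only)
#' @param posterior_sign passed to [nsc_discriminant()]
#' @param ... ignored
#' @return see `type`
#' @export
predict.voomdda_model <- function(object, newdata,
                                  type = c("class", "scores", "posterior"),
                                  posterior_sign = c("printed", "softmax"), ...) {
  type <- match.arg(type)
  posterior_sign <- match.arg(posterior_sign)
  if (inherits(newdata, "count_matrix")) newdata <- newdata$counts
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1, dimnames = list(names(newdata), "sample1"))
  if (type == "posterior" && object$flavor != "voomNSC") {
    stop("posterior probabilities are defined for voomNSC models")
  }
  K <- length(object$classes)
  scores <- matrix(NA_real_, ncol(newdata), K,
                   dimnames = list(colnames(newdata), object$classes))
  posterior <- scores
  for (j in seq_len(ncol(newdata))) {
    tt <- transform_test(newdata[, j], object$norm, object$voom)
    if (object$flavor == "voomNSC") {
      sc <- nsc_discriminant(tt$z, object, posterior_sign)
      scores[j, ] <- sc$scores
      posterior[j, ] <- sc$posterior
    } else {
      scores[j, ] <- dda_discriminant(tt$z, object)
    }
  }
  switch(type,
    class = factor(object$classes[max.col(scores, ties.method = "first")],
                   levels = object$classes),
    scores = scores,
    posterior = posterior)
}

#' Classification performance metrics
#'
#' Misclassification error, balanced misclassification error
#' (`1 - (sensitivity + specificity)/2`, averaged one-vs-all over classes
#' for multiclass problems), the confusion matrix, and - when a sparse model
#' size is supplied - sparsity and relative sparsity (selected genes over
#' total genes).
#'
#' @param truth true class labels
#' @param predicted predicted class labels (must not contain classes absent
#'   from `truth`)
#' @param n_features optional number of genes in the decision rule
#' @param n_total optional total number of genes available to the model
#' @return list with `error`, `balanced_error`, `confusion`, and optionally
#'   `sparsity`, `relative_sparsity`
#' @export
evaluate_predictions <- function(truth, predicted, n_features = NULL, n_total = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("truth and predictions differ in length")
  classes <- unique(truth)
  unseen <- setdiff(predicted, classes)
  if (length(unseen)) {
    stop(sprintf("predicted label(s) absent from truth: %s", paste(unseen, collapse = ", ")))
  }
  bal <- vapply(classes, function(k) {
    tp <- sum(truth == k & predicted == k)
    fn <- sum(truth == k & predicted != k)
    tn <- sum(truth != k & predicted != k)
    fp <- sum(truth != k & predicted == k)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    1 - (sens + spec) / 2
  }, numeric(1))
  out <- list(error = mean(truth != predicted),
              balanced_error = mean(bal),
              confusion = table(truth = factor(truth, classes),
                                predicted = factor(predicted, classes)))
  if (!is.null(n_features)) {
    out$sparsity <- n_features
    if (!is.null(n_total)) out$relative_sparsity <- n_features / n_total
  }
  out
}
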