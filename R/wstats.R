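#' Weighted class means (centroids)
#'
#' Per gene and class, the precision-weighted average of the log-cpm values
#' over that class's samples: `zbar_wgk = sum_i(w_gi z_gi) / sum_i(w_gi)`.
#'
#' @param z p x n log-cpm matrix
#' @param w p x n positive weight matrix (a scalar is recycled)
#' @param labels factor of classes, one per sample
#' @return p x K matrix of weighted class means
#' @export
weighted_class_means <- function(z, w, labels) {
  w <- recycle_weights(w, z)
  labels <- droplevels(as_class_factor(labels))
  out <- vapply(levels(labels), function(k) {
    idx <- which(labels == k)
    sw <- rowSums(w[, idx, drop = FALSE])
    if (any(sw <= 0)) stop(sprintf("zero total weight in class '%s'", k))
    rowSums((w * z)[, idx, drop = FALSE]) / sw
  }, numeric(nrow(z)))
  matrix(out, nrow = nrow(z), dimnames = list(rownames(z), levels(labels)))
}

#' Overall weighted mean from class means
#'
#' Class-size-weighted average of the class centroids:
#' `zbar_wg = sum_k n_k zbar_wgk / n`.
#'
#' @param class_means p x K matrix of class means
#' @param class_sizes per-class sample counts `n_k`
#' @return per-gene overall mean
#' @export
weighted_overall_mean <- function(class_means, class_sizes) {
  stopifnot(ncol(class_means) == length(class_sizes))
  as.vector(class_means %*% class_sizes) / sum(class_sizes)
}

#' Weighted within-class variances
#'
#' Unbiased weighted variance of each gene within each class:
#' `s2_wgk = [ S1 / (S1^2 - S2) ] * sum_i w_gi (z_gi - zbar_wgk)^2`, with
#' `S1 = sum w_gi`, `S2 = sum w_gi^2` over the class's samples. With equal
#' weights this reduces to the classical sample variance (divisor n_k - 1).
#'
#' @inheritParams weighted_class_means
#' @return p x K matrix of weighted class variances
#' @export
weighted_class_variance <- function(z, w, labels) {
  w <- recycle_weights(w, z)
  labels <- droplevels(as_class_factor(labels))
  means <- weighted_class_means(z, w, labels)
  out <- vapply(levels(labels), function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2) stop(sprintf("class '%s' needs at least 2 samples for a variance", k))
    wk <- w[, idx, drop = FALSE]
    s1 <- rowSums(wk)
    s2 <- rowSums(wk^2)
    denom <- s1^2 - s2
    if (any(denom <= 0)) {
      stop(sprintf("effective sample size too small in class '%s' ((sum w)^2 <= sum w^2)", k))
    }
    dev2 <- (z[, idx, drop = FALSE] - means[, k])^2
    (s1 / denom) * rowSums(wk * dev2)
  }, numeric(nrow(z)))
  matrix(out, nrow = nrow(z), dimnames = dimnames(means))
}

#' Weighted pooled variance
#'
#' Pools the weighted class variances with classical degrees of freedom:
#' `s2_wg = sum_k (n_k - 1) s2_wgk / (n - K)`.
#'
#' @param class_vars p x K matrix of weighted class variances
#' @param class_sizes per-class sample counts
#' @return per-gene pooled variance
#' @export
weighted_pooled_variance <- function(class_vars, class_sizes) {
  stopifnot(ncol(class_vars) == length(class_sizes))
  n <- sum(class_sizes)
  K <- length(class_sizes)
  if (n <= K) stop("pooling needs n > K")
  as.vector(class_vars %*% (class_sizes - 1)) / (n - K)
}

#' All weighted moments used by the classifiers
#'
#' Convenience wrapper computing, in one pass, the weighted class centroids,
#' the overall centroid, the weighted class and pooled variances, class
#' sizes and class priors.
#'
#' @inheritParams weighted_class_means
#' @param priors optional per-class prior probabilities (must sum to 1);
#'   defaults to the class proportions `n_k / n`
#' @return object of class `weighted_moments`: list with `class_means`,
#'   `overall_mean`, `class_vars`, `pooled_vars`, `class_sizes`, `priors`,
#'   `classes`, `n`
#' @export
weighted_moments <- function(z, w, labels, priors = NULL) {
  w <- recycle_weights(w, z)
  labels <- droplevels(as_class_factor(labels))
  class_sizes <- as.vector(table(labels))
  names(class_sizes) <- levels(labels)
  class_means <- weighted_class_means(z, w, labels)
  class_vars <- weighted_class_variance(z, w, labels)
  n <- ncol(z)
  if (is.null(priors)) {
    priors <- class_sizes / n
  } else {
    if (length(priors) != length(class_sizes)) stop("need one prior per class")
    if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
    priors <- stats::setNames(as.numeric(priors), levels(labels))
  }
  structure(list(class_means = class_means,
                 overall_mean = weighted_overall_mean(class_means, class_sizes),
                 class_vars = class_vars,
                 pooled_vars = weighted_pooled_variance(class_vars, class_sizes),
                 class_sizes = class_sizes,
                 priors = priors,
                 classes = levels(labels),
                 n = n),
            class = "weighted_moments")
}

recycle_weights <- function(w, z) {
  if (length(w) == 1) w <- matrix(w, nrow(z), ncol(z))
  if (!all(dim(w) == dim(z))) stop("weights must match the shape of z")
  if (any(w <= 0) || any(!is.finite(w))) stop("weights must be positive and finite")
  w
}
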