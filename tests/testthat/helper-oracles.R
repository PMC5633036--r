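# Fixture generators and independent brute-force oracles used across the
# suite. Oracles are deliberately written as plain loops over the defining
# formulas, independent of the package's vectorized implementations.

rand_counts <- function(p, n, mu = 50, size = 5, labels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(rnbinom(p * n, mu = mu, size = size), p, n,
                   dimnames = list(paste0("g", seq_len(p)), paste0("s", seq_len(n))))
  count_matrix(counts, labels)
}

two_class_labels <- function(n) factor(rep(c("A", "B"), length.out = n), levels = c("A", "B"))

# One simulated dataset split 70/30 (stratified) into filtered training and
# held-out test sets sharing the same differential-expression structure.
toy_split <- function(seed, p = 500, n = 80, p_keep = 250, de_prob = 0.1,
                      sigma = 0.2, phi = 0.01) {
  sim <- simulate_counts(sim_scenario(p = p, n = n, K = 2, de_prob = de_prob,
                                      sigma = sigma, phi = phi, p_keep = p_keep,
                                      seed = seed))
  lab <- sim$data$labels
  set.seed(seed)
  tr <- logical(n)
  for (k in levels(lab)) {
    idx <- which(lab == k)
    tr[sample(idx, round(0.7 * length(idx)))] <- TRUE
  }
  m_tr <- sim$data[, tr]
  nz <- near_zero_filter(m_tr)
  mf <- variance_filter(nz$kept, min(p_keep, nrow(nz$kept$counts)),
                        deseq_size_factors(nz$kept)$size_factors)
  list(sim = sim, train = mf, test = sim$data[, !tr])
}

# --- formula oracles -------------------------------------------------------

bf_log_cpm <- function(x, lib) {
  z <- matrix(NA_real_, nrow(x), ncol(x))
  for (i in seq_len(ncol(x))) for (g in seq_len(nrow(x))) {
    z[g, i] <- log2((x[g, i] + 0.5) / (lib[i] + 1) * 1e6)
  }
  z
}

bf_weighted_mean <- function(z, w) sum(w * z) / sum(w)

bf_weighted_var <- function(z, w) {
  zb <- bf_weighted_mean(z, w)
  s1 <- sum(w); s2 <- sum(w^2)
  (s1 / (s1^2 - s2)) * sum(w * (z - zb)^2)
}

bf_pooled_var <- function(class_vars, nk) {
  tot <- 0
  for (k in seq_along(nk)) tot <- tot + (nk[k] - 1) * class_vars[k]
  unname(tot / (sum(nk) - length(nk)))
}

bf_deseq_factors <- function(counts) {
  p <- nrow(counts); n <- ncol(counts)
  geo <- apply(counts, 1, function(x) prod(x)^(1 / n))
  use <- apply(counts, 1, function(x) all(x > 0))
  sapply(seq_len(n), function(i) median(counts[use, i] / geo[use]))
}

# Untrimmed Eq-style weighted mean of M values (weights as printed).
bf_tmm_untrimmed <- function(x, xr) {
  lx <- sum(x); lr <- sum(xr)
  num <- 0; den <- 0
  for (g in seq_along(x)) {
    if (x[g] > 0 && xr[g] > 0) {
      M <- log2((x[g] / lx) / (xr[g] / lr))
      w <- (lx - x[g]) / (lx * x[g]) + (lr - xr[g]) / (lr * xr[g])
      num <- num + w * M
      den <- den + w
    }
  }
  num / den
}

bf_dda_scores <- function(z_star, means, vars, priors, dlda_pooled = NULL, floor = 1e-8) {
  K <- ncol(means)
  priors <- unname(priors)
  sapply(seq_len(K), function(k) {
    s <- 0
    for (g in seq_len(nrow(means))) {
      v <- if (is.null(dlda_pooled)) vars[g, k] else dlda_pooled[g]
      s <- s - (z_star[g] - means[g, k])^2 / (v + floor)
    }
    s + 2 * log(priors[k])
  })
}

# Classical (unweighted) nearest-shrunken-centroid recipe computed on a
# log-expression matrix z by direct loops: centroids, pooled sd with divisor
# n-K, median s0, soft-thresholded standardized contrasts, shrunken
# centroids, and the discriminant of one observation.
bf_classical_nsc <- function(z, labels, lambda) {
  labels <- factor(labels)
  K <- nlevels(labels); n <- ncol(z); p <- nrow(z)
  nk <- as.vector(table(labels))
  cent <- sapply(levels(labels), function(k) rowMeans(z[, labels == k, drop = FALSE]))
  overall <- as.vector(cent %*% nk) / n
  s2 <- numeric(p)
  for (g in seq_len(p)) {
    rss <- 0
    for (i in seq_len(n)) rss <- rss + (z[g, i] - cent[g, as.integer(labels)[i]])^2
    s2[g] <- rss / (n - K)
  }
  s <- sqrt(s2)
  s0 <- median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d <- matrix(NA_real_, p, K)
  for (g in seq_len(p)) for (k in seq_len(K)) {
    d[g, k] <- (cent[g, k] - overall[g]) / (mk[k] * (s[g] + s0))
  }
  dp <- sign(d) * pmax(abs(d) - lambda, 0)
  cent_shrunk <- matrix(NA_real_, p, K)
  for (g in seq_len(p)) for (k in seq_len(K)) {
    cent_shrunk[g, k] <- overall[g] + mk[k] * (s[g] + s0) * dp[g, k]
  }
  list(centroids = cent, overall = overall, s = s, s0 = s0, d = d,
       d_shrunk = dp, shrunk_centroids = cent_shrunk, priors = nk / n,
       classes = levels(labels))
}

bf_nsc_score <- function(z_star, nsc) {
  K <- length(nsc$classes)
  sapply(seq_len(K), function(k) {
    s <- 0
    for (g in seq_along(z_star)) {
      s <- s - 0.5 * (z_star[g] - nsc$shrunk_centroids[g, k])^2 / (nsc$s[g] + nsc$s0)^2
    }
    s + log(nsc$priors[k])
  })
}

bf_metrics <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- unique(truth)
  bal <- sapply(classes, function(k) {
    sens <- sum(truth == k & pred == k) / sum(truth == k)
    spec <- sum(truth != k & pred != k) / sum(truth != k)
    1 - (sens + spec) / 2
  })
  list(error = mean(truth != pred), balanced_error = mean(bal))
}
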